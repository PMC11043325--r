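# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# Gamma GLM with log link by hand-rolled IRLS. For the log link with Gamma
# variance V(mu) = mu^2 the IRLS weights are identically 1, so each step is
# an OLS solve on the working response z = eta + (y - mu) / mu.
irls_gamma_log <- function(X, y, tol = 1e-12, max_iter = 200) {
  eta <- rep(log(mean(y)), length(y))
  beta <- NULL
  for (i in seq_len(max_iter)) {
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X), crossprod(X, z))
    eta_new <- as.numeric(X %*% beta_new)
    if (!is.null(beta) && max(abs(beta_new - beta)) < tol) {
      return(as.numeric(beta_new))
    }
    beta <- beta_new
    eta <- eta_new
  }
  as.numeric(beta)
}

# Ray-casting point-in-polygon: counts crossings of a horizontal ray.
ray_cast_inside <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

ray_cast_label <- function(px, py, layer) {
  for (i in seq_along(layer$labels)) {
    if (ray_cast_inside(px, py, layer$rings[[i]])) return(layer$labels[[i]])
  }
  NA_character_
}

# Exhaustive minimum SSE over all 2-partitions of n points (both parts
# non-empty); 2^(n-1) - 1 candidate splits.
brute_force_sse_k2 <- function(points) {
  n <- nrow(points)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    sse <- 0
    for (g in list(grp, !grp)) {
      ctr <- colMeans(points[g, , drop = FALSE])
      sse <- sse + sum(sweep(points[g, , drop = FALSE], 2, ctr)^2)
    }
    best <- min(best, sse)
  }
  best
}

# Zero-noise generator settings: one common intercept, flat age/year
# effects, no random intercepts, no Gamma noise, no missingness.
zero_noise_config <- function(...) {
  defaults <- list(
    seed = 11L, n_reservoirs = 120L,
    density_intercept_per_class = c(small_low = 150, small_high = 150,
                                    large_low = 150, large_high = 150),
    age_amplitude = 0, year_trend_slope = 0, random_intercept_sd = 0,
    gamma_shape = Inf, area_noise_sd = 0,
    prop_missing_area = 0, prop_missing_coords = 0,
    prop_missing_discharge = 0, prop_duplicate = 0, prop_natural_lake = 0,
    survey_fraction = 0.3)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Hand-built linked-survey tables for model tests (bypassing CSV IO).
make_model_table <- function(density, age, year, class_label, reservoir_id,
                             year_completed = year - age) {
  tibble::tibble(
    survey_id = sprintf("S%03d", seq_along(density)),
    reservoir_id = reservoir_id,
    year_sampled = year,
    corrected_density = density,
    reservoir_age = age,
    year_completed = year_completed,
    class_label = class_label)
}
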
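#' Simulate a dam/reservoir inventory table
#'
#' Generates `n_reservoirs` inventory rows with the statistical structure
#' the estimation pipeline assumes: jointly log-normal storage volume and
#' maximum discharge with per-ecoregion mean shifts, a power-law
#' area--volume relation, coordinates placed inside square ecoregion tiles,
#' plus injected duplicate-dam rows (a second, smaller dam listed under the
#' same reservoir name and state) and flagged natural-lake rows so the
#' cleaning rules are exercised. A configured fraction of areas,
#' coordinates, and discharges is blanked missing-completely-at-random.
#'
#' Hidden ground-truth columns (`true_class`, `true_area_ha`) are carried
#' for parameter-recovery tests and are not written by [write_simulation()].
#' The generated ecoregion tiling is attached as attribute `"ecoregions"`.
#'
#' @param config a [simulation_config()].
#' @return a tibble of reservoir records.
#' @export
simulate_inventory <- function(config) {
  validate_simulation_config(config)
  layer <- make_ecoregion_grid(config$n_ecoregions, config$bbox)
  empty <- tibble::tibble(
    reservoir_id = character(), name = character(), state = character(),
    latitude = numeric(), longitude = numeric(),
    year_completed = integer(), storage_volume_m3 = numeric(),
    max_discharge_m3s = numeric(), surface_area_ha = numeric(),
    natural_lake = logical(), true_class = character(),
    true_area_ha = numeric())
  if (config$n_reservoirs == 0) {
    attr(empty, "ecoregions") <- layer
    return(empty)
  }
  with_child_seed(config$seed, 1L, {
    n <- config$n_reservoirs
    n_lake <- min(n, round(config$prop_natural_lake * n))
    n_dup <- min(n - n_lake, round(config$prop_duplicate * n))
    n_base <- n - n_lake - n_dup

    state_pool <- c("AL", "AR", "FL", "GA", "IA", "IL", "IN", "KS", "KY",
                    "LA", "MA", "MD", "MO", "MS", "NC", "NM", "OK", "SC",
                    "TN", "TX", "VA", "WV",
                    "CA", "CO", "MT", "ND", "NE", "NV", "OR", "UT")

    eco_idx <- sample.int(config$n_ecoregions, n_base, replace = TRUE)
    eco_shift_v <- stats::rnorm(config$n_ecoregions, 0, config$ecoregion_sd)
    eco_shift_q <- stats::rnorm(config$n_ecoregions, 0, config$ecoregion_sd)

    z1 <- stats::rnorm(n_base)
    z2 <- stats::rnorm(n_base)
    rho <- config$vol_discharge_cor
    ln_v <- config$ln_volume_mean + eco_shift_v[eco_idx] +
      config$ln_volume_sd * z1
    ln_q <- config$ln_discharge_mean + eco_shift_q[eco_idx] +
      config$ln_discharge_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    volume <- exp(ln_v)
    discharge <- exp(ln_q)
    area <- config$area_coeff * volume^config$area_exponent *
      exp(stats::rnorm(n_base, 0, config$area_noise_sd))

    # uniform position within the reservoir's ecoregion tile (2% margin
    # keeps points off shared tile edges)
    lon <- lat <- numeric(n_base)
    for (e in unique(eco_idx)) {
      idx <- which(eco_idx == e)
      ring <- layer$rings[[e]]
      xr <- range(ring[, 1]); yr <- range(ring[, 2])
      mx <- 0.02 * diff(xr); my <- 0.02 * diff(yr)
      lon[idx] <- stats::runif(length(idx), xr[1] + mx, xr[2] - mx)
      lat[idx] <- stats::runif(length(idx), yr[1] + my, yr[2] - my)
    }

    # latent class: median splits of the clustering covariates, so the
    # size-flow schemas can recover the generating partition
    small <- log1p(volume) <= stats::median(log1p(volume))
    low <- log1p(discharge) <= stats::median(log1p(discharge))
    true_class <- ifelse(small,
                         ifelse(low, "small_low", "small_high"),
                         ifelse(low, "large_low", "large_high"))

    base <- tibble::tibble(
      reservoir_id = sprintf("R%05d", seq_len(n_base)),
      name = sprintf("Reservoir %d", seq_len(n_base)),
      state = sample(state_pool, n_base, replace = TRUE),
      latitude = lat, longitude = lon,
      year_completed = sample(
        seq(config$year_completed_range[1], config$year_completed_range[2]),
        n_base, replace = TRUE),
      storage_volume_m3 = volume, max_discharge_m3s = discharge,
      surface_area_ha = area, natural_lake = FALSE,
      true_class = true_class, true_area_ha = area)

    dup <- base[sample.int(n_base, min(n_dup, n_base)), , drop = FALSE]
    if (nrow(dup) > 0) {
      dup$reservoir_id <- sprintf("D%05d", seq_len(nrow(dup)))
      dup$storage_volume_m3 <- dup$storage_volume_m3 *
        stats::runif(nrow(dup), 0.05, 0.5)
      dup$surface_area_ha <- NA_real_
      dup$true_class <- NA_character_
      dup$true_area_ha <- NA_real_
    }

    lake <- if (n_lake > 0) {
      tibble::tibble(
        reservoir_id = sprintf("L%05d", seq_len(n_lake)),
        name = sprintf("Natural Lake %d", seq_len(n_lake)),
        state = sample(state_pool, n_lake, replace = TRUE),
        latitude = stats::runif(n_lake, config$bbox[3], config$bbox[4]),
        longitude = stats::runif(n_lake, config$bbox[1], config$bbox[2]),
        year_completed = sample(
          seq(config$year_completed_range[1], config$year_completed_range[2]),
          n_lake, replace = TRUE),
        storage_volume_m3 = exp(stats::rnorm(n_lake, 22, 1)),
        max_discharge_m3s = exp(stats::rnorm(n_lake, 5, 1)),
        surface_area_ha = exp(stats::rnorm(n_lake, 12, 0.5)),
        natural_lake = TRUE,
        true_class = NA_character_, true_area_ha = NA_real_)
    } else {
      base[0, , drop = FALSE]
    }

    inv <- dplyr::bind_rows(base, dup, lake)

    blank <- function(x, prop) {
      x[stats::runif(length(x)) < prop] <- NA
      x
    }
    inv$surface_area_ha <- blank(inv$surface_area_ha, config$prop_missing_area)
    inv$max_discharge_m3s <- blank(inv$max_discharge_m3s,
                                   config$prop_missing_discharge)
    miss_xy <- stats::runif(nrow(inv)) < config$prop_missing_coords
    inv$latitude[miss_xy] <- NA_real_
    inv$longitude[miss_xy] <- NA_real_

    attr(inv, "ecoregions") <- layer
    inv
  })
}

# log-scale age effect: a short-lived post-impoundment production spike
# that peaks at age = tau and dissipates
age_effect <- function(age, amplitude, timescale) {
  amplitude * age * exp(-age / timescale)
}

# deterministic log expected density for one reservoir-year
expected_log_density <- function(config, class, age, year) {
  b0 <- log(config$density_intercept_per_class[class])
  unname(b0 + age_effect(age, config$age_amplitude, config$age_timescale) +
           config$year_trend_slope * (year - config$year_range[1]))
}

#' Simulate rotenone survey records for an inventory
#'
#' Draws surveys for a fraction of (unique, non-lake) reservoirs. The true
#' density of reservoir i in year t is
#' `exp(b0_class + alpha*age*exp(-age/tau) + slope*(t - t0) + u_i) * eps`
#' with `u_i ~ N(0, random_intercept_sd)` and multiplicative
#' `eps ~ Gamma(shape, scale = 1/shape)` (mean 1). Setting
#' `gamma_shape = Inf` switches the Gamma noise off exactly. The recorded
#' raw density is the true density divided by `recovery_constant`,
#' emulating incomplete recovery of poisoned fish. Surveys whose sampling
#' year precedes dam completion are skipped; the count is returned in
#' attribute `"n_skipped"`.
#'
#' @param inventory output of [simulate_inventory()].
#' @param config the same [simulation_config()].
#' @return a tibble of survey records with hidden column `true_density`.
#' @export
simulate_surveys <- function(inventory, config) {
  validate_simulation_config(config)
  empty <- tibble::tibble(
    survey_id = character(), reservoir_id = character(),
    year_sampled = integer(), raw_density_kg_ha = numeric(),
    true_density = numeric())
  attr(empty, "n_skipped") <- 0L
  if (config$survey_fraction == 0) return(empty)
  eligible <- inventory[!inventory$natural_lake &
                          !is.na(inventory$true_class), , drop = FALSE]
  if (nrow(eligible) == 0) {
    stop("inventory has no eligible reservoirs but survey_fraction > 0",
         call. = FALSE)
  }
  with_child_seed(config$seed, 2L, {
    n_sampled <- max(1L, round(config$survey_fraction * nrow(eligible)))
    sampled <- eligible[sample.int(nrow(eligible), n_sampled), , drop = FALSE]
    u <- stats::rnorm(n_sampled, 0, config$random_intercept_sd)
    years_all <- seq(config$year_range[1], config$year_range[2])
    spr <- min(config$surveys_per_reservoir, length(years_all))

    rows <- vector("list", n_sampled)
    for (i in seq_len(n_sampled)) {
      yrs <- sort(sample(years_all, spr))
      rows[[i]] <- tibble::tibble(
        reservoir_id = sampled$reservoir_id[i],
        true_class = sampled$true_class[i],
        year_completed = sampled$year_completed[i],
        year_sampled = yrs, u = u[i])
    }
    sv <- dplyr::bind_rows(rows)
    sv$age <- sv$year_sampled - sv$year_completed
    n_skipped <- sum(sv$age < 0)
    if (n_skipped > 0) {
      warning(n_skipped, " survey row(s) predate dam completion; skipped",
              call. = FALSE)
    }
    sv <- sv[sv$age >= 0, , drop = FALSE]

    eta <- expected_log_density(config, sv$true_class, sv$age,
                                sv$year_sampled) + sv$u
    eps <- if (is.finite(config$gamma_shape)) {
      stats::rgamma(nrow(sv), shape = config$gamma_shape,
                    rate = config$gamma_shape)
    } else {
      rep(1, nrow(sv))
    }
    true_density <- exp(eta) * eps
    out <- tibble::tibble(
      survey_id = sprintf("S%05d", seq_len(nrow(sv))),
      reservoir_id = sv$reservoir_id,
      year_sampled = as.integer(sv$year_sampled),
      raw_density_kg_ha = true_density / config$recovery_constant,
      true_density = true_density)
    attr(out, "n_skipped") <- n_skipped
    # ground truth for recovery tests: the realized per-reservoir intercepts
    attr(out, "random_intercepts") <-
      tibble::tibble(reservoir_id = sampled$reservoir_id, u = u)
    out
  })
}

#' Simulate independent validation surveys
#'
#' Picks `n_validation` reservoirs and records an "observed" total standing
#' stock: the deterministic expected density at the standardization year
#' times true surface area, perturbed by log-normal observation error.
#'
#' @inheritParams simulate_surveys
#' @return tibble with `reservoir_id`, `observed_kg`.
#' @export
simulate_validation <- function(inventory, config) {
  validate_simulation_config(config)
  eligible <- inventory[!inventory$natural_lake &
                          !is.na(inventory$true_class), , drop = FALSE]
  if (nrow(eligible) == 0 || config$n_validation == 0) {
    return(tibble::tibble(reservoir_id = character(), observed_kg = numeric()))
  }
  with_child_seed(config$seed, 3L, {
    idx <- sample.int(nrow(eligible),
                      min(config$n_validation, nrow(eligible)))
    res <- eligible[idx, , drop = FALSE]
    age <- pmax(0, config$standardization_year - res$year_completed)
    dens <- exp(expected_log_density(config, res$true_class, age,
                                     config$standardization_year))
    err <- exp(stats::rnorm(nrow(res), 0, config$validation_error_sd))
    tibble::tibble(reservoir_id = res$reservoir_id,
                   observed_kg = dens * res$true_area_ha * err)
  })
}

#' Ground-truth densities and standing stock
#'
#' The generator's own answer key: for every unique, non-lake reservoir,
#' the deterministic expected density at the standardization year (random
#' intercept at its mode 0; Gamma noise at its mean 1) and the implied
#' standing stock over the true surface area. With
#' `expectation = TRUE` the log-normal random-intercept mean factor
#' `exp(sd^2 / 2)` is included, giving the exact marginal expectation.
#'
#' @inheritParams simulate_surveys
#' @param expectation include the random-intercept log-normal mean factor.
#' @return tibble of per-reservoir truth with attribute `total_kg`.
#' @export
true_summary <- function(inventory, config, expectation = FALSE) {
  validate_simulation_config(config)
  res <- inventory[!inventory$natural_lake &
                     !is.na(inventory$true_class), , drop = FALSE]
  if (nrow(res) == 0) {
    out <- tibble::tibble(reservoir_id = character(),
                          class_label = character(), density_kg_ha = numeric(),
                          surface_area_ha = numeric(), standing_stock_kg = numeric())
    attr(out, "total_kg") <- 0
    return(out)
  }
  age <- pmax(0, config$standardization_year - res$year_completed)
  dens <- exp(expected_log_density(config, res$true_class, age,
                                   config$standardization_year))
  if (expectation) dens <- dens * exp(config$random_intercept_sd^2 / 2)
  out <- tibble::tibble(
    reservoir_id = res$reservoir_id, class_label = res$true_class,
    density_kg_ha = dens, surface_area_ha = res$true_area_ha,
    standing_stock_kg = dens * res$true_area_ha)
  attr(out, "total_kg") <- sum(out$standing_stock_kg)
  out
}

#' Simulate the full input bundle
#'
#' @param config a [simulation_config()].
#' @return list with `inventory`, `surveys`, `validation`, `truth`,
#'   `ecoregions`.
#' @export
simulate_dataset <- function(config) {
  inventory <- simulate_inventory(config)
  surveys <- withCallingHandlers(
    simulate_surveys(inventory, config),
    warning = function(w) invokeRestart("muffleWarning"))
  list(inventory = inventory,
       surveys = surveys,
       validation = simulate_validation(inventory, config),
       truth = true_summary(inventory, config),
       ecoregions = attr(inventory, "ecoregions"))
}

#' Write a simulated dataset to disk
#'
#' Writes `inventory.csv`, `surveys.csv`, `validation.csv`, `truth.csv`,
#' `ecoregions.geojson`, and `config.yml` under `dir`. Ground-truth columns
#' are kept out of the inventory and survey CSVs (they live in
#' `truth.csv`).
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory, created if absent.
#' @param config the [simulation_config()] used.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv <- sim$inventory[, setdiff(names(sim$inventory),
                                 c("true_class", "true_area_ha"))]
  readr::write_csv(inv, file.path(dir, "inventory.csv"), na = "")
  sv <- sim$surveys[, setdiff(names(sim$surveys), "true_density")]
  readr::write_csv(sv, file.path(dir, "surveys.csv"), na = "")
  readr::write_csv(sim$validation, file.path(dir, "validation.csv"), na = "")
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  write_ecoregions(sim$ecoregions, file.path(dir, "ecoregions.geojson"))
  yaml::write_yaml(unclass(config), file.path(dir, "config.yml"))
  invisible(dir)
}
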
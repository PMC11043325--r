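#' Density model specification
#'
#' Settings for the Gamma/log-link penalized-spline model of corrected
#' biomass density: thin-plate smooths of reservoir age and sampling year,
#' a separate age smooth per reservoir class (factor-smooth interaction),
#' and a per-reservoir random-intercept smooth, with REML smoothness
#' selection.
#'
#' @param k_basis spline basis dimension (default 10).
#' @param min_class_n minimum surveys a class needs to stay in the model
#'   (default 5).
#' @param standardization_year common prediction year (default 1993).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(k_basis = 10L, min_class_n = 5L,
                       standardization_year = 1993L) {
  stopifnot(k_basis >= 3, min_class_n >= 1)
  structure(list(k_basis = as.integer(k_basis),
                 min_class_n = as.integer(min_class_n),
                 standardization_year = as.integer(standardization_year)),
            class = "model_spec")
}

#' Prepare the model table
#'
#' Joins class assignments onto linked surveys and applies the exclusion
#' rules: rows with missing age (including negative-age flags), missing
#' sampling year, missing/`"unclassified"` class, or non-positive density
#' (outside Gamma support) are removed with itemized reasons; classes left
#' with fewer than `min_class_n` rows are then removed entirely.
#'
#' @param linked linked surveys from [link_surveys()] (`$linked`).
#' @param assignments schema assignments from [assign_schema()].
#' @param spec a [model_spec()].
#' @return list with `table` (model-ready tibble) and `report` (named
#'   exclusion counts).
#' @export
prepare_model_table <- function(linked, assignments, spec = model_spec()) {
  tab <- linked
  tab$class_label <- assignments$class_label[
    match(tab$reservoir_id, assignments$reservoir_id)]
  report <- c(missing_age = 0L, missing_year = 0L, missing_class = 0L,
              nonpositive_density = 0L, small_class = 0L)

  bad_age <- is.na(tab$reservoir_age)
  report[["missing_age"]] <- sum(bad_age)
  tab <- tab[!bad_age, , drop = FALSE]

  bad_year <- is.na(tab$year_sampled)
  report[["missing_year"]] <- sum(bad_year)
  tab <- tab[!bad_year, , drop = FALSE]

  bad_class <- is.na(tab$class_label) | tab$class_label == "unclassified"
  report[["missing_class"]] <- sum(bad_class)
  tab <- tab[!bad_class, , drop = FALSE]

  bad_dens <- is.na(tab$corrected_density) | tab$corrected_density <= 0
  report[["nonpositive_density"]] <- sum(bad_dens)
  tab <- tab[!bad_dens, , drop = FALSE]

  counts <- table(tab$class_label)
  small <- names(counts)[counts < spec$min_class_n]
  report[["small_class"]] <- sum(tab$class_label %in% small)
  tab <- tab[!tab$class_label %in% small, , drop = FALSE]

  if (nrow(tab) == 0) {
    stop("estimation error: no survey rows left after exclusions",
         call. = FALSE)
  }
  list(table = tab, report = as.list(report))
}

#' Fit the Gamma/log-link GAMM of density on age and year
#'
#' Fits `corrected_density ~ s(age) + s(year) + class + s(age, by = class)
#' + s(reservoir, bs = "re")` with `mgcv::gam`, Gamma family, log link,
#' REML smoothness selection. Terms degenerate gracefully: the by-class
#' smooths and class effect are dropped with a single class, the random
#' intercept with a single reservoir, and a smooth falls back to a linear
#' term when its covariate has too few distinct values. With
#' `smooth = FALSE` all terms enter linearly, giving the Gamma GLM limit
#' of the model.
#'
#' @param table model table from [prepare_model_table()].
#' @param spec a [model_spec()].
#' @param smooth use penalized smooths (default) or linear terms only.
#' @return object of class `density_fit` supporting [predict_density()].
#' @export
fit_density_gamm <- function(table, spec = model_spec(), smooth = TRUE) {
  dat <- data.frame(
    y = table$corrected_density,
    age = as.numeric(table$reservoir_age),
    year_sampled = as.numeric(table$year_sampled),
    class_label = factor(table$class_label),
    reservoir_id = factor(table$reservoir_id))
  n_class <- nlevels(dat$class_label)
  n_res <- nlevels(dat$reservoir_id)
  ka <- min(spec$k_basis, length(unique(dat$age)) - 1L)
  ky <- min(spec$k_basis, length(unique(dat$year_sampled)) - 1L)

  terms <- character(0)
  if (smooth && ka >= 3) {
    terms <- c(terms, sprintf("s(age, k = %d, bs = 'tp')", ka))
  } else if (length(unique(dat$age)) > 1) {
    terms <- c(terms, "age")
  }
  if (smooth && ky >= 3) {
    terms <- c(terms, sprintf("s(year_sampled, k = %d, bs = 'tp')", ky))
  } else if (length(unique(dat$year_sampled)) > 1) {
    terms <- c(terms, "year_sampled")
  }
  if (n_class >= 2) {
    terms <- c(terms, "class_label")
    if (smooth && ka >= 3) {
      terms <- c(terms,
                 sprintf("s(age, by = class_label, k = %d, bs = 'tp')", ka))
    }
  }
  if (n_res >= 2) {
    terms <- c(terms, "s(reservoir_id, bs = 're')")
  }
  if (length(terms) == 0) terms <- "1"
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))

  gam_try <- function(method) {
    tryCatch(
      suppressWarnings(mgcv::gam(form, family = stats::Gamma(link = "log"),
                                 data = dat, method = method)),
      error = function(e) NULL)
  }
  # a (near-)perfect fit can trip the REML convergence flag even though
  # the solution is exact; accept it, and fall back to GCV smoothness
  # selection when the REML surface degenerates entirely
  fit_ok <- function(f) {
    !is.null(f) && (isTRUE(f$converged) ||
                      f$deviance <= 1e-6 * max(f$null.deviance, 1e-12))
  }
  fit <- gam_try("REML")
  if (!fit_ok(fit)) {
    fit <- gam_try("GCV.Cp")
  }
  if (!fit_ok(fit)) {
    stop("estimation error: GAMM did not converge",
         if (!is.null(fit)) paste0(" (deviance = ", signif(fit$deviance, 6),
                                   ")"),
         call. = FALSE)
  }
  reservoirs <- dplyr::distinct(
    tibble::tibble(reservoir_id = table$reservoir_id,
                   year_completed = table$year_completed,
                   class_label = table$class_label))
  structure(list(
    gam = fit, spec = spec, smooth = smooth,
    classes = levels(dat$class_label),
    reservoirs = reservoirs,
    last_year = max(dat$year_sampled),
    deviance_explained =
      (fit$null.deviance - fit$deviance) / fit$null.deviance),
    class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat("Gamma/log-link density GAMM:", length(x$classes), "class(es),",
      nrow(x$reservoirs), "sampled reservoir(s)\n")
  cat(sprintf("  deviance explained: %.1f%%\n", 100 * x$deviance_explained))
  invisible(x)
}

# factor levels of the reservoir random effect, or the known reservoir
# ids when the fit has no random-intercept term (single reservoir)
reservoir_levels <- function(fit) {
  lv <- levels(fit$gam$model$reservoir_id)
  if (is.null(lv)) unique(fit$reservoirs$reservoir_id) else lv
}

has_re_term <- function(fit) {
  any(vapply(fit$gam$smooth, `[[`, "", "label") == "s(reservoir_id)")
}

# Age covariate at a prediction year: the year (trend) term advances to
# the target year, but the age smooths are never evaluated beyond the
# span of the final empirical year — extrapolating a penalized spline
# outside its support is unstable, and post-impoundment age effects have
# dissipated at these ages anyway.
prediction_age <- function(fit, year, year_completed) {
  as.numeric(pmin(year, fit$last_year) - year_completed)
}

# Vectorized prediction for sampled reservoirs (their own random
# intercepts included), at the given calendar year.
predict_sampled <- function(fit, year) {
  res <- fit$reservoirs
  nd <- data.frame(
    age = prediction_age(fit, year, res$year_completed),
    year_sampled = as.numeric(year),
    class_label = factor(res$class_label, levels = fit$classes),
    reservoir_id = factor(res$reservoir_id, levels = reservoir_levels(fit)))
  eta <- as.numeric(mgcv::predict.gam(fit$gam, newdata = nd, type = "link"))
  tibble::tibble(reservoir_id = res$reservoir_id,
                 class_label = res$class_label,
                 density = exp(eta))
}

#' Predict density for a class or a sampled reservoir
#'
#' For a sampled reservoir (known to the fit) the prediction includes its
#' own random intercept; for a class-level (population) prediction the
#' random intercept is excluded and age is evaluated at the class mean
#' age trajectory. When standardizing beyond the final empirical year the
#' year term advances to the target year while the age smooths are
#' evaluated at the final empirical year's ages (penalized splines are
#' not extrapolated outside their support).
#'
#' @param fit a `density_fit`.
#' @param class_label class, must be known to the fit.
#' @param reservoir_id optional sampled reservoir id.
#' @param year calendar year.
#' @return predicted density (kg ha^-1), strictly positive.
#' @export
predict_density <- function(fit, class_label, reservoir_id = NULL,
                            year = fit$spec$standardization_year) {
  if (!class_label %in% fit$classes) {
    stop("lookup error: class '", class_label, "' unknown to the fit",
         call. = FALSE)
  }
  res_levels <- reservoir_levels(fit)
  if (!is.null(reservoir_id)) {
    i <- match(reservoir_id, fit$reservoirs$reservoir_id)
    if (is.na(i)) {
      stop("lookup error: reservoir '", reservoir_id,
           "' was not in the fitted data", call. = FALSE)
    }
    nd <- data.frame(
      age = prediction_age(fit, year, fit$reservoirs$year_completed[i]),
      year_sampled = as.numeric(year),
      class_label = factor(class_label, levels = fit$classes),
      reservoir_id = factor(reservoir_id, levels = res_levels))
    eta <- mgcv::predict.gam(fit$gam, newdata = nd, type = "link")
    return(unname(exp(as.numeric(eta))))
  }
  in_class <- fit$reservoirs$class_label == class_label
  mean_age <- mean(prediction_age(
    fit, year, fit$reservoirs$year_completed[in_class]))
  nd <- data.frame(
    age = as.numeric(mean_age), year_sampled = as.numeric(year),
    class_label = factor(class_label, levels = fit$classes),
    reservoir_id = factor(res_levels[1], levels = res_levels))
  eta <- mgcv::predict.gam(fit$gam, newdata = nd, type = "link",
                           exclude = if (has_re_term(fit)) "s(reservoir_id)")
  unname(exp(as.numeric(eta)))
}

#' Class mean densities at the standardization year
#'
#' Per class, the arithmetic mean of the per-sampled-reservoir predicted
#' densities (random intercepts included) at the given year. Classes
#' dropped before fitting are absent from the map.
#'
#' @param fit a `density_fit`.
#' @param year calendar year (default: the spec's standardization year).
#' @return named numeric vector, class -> kg ha^-1.
#' @export
class_mean_density <- function(fit, year = fit$spec$standardization_year) {
  pred <- predict_sampled(fit, year)
  out <- tapply(pred$density, pred$class_label, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Mean predicted density across all sampled reservoirs
#'
#' The fallback density assigned to reservoirs in classes with no surveys.
#'
#' @inheritParams class_mean_density
#' @return a single density (kg ha^-1).
#' @export
global_mean_density <- function(fit, year = fit$spec$standardization_year) {
  mean(predict_sampled(fit, year)$density)
}
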
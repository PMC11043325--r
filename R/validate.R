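#' Mixed-effects calibration of observed against predicted standing stock
#'
#' Regresses `ln(observed)` on `ln(predicted)` with a random intercept for
#' the grouping factor (the classification schema that produced each
#' prediction), fitted by REML with `lme4::lmer`. Reports the calibration
#' slope with a Wald test against the ideal slope of 1, Nakagawa-style
#' marginal and conditional pseudo-R^2, and the standardized-major-axis
#' slope as a robustness companion. A single group degenerates to ordinary
#' least squares with a warning.
#'
#' Standing stocks span orders of magnitude, so the regression is on the
#' log-log scale by default; `log_scale = FALSE` switches to the raw
#' scale.
#'
#' @param observed observed standing stock (kg), positive.
#' @param predicted predicted standing stock (kg), positive.
#' @param group grouping factor (e.g. schema label).
#' @param log_scale regress on ln-ln scale (default TRUE).
#' @return object of class `calibration_result`: slope, intercept,
#'   slope_se, Wald statistic and p-value for slope = 1, variance
#'   components, R2 marginal/conditional, and the SMA slope.
#' @export
fit_mixed_calibration <- function(observed, predicted, group,
                                  log_scale = TRUE) {
  if (length(observed) < 3) {
    stop("input error: need at least 3 observation pairs", call. = FALSE)
  }
  if (log_scale && (any(observed <= 0) || any(predicted <= 0))) {
    stop("domain error: log-scale calibration needs positive values",
         call. = FALSE)
  }
  y <- if (log_scale) log(observed) else observed
  x <- if (log_scale) log(predicted) else predicted
  group <- factor(group)
  dat <- data.frame(y = y, x = x, group = group)

  if (nlevels(group) < 2) {
    warning("single group: random effect degenerate, reducing to OLS",
            call. = FALSE)
    fit <- stats::lm(y ~ x, data = dat)
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
    var_f <- stats::var(stats::fitted(fit)) * (length(y) - 1) / length(y)
    var_r <- 0
    var_e <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | group), data = dat, REML = TRUE)))
    beta <- lme4::fixef(fit)
    # vcov can fail on an exactly singular (perfect) fit; recover the
    # fixed-effect covariance from the residual scale directly
    vc <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                   error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc))) {
      Xf <- lme4::getME(fit, "X")
      vc <- stats::sigma(fit)^2 * solve(crossprod(Xf))
    }
    vcs <- as.data.frame(lme4::VarCorr(fit))
    var_r <- vcs$vcov[vcs$grp == "group"]
    var_e <- vcs$vcov[vcs$grp == "Residual"]
    eta <- as.numeric(stats::model.matrix(fit) %*% beta)
    var_f <- stats::var(eta) * (length(y) - 1) / length(y)
  }
  slope <- unname(beta[2])
  slope_se <- sqrt(vc[2, 2])
  z <- if (slope_se > 0) {
    (slope - 1) / slope_se
  } else if (abs(slope - 1) < 1e-10) 0 else Inf
  r2 <- conditional_r2(var_f, var_r, var_e)
  structure(list(
    slope = slope, intercept = unname(beta[1]), slope_se = slope_se,
    slope_test = list(statistic = z, p_value = 2 * stats::pnorm(-abs(z))),
    var_fixed = var_f, var_random = var_r, var_residual = var_e,
    r2_marginal = r2[["r2_marginal"]],
    r2_conditional = r2[["r2_conditional"]],
    sma_slope = sma_slope(x, y),
    n = length(y), n_groups = nlevels(group), log_scale = log_scale),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration (n = %d, %d group(s), %s scale):\n", x$n, x$n_groups,
    if (x$log_scale) "ln-ln" else "raw"))
  cat(sprintf("  slope %.3f (SE %.3f), test vs 1: z = %.2f, p = %.3g\n",
              x$slope, x$slope_se, x$slope_test$statistic,
              x$slope_test$p_value))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f; SMA slope %.3f\n",
              x$r2_marginal, x$r2_conditional, x$sma_slope))
  invisible(x)
}

#' Marginal and conditional pseudo-R-squared from variance components
#'
#' `R2_marginal = var_f / (var_f + var_r + var_e)` (fixed effects only);
#' `R2_conditional = (var_f + var_r) / (var_f + var_r + var_e)` (fixed
#' plus random).
#'
#' @param var_fixed variance of the fixed-effect linear predictor.
#' @param var_random random-effect variance.
#' @param var_residual residual variance.
#' @return named numeric `r2_marginal`, `r2_conditional`.
#' @export
conditional_r2 <- function(var_fixed, var_random, var_residual) {
  if (any(c(var_fixed, var_random, var_residual) < 0)) {
    stop("domain error: variance components must be >= 0", call. = FALSE)
  }
  total <- var_fixed + var_random + var_residual
  if (total == 0) {
    stop("domain error: all variance components are zero", call. = FALSE)
  }
  c(r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + var_random) / total)
}

#' Standardized-major-axis slope
#'
#' `sign(cor(x, y)) * sd(y) / sd(x)`; with zero correlation the sign is
#' undefined and the positive slope is returned with a warning.
#'
#' @param x,y numeric vectors with positive spread.
#' @return the SMA slope.
#' @export
sma_slope <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    stop("domain error: sma_slope needs sd(x) > 0 and sd(y) > 0",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  s <- sign(r)
  if (s == 0) {
    warning("zero correlation: SMA slope sign undefined, returning positive",
            call. = FALSE)
    s <- 1
  }
  s * sy / sx
}
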
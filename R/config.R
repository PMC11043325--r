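#' Simulation configuration
#'
#' Parameters of the synthetic dam-inventory and rotenone-survey generator.
#' The generator draws `ln(volume)` and `ln(discharge)` jointly normal with
#' per-ecoregion mean shifts, derives surface area from a power law
#' `area_ha = a * volume^b * exp(noise)`, and produces survey biomass
#' densities from a class-specific intercept, a reservoir-age "trophic
#' upsurge" curve `alpha * age * exp(-age / tau)`, a sampling-year trend,
#' a per-reservoir random intercept, and multiplicative Gamma noise.
#' Recorded raw densities are the true densities divided by the recovery
#' constant, emulating incomplete recovery of fish in poisoning surveys.
#'
#' @param seed integer root seed; each output table draws from its own
#'   child stream so adding reservoirs does not perturb survey draws.
#' @param n_reservoirs number of inventory rows to generate (including the
#'   injected duplicate-dam and natural-lake rows).
#' @param n_ecoregions number of synthetic ecoregions, laid out as a square
#'   tiling of the bounding box.
#' @param ln_volume_mean,ln_volume_sd mean and sd of `ln(storage volume)`,
#'   volume in m^3.
#' @param ln_discharge_mean,ln_discharge_sd mean and sd of
#'   `ln(maximum discharge)`, discharge in m^3 s^-1.
#' @param vol_discharge_cor correlation of `ln(volume)` and `ln(discharge)`.
#' @param ecoregion_sd sd of the per-ecoregion shift added to both log
#'   covariate means.
#' @param area_coeff,area_exponent,area_noise_sd power-law parameters of
#'   the surface-area relation `area_ha = a * V^b * exp(N(0, sd))`.
#' @param density_intercept_per_class expected baseline density (kg ha^-1)
#'   for the four latent reservoir classes, ordered
#'   small-low, small-high, large-low, large-high.
#' @param age_amplitude,age_timescale amplitude (log scale, per year) and
#'   timescale (years) of the age curve `alpha * age * exp(-age / tau)`.
#' @param year_trend_slope log-scale trend per sampling year.
#' @param random_intercept_sd sd of the per-reservoir log-scale random
#'   intercept.
#' @param gamma_shape shape of the multiplicative Gamma(shape, scale =
#'   1/shape) observation noise (mean 1, CV `1/sqrt(shape)`).
#' @param recovery_constant divisor applied to true densities to produce
#'   the recorded (under-recovered) raw densities; default 1.773056.
#' @param survey_fraction fraction of (unique, non-lake) reservoirs that
#'   receive rotenone surveys.
#' @param surveys_per_reservoir surveys per sampled reservoir (distinct
#'   years).
#' @param year_range sampling-year range (calendar years).
#' @param year_completed_range dam completion-year range.
#' @param standardization_year common prediction year for ground truth.
#' @param prop_missing_area,prop_missing_coords,prop_missing_discharge
#'   fractions of rows whose area / coordinates / discharge are blanked
#'   missing-completely-at-random, exercising the cleaning and
#'   approximation paths.
#' @param prop_duplicate fraction of rows that are second-dam duplicates of
#'   another reservoir (same name and state, smaller dam).
#' @param prop_natural_lake fraction of rows that are flagged natural lakes
#'   with very large areas, to exercise the exclusion rule.
#' @param n_validation number of independent validation surveys.
#' @param validation_error_sd log-scale sd of validation observation error.
#' @param bbox bounding box `c(lon_min, lon_max, lat_min, lat_max)` tiled
#'   by the synthetic ecoregions.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_reservoirs = 2000L,
                              n_ecoregions = 6L,
                              ln_volume_mean = 12,
                              ln_volume_sd = 2,
                              ln_discharge_mean = 1,
                              ln_discharge_sd = 1.5,
                              vol_discharge_cor = 0.7,
                              ecoregion_sd = 0.5,
                              area_coeff = 1e-4,
                              area_exponent = 0.9,
                              area_noise_sd = 0.3,
                              density_intercept_per_class =
                                c(small_low = 150, small_high = 250,
                                  large_low = 350, large_high = 500),
                              age_amplitude = 0.08,
                              age_timescale = 12,
                              year_trend_slope = 0.004,
                              random_intercept_sd = 0.4,
                              gamma_shape = 20,
                              recovery_constant = 1.773056,
                              survey_fraction = 0.15,
                              surveys_per_reservoir = 4L,
                              year_range = c(1948L, 1978L),
                              year_completed_range = c(1900L, 1975L),
                              standardization_year = 1993L,
                              prop_missing_area = 0.05,
                              prop_missing_coords = 0.03,
                              prop_missing_discharge = 0.05,
                              prop_duplicate = 0.02,
                              prop_natural_lake = 0.005,
                              n_validation = 42L,
                              validation_error_sd = 0.1,
                              bbox = c(-100, -80, 30, 45)) {
  cfg <- list(
    seed = as.integer(seed), n_reservoirs = as.integer(n_reservoirs),
    n_ecoregions = as.integer(n_ecoregions),
    ln_volume_mean = ln_volume_mean, ln_volume_sd = ln_volume_sd,
    ln_discharge_mean = ln_discharge_mean, ln_discharge_sd = ln_discharge_sd,
    vol_discharge_cor = vol_discharge_cor, ecoregion_sd = ecoregion_sd,
    area_coeff = area_coeff, area_exponent = area_exponent,
    area_noise_sd = area_noise_sd,
    density_intercept_per_class = density_intercept_per_class,
    age_amplitude = age_amplitude, age_timescale = age_timescale,
    year_trend_slope = year_trend_slope,
    random_intercept_sd = random_intercept_sd,
    gamma_shape = gamma_shape, recovery_constant = recovery_constant,
    survey_fraction = survey_fraction,
    surveys_per_reservoir = as.integer(surveys_per_reservoir),
    year_range = as.integer(year_range),
    year_completed_range = as.integer(year_completed_range),
    standardization_year = as.integer(standardization_year),
    prop_missing_area = prop_missing_area,
    prop_missing_coords = prop_missing_coords,
    prop_missing_discharge = prop_missing_discharge,
    prop_duplicate = prop_duplicate,
    prop_natural_lake = prop_natural_lake,
    n_validation = as.integer(n_validation),
    validation_error_sd = validation_error_sd,
    bbox = bbox
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  sds <- c(cfg$ln_volume_sd, cfg$ln_discharge_sd, cfg$ecoregion_sd,
           cfg$area_noise_sd, cfg$random_intercept_sd,
           cfg$validation_error_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("configuration error: all standard deviations must be finite and >= 0",
         call. = FALSE)
  }
  if (cfg$n_reservoirs < 0) {
    stop("configuration error: n_reservoirs must be >= 0", call. = FALSE)
  }
  if (cfg$gamma_shape <= 0) {
    stop("configuration error: gamma_shape must be > 0", call. = FALSE)
  }
  if (cfg$recovery_constant < 1) {
    stop("configuration error: recovery_constant must be >= 1", call. = FALSE)
  }
  if (abs(cfg$vol_discharge_cor) > 1) {
    stop("configuration error: vol_discharge_cor must lie in [-1, 1]",
         call. = FALSE)
  }
  if (cfg$survey_fraction < 0 || cfg$survey_fraction > 1) {
    stop("configuration error: survey_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (length(cfg$density_intercept_per_class) != 4 ||
      any(cfg$density_intercept_per_class <= 0)) {
    stop("configuration error: density_intercept_per_class must be 4 positive values",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Pipeline configuration
#'
#' Bundles the constants of the estimation pipeline: the rotenone recovery
#' correction, the standardization year, the classification and model
#' settings, the production-to-biomass (P/B) parameters, the southern-region
#' state list, and (optionally) file paths for externally supplied inputs.
#' When paths are `NULL` the pipeline generates synthetic inputs from
#' `$simulation`.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param schemas classification schema ids to run, a subset of `1:5`.
#' @param recovery_constant multiplicative recovery correction
#'   (default 1.773056).
#' @param standardization_year year all densities are standardized to
#'   (default 1993).
#' @param k_clusters clusters per ecoregion in the eco-size-flow schema
#'   (default 4).
#' @param min_class_n minimum surveys per class retained in the model
#'   (default 5).
#' @param k_basis spline basis dimension for the age and year smooths.
#' @param pb_mean,pb_q25,pb_q75 production-to-biomass ratio (y^-1): point
#'   value and interquartile range for whole fish communities.
#' @param southern_states two-letter codes defining the survey-rich
#'   southern region; defaults to the 22 states with legacy rotenone data.
#' @param paths named list of input paths (`inventory`, `surveys`,
#'   `ecoregions`, `validation`), each `NULL` to synthesize instead.
#' @param simulation a [simulation_config()] used when paths are `NULL`.
#'
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            schemas = 1:5,
                            recovery_constant = 1.773056,
                            standardization_year = 1993L,
                            k_clusters = 4L,
                            min_class_n = 5L,
                            k_basis = 10L,
                            pb_mean = 1.30,
                            pb_q25 = 0.583,
                            pb_q75 = 1.823,
                            southern_states = c(
                              "AL", "AR", "FL", "GA", "IA", "IL", "IN", "KS",
                              "KY", "LA", "MA", "MD", "MO", "MS", "NC", "NM",
                              "OK", "SC", "TN", "TX", "VA", "WV"),
                            paths = list(inventory = NULL, surveys = NULL,
                                         ecoregions = NULL, validation = NULL),
                            simulation = simulation_config(seed = seed)) {
  if (length(schemas) == 0 || !all(schemas %in% 1:5)) {
    stop("configuration error: schemas must be a non-empty subset of 1:5",
         call. = FALSE)
  }
  stopifnot(recovery_constant >= 1, k_clusters >= 2, min_class_n >= 1,
            k_basis >= 3, pb_mean > 0, pb_q25 > 0, pb_q75 > 0,
            pb_q25 <= pb_q75)
  cfg <- list(
    seed = as.integer(seed), schemas = as.integer(schemas),
    recovery_constant = recovery_constant,
    standardization_year = as.integer(standardization_year),
    k_clusters = as.integer(k_clusters),
    min_class_n = as.integer(min_class_n),
    k_basis = as.integer(k_basis),
    pb = c(mean = pb_mean, q25 = pb_q25, q75 = pb_q75),
    southern_states = southern_states,
    paths = paths,
    simulation = simulation
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  x$pb <- as.list(x$pb)  # keep names through YAML
  x$simulation$density_intercept_per_class <-
    as.list(x$simulation$density_intercept_per_class)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulation$density_intercept_per_class)) {
    x$simulation$density_intercept_per_class <-
      unlist(x$simulation$density_intercept_per_class)
  }
  sim <- do.call(simulation_config, utils::modifyList(
    list(), x$simulation[names(x$simulation) %in%
                           names(formals(simulation_config))]))
  args <- x[names(x) %in% names(formals(pipeline_config))]
  args$simulation <- sim
  if (!is.null(x$pb)) {
    args$pb_mean <- x$pb[["mean"]]; args$pb_q25 <- x$pb[["q25"]]
    args$pb_q75 <- x$pb[["q75"]]; args$pb <- NULL
  }
  do.call(pipeline_config, args)
}

# Child RNG streams: one root seed, deterministic offsets per table, so
# e.g. enlarging the inventory never perturbs the survey draws.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * stream) %% 2147483647)
}

with_child_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(child_seed(seed, stream))
  expr
}

# Case-folded, punctuation- and whitespace-stripped name key used for
# duplicate-dam collapse and survey-to-inventory name matching.
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]", "", x)
  gsub("[[:space:]]+", " ", x)
}
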
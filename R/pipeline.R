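stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full estimation pipeline
#'
#' Orchestrates, deterministically for a given seed:
#' clean inventory -> approximate missing areas -> ecoregion spatial join
#' -> link + recovery-correct surveys -> per schema: classify, fit the
#' Gamma/log GAMM, predict at the standardization year, impute densities
#' to every reservoir, scale up by surface area -> aggregate totals by
#' state / ecoregion / region / nation -> ensemble mean and SE across
#' schemas -> production via P/B ratios -> mixed-effects calibration
#' against independent validation surveys.
#'
#' Inputs come from `config$paths` when set; with all paths `NULL` a
#' synthetic dataset is generated from `config$simulation` (whose ground
#' truth is then attached to the report for recovery checks). When any
#' path is supplied, `inventory`, `surveys`, and `ecoregions` are all
#' required; `validation` stays optional.
#'
#' @param config a [pipeline_config()].
#' @return object of class `resstock_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  external <- !all(vapply(p, is.null, logical(1)))
  if (external) {
    for (need in c("inventory", "surveys", "ecoregions")) {
      if (is.null(p[[need]])) {
        stop(sprintf("[stage %s] configuration error: path '%s' is required",
                     need, need), call. = FALSE)
      }
    }
    inventory <- stage("inventory", load_inventory(p$inventory))
    surveys <- stage("surveys", load_surveys(p$surveys))
    ecoregions <- stage("ecoregions", read_ecoregions(p$ecoregions))
    validation <- if (!is.null(p$validation)) {
      stage("validation", readr::read_csv(
        p$validation, col_types = readr::cols(
          reservoir_id = "c", observed_kg = "d"), progress = FALSE))
    }
    truth <- NULL
  } else {
    sim <- stage("simulate", simulate_dataset(config$simulation))
    inventory <- sim$inventory
    surveys <- sim$surveys
    ecoregions <- sim$ecoregions
    validation <- sim$validation
    truth <- sim$truth
  }

  cleaned <- stage("clean", clean_inventory(inventory))
  records <- stage("area", approximate_missing_area(cleaned$records))
  records <- stage("ecoregion_join", assign_ecoregion(records, ecoregions))
  link <- stage("link", link_surveys(surveys, records,
                                     constant = config$recovery_constant))
  spec <- model_spec(k_basis = config$k_basis,
                     min_class_n = config$min_class_n,
                     standardization_year = config$standardization_year)

  schema_runs <- list()
  for (s in config$schemas) {
    nm <- as.character(s)
    assignments <- stage(paste0("classify_", nm),
                         assign_schema(records, s, seed = config$seed,
                                       k = config$k_clusters))
    prep <- stage(paste0("prepare_", nm),
                  prepare_model_table(link$linked, assignments, spec))
    fit <- stage(paste0("fit_", nm), fit_density_gamm(prep$table, spec))
    dens <- stage(paste0("impute_", nm),
                  impute_densities(records, assignments, fit))
    st <- stage(paste0("scaleup_", nm), stock_table(records, dens, s))
    schema_runs[[nm]] <- list(
      schema_id = s, assignments = assignments,
      exclusions = prep$report, fit = fit, stock = st,
      usa_total = sum(st$standing_stock_kg),
      southern_total = sum(st$standing_stock_kg[
        !is.na(st$state) & st$state %in% config$southern_states]),
      by_state = aggregate_stock(st, "state",
                                 southern_states = config$southern_states),
      by_ecoregion = aggregate_stock(st, "ecoregion",
                                     southern_states = config$southern_states))
  }

  usa_totals <- vapply(schema_runs, function(r) r$usa_total, numeric(1))
  southern_totals <- vapply(schema_runs, function(r) r$southern_total,
                            numeric(1))
  ensemble <- if (length(usa_totals) >= 2) {
    list(usa = ensemble_across_schemas(usa_totals),
         southern = ensemble_across_schemas(southern_totals))
  } else {
    list(usa = list(totals = usa_totals, mean = usa_totals[[1]], se = NA_real_,
                    n = 1L),
         southern = list(totals = southern_totals,
                         mean = southern_totals[[1]], se = NA_real_, n = 1L))
  }
  production <- stage("production", list(
    usa = production_from_biomass(ensemble$usa$mean, config$pb),
    usa_range = range(production_from_biomass(usa_totals,
                                              config$pb)$production_kg_y),
    southern = production_from_biomass(ensemble$southern$mean, config$pb),
    southern_range = range(production_from_biomass(
      southern_totals, config$pb)$production_kg_y)))

  calibration <- NULL
  if (!is.null(validation) && nrow(validation) >= 3) {
    obs <- pred <- grp <- list()
    for (nm in names(schema_runs)) {
      st <- schema_runs[[nm]]$stock
      i <- match(validation$reservoir_id, st$reservoir_id)
      ok <- !is.na(i)
      obs[[nm]] <- validation$observed_kg[ok]
      pred[[nm]] <- st$standing_stock_kg[i[ok]]
      grp[[nm]] <- rep(paste0("schema_", nm), sum(ok))
    }
    obs <- unlist(obs); pred <- unlist(pred); grp <- unlist(grp)
    if (length(obs) >= 3) {
      calibration <- stage("validate", suppressWarnings(
        fit_mixed_calibration(obs, pred, grp)))
    }
  }

  report <- list(
    config = config,
    cleaning = cleaned$report,
    n_unassigned_ecoregion = attr(records, "n_unassigned"),
    n_unmatched_surveys = nrow(link$unmatched),
    schema_runs = schema_runs,
    totals = tibble::tibble(
      schema_id = as.integer(names(schema_runs)),
      southern_kg = unname(southern_totals),
      usa_kg = unname(usa_totals)),
    ensemble = ensemble,
    production = production,
    calibration = calibration,
    truth = truth,
    manifest = list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      n_inventory_in = cleaned$report$n_in,
      n_inventory_clean = cleaned$report$n_out,
      n_surveys = nrow(surveys),
      n_surveys_linked = if (is.null(link$linked)) 0L else nrow(link$linked),
      n_validation = if (is.null(validation)) 0L else nrow(validation),
      schemas = config$schemas))
  class(report) <- "resstock_report"
  report
}

#' @export
print.resstock_report <- function(x, ...) {
  cat("Reservoir fish standing stock report\n")
  cat(sprintf("  inventory: %d rows in, %d after cleaning\n",
              x$manifest$n_inventory_in, x$manifest$n_inventory_clean))
  cat(sprintf("  surveys linked: %d (unmatched %d)\n",
              x$manifest$n_surveys_linked, x$n_unmatched_surveys))
  cat("  per-schema totals (kg):\n")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("    schema %d: southern %.0f, USA %.0f\n",
                x$totals$schema_id[i], x$totals$southern_kg[i],
                x$totals$usa_kg[i]))
  }
  cat(sprintf("  ensemble USA: %.3g kg (SE %.3g); southern: %.3g kg (SE %.3g)\n",
              x$ensemble$usa$mean, x$ensemble$usa$se,
              x$ensemble$southern$mean, x$ensemble$southern$se))
  cat(sprintf("  USA production: %.3g kg/y (schema range %.3g-%.3g)\n",
              x$production$usa$production_kg_y,
              x$production$usa_range[1], x$production$usa_range[2]))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: slope %.3f, R2c %.3f\n",
                x$calibration$slope, x$calibration$r2_conditional))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes per-schema stock tables and state/ecoregion totals as CSV, a
#' JSON report mirroring the schema-by-region totals table with ensemble
#' mean/SE and the production line, and a manifest sufficient to re-run
#' identically.
#'
#' @param report a `resstock_report`.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "resstock_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$schema_runs)) {
    run <- report$schema_runs[[nm]]
    readr::write_csv(run$stock,
                     file.path(dir, sprintf("stock_schema%s.csv", nm)))
    readr::write_csv(run$by_state,
                     file.path(dir, sprintf("totals_state_schema%s.csv", nm)))
  }
  readr::write_csv(report$totals, file.path(dir, "totals_by_schema.csv"))
  json <- list(
    totals_by_schema = report$totals,
    ensemble = list(
      usa = report$ensemble$usa[c("mean", "se", "n")],
      southern = report$ensemble$southern[c("mean", "se", "n")]),
    production = list(
      usa = as.list(report$production$usa),
      usa_schema_range = report$production$usa_range,
      southern = as.list(report$production$southern),
      southern_schema_range = report$production$southern_range),
    calibration = if (!is.null(report$calibration)) {
      report$calibration[c("slope", "intercept", "slope_se", "r2_marginal",
                           "r2_conditional", "sma_slope", "n", "n_groups")]
    },
    cleaning = report$cleaning,
    manifest = report$manifest)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
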
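#' Impute a standardized density to every reservoir
#'
#' Sampled reservoirs keep their own model prediction (random intercept
#' included); unsampled reservoirs in a class with surveys receive the
#' class mean; reservoirs in classes with no surveys (including
#' `"unclassified"`) receive the mean predicted density across all sampled
#' reservoirs. The provenance of each density is recorded.
#'
#' @param inventory cleaned inventory tibble.
#' @param assignments schema assignments from [assign_schema()].
#' @param fit a `density_fit` for this schema.
#' @param year prediction year.
#' @return tibble `reservoir_id`, `class_label`, `density_kg_ha`, `source`
#'   in `{model, class_mean, global_mean}`.
#' @export
impute_densities <- function(inventory, assignments, fit,
                             year = fit$spec$standardization_year) {
  class_means <- class_mean_density(fit, year)
  global_mean <- global_mean_density(fit, year)
  cls <- assignments$class_label[
    match(inventory$reservoir_id, assignments$reservoir_id)]
  sampled <- predict_sampled(fit, year)
  own <- sampled$density[match(inventory$reservoir_id, sampled$reservoir_id)]
  by_class <- unname(class_means[cls])

  density <- ifelse(!is.na(own), own,
                    ifelse(!is.na(by_class), by_class, global_mean))
  source <- ifelse(!is.na(own), "model",
                   ifelse(!is.na(by_class), "class_mean", "global_mean"))
  tibble::tibble(reservoir_id = inventory$reservoir_id,
                 class_label = cls,
                 density_kg_ha = density, source = source)
}

#' Standing stock from density and surface area
#'
#' @param density density (kg ha^-1), >= 0.
#' @param area surface area (ha), > 0; cleaning guarantees presence.
#' @return standing stock (kg), `density * area`.
#' @export
standing_stock <- function(density, area) {
  if (any(is.na(density)) || any(density < 0)) {
    stop("domain error: density must be present and >= 0", call. = FALSE)
  }
  if (any(is.na(area)) || any(area <= 0)) {
    stop("invariant violation: surface area must be present and > 0 ",
         "(cleaning guarantees an area for every reservoir)", call. = FALSE)
  }
  density * area
}

#' Build a per-reservoir stock table for one schema
#'
#' @param inventory cleaned inventory (areas present).
#' @param densities output of [impute_densities()].
#' @param schema_id schema identifier recorded in the table.
#' @return tibble with density, area, standing stock, provenance, state,
#'   and ecoregion per reservoir.
#' @export
stock_table <- function(inventory, densities, schema_id) {
  stopifnot(nrow(inventory) == nrow(densities))
  tibble::tibble(
    reservoir_id = inventory$reservoir_id,
    schema_id = as.integer(schema_id),
    class_label = densities$class_label,
    state = inventory$state,
    ecoregion_l2 = if ("ecoregion_l2" %in% names(inventory)) {
      inventory$ecoregion_l2
    } else {
      NA_character_
    },
    density_kg_ha = densities$density_kg_ha,
    surface_area_ha = inventory$surface_area_ha,
    standing_stock_kg = standing_stock(densities$density_kg_ha,
                                       inventory$surface_area_ha),
    source = densities$source)
}

#' Aggregate standing stock
#'
#' Group sums of standing stock. Missing state/ecoregion rows aggregate
#' into an explicit `"unassigned"` bucket, so group totals always sum to
#' the national total.
#'
#' @param stock a [stock_table()].
#' @param by one of `"state"`, `"ecoregion"`, `"region"`, `"national"`.
#' @param southern_states state codes defining the southern region.
#' @return tibble `group`, `standing_stock_kg`.
#' @export
aggregate_stock <- function(stock, by = c("state", "ecoregion", "region",
                                          "national"),
                            southern_states = pipeline_config()$southern_states) {
  by <- match.arg(by)
  key <- switch(by,
    state = ifelse(is.na(stock$state), "unassigned", stock$state),
    ecoregion = ifelse(is.na(stock$ecoregion_l2), "unassigned",
                       stock$ecoregion_l2),
    region = ifelse(!is.na(stock$state) & stock$state %in% southern_states,
                    "southern", "other"),
    national = rep("USA", nrow(stock)))
  if (nrow(stock) == 0) {
    return(tibble::tibble(group = character(), standing_stock_kg = numeric()))
  }
  sums <- tapply(stock$standing_stock_kg, key, sum)
  tibble::tibble(group = names(sums), standing_stock_kg = as.numeric(sums))
}

#' Ensemble mean and standard error across classification schemas
#'
#' The five classification schemas give five alternative regional totals;
#' their arithmetic mean is the reported estimate and the standard error
#' of the mean (sample sd / sqrt(n)) the "across calculations"
#' uncertainty.
#'
#' @param totals numeric vector of per-schema totals (kg), length >= 2.
#' @return list `totals`, `mean`, `se`, `n`.
#' @export
ensemble_across_schemas <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 2 || any(!is.finite(totals))) {
    stop("input error: need >= 2 finite schema totals for an ensemble SE",
         call. = FALSE)
  }
  list(totals = totals, mean = mean(totals),
       se = stats::sd(totals) / sqrt(length(totals)), n = length(totals))
}

#' Production from standing stock via P/B ratios
#'
#' Secondary production is estimated as standing stock times a
#' literature assemblage-level production-to-biomass ratio, with an
#' interquartile production range from the P/B quartiles.
#'
#' @param biomass_kg standing stock (kg), >= 0 (vectorized).
#' @param pb named numeric `c(mean=, q25=, q75=)` of P/B values (y^-1).
#' @return tibble `production_kg_y`, `production_q25_kg_y`,
#'   `production_q75_kg_y`.
#' @export
production_from_biomass <- function(biomass_kg,
                                    pb = c(mean = 1.30, q25 = 0.583,
                                           q75 = 1.823)) {
  if (any(is.na(biomass_kg)) || any(biomass_kg < 0)) {
    stop("domain error: biomass must be >= 0", call. = FALSE)
  }
  stopifnot(all(pb > 0), pb[["q25"]] <= pb[["q75"]])
  tibble::tibble(
    production_kg_y = biomass_kg * pb[["mean"]],
    production_q25_kg_y = biomass_kg * pb[["q25"]],
    production_q75_kg_y = biomass_kg * pb[["q75"]])
}
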
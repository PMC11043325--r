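#' Published regional standing-stock totals by classification schema
#'
#' Reference values from the published national assessment of USA
#' reservoir fish standing stock: total standing stock (kg) for the
#' survey-rich southern region and for the contiguous USA under the five
#' classification schemas (simple average; large & small; size-flow;
#' ecoregion; eco-size-flow). These totals are the inputs to the ensemble
#' and production chains — their mean is the headline biomass estimate and
#' their spread the "across calculations" uncertainty.
#'
#' @return tibble with `schema_id`, `schema`, `southern_kg`, `usa_kg`.
#' @export
published_stock_totals <- function() {
  tibble::tibble(
    schema_id = 1:5,
    schema = c("simple average", "large & small", "size-flow",
               "ecoregion", "eco-size-flow"),
    southern_kg = c(1693346335, 2001994842, 1713033098,
                    2055598037, 2137464393),
    usa_kg = c(3031693257, 3587800617, 2976459235,
               3689453361, 3855651138))
}
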
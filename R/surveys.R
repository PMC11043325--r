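#' Load a rotenone survey CSV
#'
#' Canonical columns: `survey_id`, `reservoir_id`, `year_sampled`,
#' `raw_density_kg_ha` (renameable through `column_map`). Rows with
#' negative density are dropped row-wise; the count is returned in
#' attribute `"n_rejected"`. Sampling years outside `year_limits` are set
#' missing with a coercion count.
#'
#' @param path CSV file path.
#' @param column_map named character vector, `canonical = file_column`.
#' @param year_limits plausible sampling-year range.
#' @return tibble of survey records.
#' @export
load_surveys <- function(path, column_map = NULL,
                         year_limits = c(1900L, as.integer(
                           format(Sys.Date(), "%Y")))) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      file_col <- column_map[[canon]]
      if (!file_col %in% names(raw)) {
        stop("schema error: mapped column '", file_col, "' not in file",
             call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  if (!all(c("reservoir_id", "year_sampled", "raw_density_kg_ha") %in%
             names(raw))) {
    stop("schema error: surveys need reservoir_id, year_sampled, ",
         "raw_density_kg_ha", call. = FALSE)
  }
  if (!"survey_id" %in% names(raw)) {
    raw$survey_id <- sprintf("S%05d", seq_len(nrow(raw)))
  }
  raw$year_sampled <- suppressWarnings(as.integer(raw$year_sampled))
  bad_year <- !is.na(raw$year_sampled) &
    (raw$year_sampled < year_limits[1] | raw$year_sampled > year_limits[2])
  raw$year_sampled[bad_year] <- NA_integer_
  raw$raw_density_kg_ha <- suppressWarnings(as.numeric(raw$raw_density_kg_ha))
  neg <- !is.na(raw$raw_density_kg_ha) & raw$raw_density_kg_ha < 0
  out <- tibble::as_tibble(raw[!neg, , drop = FALSE])
  attr(out, "n_rejected") <- sum(neg)
  attr(out, "n_bad_year") <- sum(bad_year)
  out
}

#' Apply the rotenone recovery correction
#'
#' Rotenone surveys under-count biomass because not all poisoned fish are
#' recovered; published species recovery rates imply a multiplicative
#' correction, by default 1.773056.
#'
#' @param raw_density raw density (kg ha^-1), non-negative.
#' @param constant correction constant, >= 1.
#' @return corrected density `raw_density * constant`.
#' @export
apply_recovery_correction <- function(raw_density, constant = 1.773056) {
  if (any(raw_density < 0, na.rm = TRUE)) {
    stop("domain error: raw_density must be >= 0", call. = FALSE)
  }
  if (length(constant) != 1 || is.na(constant) || constant < 1) {
    stop("domain error: correction constant must be a single value >= 1",
         call. = FALSE)
  }
  raw_density * constant
}

#' Link surveys to cleaned inventory reservoirs
#'
#' Matches on `reservoir_id` first, then on the normalized name + state
#' key for surveys carrying `name`/`state` columns. Computes
#' `corrected_density` via [apply_recovery_correction()] and
#' `reservoir_age` = `year_sampled - year_completed`; surveys predating
#' completion keep a missing age and are flagged `negative_age` (they are
#' excluded later by model preparation, not deleted here). Unmatched
#' surveys are returned separately, never silently dropped.
#'
#' @param surveys tibble from [load_surveys()].
#' @param inventory cleaned inventory tibble.
#' @param constant recovery-correction constant.
#' @return list with `linked` (matched surveys + reservoir covariates) and
#'   `unmatched` (surveys with no inventory match).
#' @export
link_surveys <- function(surveys, inventory, constant = 1.773056) {
  inv <- inventory
  inv$.key <- paste(normalize_name(inv$name), normalize_name(inv$state),
                    sep = "|")
  id_idx <- match(surveys$reservoir_id, inv$reservoir_id)
  key_idx <- if (all(c("name", "state") %in% names(surveys))) {
    match(paste(normalize_name(surveys$name), normalize_name(surveys$state),
                sep = "|"), inv$.key)
  } else {
    rep(NA_integer_, nrow(surveys))
  }
  idx <- ifelse(is.na(id_idx), key_idx, id_idx)
  matched <- !is.na(idx)

  linked <- surveys[matched, , drop = FALSE]
  mi <- idx[matched]
  linked$reservoir_id <- inv$reservoir_id[mi]
  linked$year_completed <- inv$year_completed[mi]
  linked$surface_area_ha <- inv$surface_area_ha[mi]
  linked$ecoregion_l2 <- if ("ecoregion_l2" %in% names(inv)) {
    inv$ecoregion_l2[mi]
  } else {
    NA_character_
  }
  linked$corrected_density <- apply_recovery_correction(
    linked$raw_density_kg_ha, constant)
  age <- linked$year_sampled - linked$year_completed
  linked$negative_age <- !is.na(age) & age < 0
  age[linked$negative_age] <- NA_integer_
  linked$reservoir_age <- age

  list(linked = linked, unmatched = surveys[!matched, , drop = FALSE])
}
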
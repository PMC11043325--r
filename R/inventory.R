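#' Load a dam/reservoir inventory CSV
#'
#' Reads an inventory table into the canonical record layout. `column_map`
#' renames file columns to the canonical names
#' `reservoir_id, name, state, latitude, longitude, year_completed,
#' storage_volume_m3, max_discharge_m3s, surface_area_ha, natural_lake`;
#' by default the file is assumed to use them already. Unparseable numeric
#' cells become missing; the number coerced per column is returned in
#' attribute `"coercion_warnings"`.
#'
#' @param path CSV file path.
#' @param column_map named character vector, `canonical = file_column`.
#' @return tibble of reservoir records.
#' @export
load_inventory <- function(path, column_map = NULL) {
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
  if (!"reservoir_id" %in% names(raw)) {
    stop("schema error: mandatory column 'reservoir_id' absent", call. = FALSE)
  }
  num_cols <- c("latitude", "longitude", "year_completed",
                "storage_volume_m3", "max_discharge_m3s", "surface_area_ha")
  coercions <- integer(0)
  for (col in num_cols) {
    if (!col %in% names(raw)) {
      raw[[col]] <- NA_real_
      next
    }
    x <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- sum(is.na(x) & !is.na(raw[[col]]) & trimws(raw[[col]]) != "")
    if (n_bad > 0) coercions[[col]] <- n_bad
    raw[[col]] <- x
  }
  for (col in c("name", "state")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  raw$year_completed <- as.integer(raw$year_completed)
  raw$natural_lake <- if ("natural_lake" %in% names(raw)) {
    tolower(trimws(raw$natural_lake)) %in% c("true", "t", "1", "yes")
  } else {
    FALSE
  }
  bad_lat <- !is.na(raw$latitude) & abs(raw$latitude) > 90
  bad_lon <- !is.na(raw$longitude) & abs(raw$longitude) > 180
  raw$latitude[bad_lat] <- NA_real_
  raw$longitude[bad_lon] <- NA_real_
  if (any(bad_lat | bad_lon)) {
    coercions[["coordinates"]] <- sum(bad_lat | bad_lon)
  }
  out <- tibble::as_tibble(raw)
  attr(out, "coercion_warnings") <- coercions
  out
}

#' Clean an inventory: deduplicate, drop natural lakes, require a basis
#' for surface area
#'
#' Applies three rules, in order:
#' 1. rows sharing a reservoir identity key (case-folded,
#'    punctuation-stripped name + state; rows without a name key on their
#'    id) are collapsed to the single row with the largest storage volume;
#' 2. rows flagged `natural_lake`, or whose normalized name is on the
#'    exclusion list, are dropped (large natural lakes impounded by small
#'    dams are not reservoirs);
#' 3. rows with neither surface area nor storage volume are dropped — there
#'    is no basis for estimating their area.
#'
#' @param records inventory tibble from [load_inventory()] or
#'   [simulate_inventory()].
#' @param natural_lake_names names to exclude (normalized match); seeded
#'   with "Lake Superior".
#' @return list with `records` (cleaned tibble) and `report` (named counts:
#'   `duplicates`, `natural_lakes`, `no_area_basis`, `n_in`, `n_out`).
#' @export
clean_inventory <- function(records, natural_lake_names = "Lake Superior") {
  n_in <- nrow(records)
  if (n_in == 0) {
    return(list(records = records,
                report = list(duplicates = 0L, natural_lakes = 0L,
                              no_area_basis = 0L, n_in = 0L, n_out = 0L)))
  }
  key <- ifelse(!is.na(records$name) & trimws(records$name) != "",
                paste(normalize_name(records$name),
                      normalize_name(records$state), sep = "|"),
                paste0("#id:", records$reservoir_id))
  # keep the maximum-storage dam in each identity group (NA volume last,
  # ties broken by original row order)
  vol <- ifelse(is.na(records$storage_volume_m3), -Inf,
                records$storage_volume_m3)
  ord <- order(key, -vol, seq_len(n_in))
  keep_first <- !duplicated(key[ord])
  keep <- sort(seq_len(n_in)[ord][keep_first])
  n_dup <- n_in - length(keep)
  out <- records[keep, , drop = FALSE]

  excl <- normalize_name(natural_lake_names)
  is_lake <- out$natural_lake %in% TRUE | normalize_name(out$name) %in% excl
  n_lake <- sum(is_lake)
  out <- out[!is_lake, , drop = FALSE]

  no_basis <- is.na(out$surface_area_ha) & is.na(out$storage_volume_m3)
  n_nobasis <- sum(no_basis)
  out <- out[!no_basis, , drop = FALSE]

  list(records = out,
       report = list(duplicates = n_dup, natural_lakes = n_lake,
                     no_area_basis = n_nobasis,
                     n_in = n_in, n_out = nrow(out)))
}

#' Approximate missing surface areas from storage volume
#'
#' Fits ordinary least squares of `ln(area)` on `ln(volume)` over records
#' with both observed and predicts (back-transformed) areas for records
#' with volume but no area, setting the `area_approximated` flag. With
#' fewer than `min_complete` complete pairs the fallback is the median
#' area/volume ratio times volume. Observed areas are never modified.
#'
#' @param records cleaned inventory tibble.
#' @param min_complete minimum complete pairs for the regression
#'   (default 10).
#' @return records with areas filled and logical column `area_approximated`.
#' @export
approximate_missing_area <- function(records, min_complete = 10L) {
  if (!"area_approximated" %in% names(records)) {
    records$area_approximated <- FALSE
  }
  need <- is.na(records$surface_area_ha) & !is.na(records$storage_volume_m3)
  if (!any(need)) return(records)
  complete <- !is.na(records$surface_area_ha) &
    !is.na(records$storage_volume_m3) &
    records$surface_area_ha > 0 & records$storage_volume_m3 > 0
  if (!any(complete)) {
    stop("estimation error: no record has both surface area and volume",
         call. = FALSE)
  }
  if (sum(complete) >= min_complete) {
    fit <- stats::lm(log(surface_area_ha) ~ log(storage_volume_m3),
                     data = records[complete, , drop = FALSE])
    pred <- exp(stats::predict(fit, newdata = records[need, , drop = FALSE]))
  } else {
    ratio <- stats::median(records$surface_area_ha[complete] /
                             records$storage_volume_m3[complete])
    pred <- ratio * records$storage_volume_m3[need]
  }
  records$surface_area_ha[need] <- pred
  records$area_approximated[need] <- TRUE
  records
}

#' Assign ecoregions by point-in-polygon spatial join
#'
#' Each reservoir with coordinates is assigned the label of the first
#' polygon (in layer order) containing its point; points on a shared edge
#' therefore go to the first polygon, deterministically. Records without
#' coordinates or outside all polygons keep a missing ecoregion; their
#' count is returned in attribute `"n_unassigned"`.
#'
#' @param records inventory tibble with `latitude`/`longitude`.
#' @param polygons an `ecoregion_layer`.
#' @return records with column `ecoregion_l2` filled.
#' @export
assign_ecoregion <- function(records, polygons) {
  stopifnot(inherits(polygons, "ecoregion_layer"))
  if (length(polygons$labels) == 0) {
    stop("configuration error: empty polygon layer", call. = FALSE)
  }
  eco <- rep(NA_character_, nrow(records))
  has_xy <- !is.na(records$latitude) & !is.na(records$longitude)
  if (any(has_xy)) {
    pts <- cbind(records$longitude[has_xy], records$latitude[has_xy])
    assigned <- rep(NA_character_, nrow(pts))
    for (i in seq_along(polygons$labels)) {
      todo <- is.na(assigned)
      if (!any(todo)) break
      inside <- mgcv::in.out(polygons$rings[[i]], pts[todo, , drop = FALSE])
      assigned[todo][inside] <- polygons$labels[[i]]
    }
    eco[has_xy] <- assigned
  }
  records$ecoregion_l2 <- eco
  attr(records, "n_unassigned") <- sum(is.na(eco))
  records
}
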
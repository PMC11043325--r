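#' Ecoregion polygon layers
#'
#' A minimal polygon-layer container for the ecoregion spatial join: a list
#' with `labels` (character) and `rings` (list of two-column lon/lat
#' matrices, outer ring only, WGS84). Layers are read from and written to
#' GeoJSON FeatureCollections; `make_ecoregion_grid()` builds the synthetic
#' square tiling the data generator uses.
#'
#' @param n number of ecoregions to tile.
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param labels optional labels; defaults to `"E1"..."En"`.
#' @return an object of class `ecoregion_layer`.
#' @export
make_ecoregion_grid <- function(n, bbox = c(-100, -80, 30, 45),
                                labels = paste0("E", seq_len(n))) {
  stopifnot(n >= 1, length(bbox) == 4, length(labels) == n)
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  xs <- seq(bbox[1], bbox[2], length.out = nx + 1)
  ys <- seq(bbox[3], bbox[4], length.out = ny + 1)
  rings <- vector("list", n)
  for (i in seq_len(n)) {
    ix <- ((i - 1) %% nx) + 1
    iy <- ((i - 1) %/% nx) + 1
    rings[[i]] <- cbind(
      lon = c(xs[ix], xs[ix + 1], xs[ix + 1], xs[ix], xs[ix]),
      lat = c(ys[iy], ys[iy], ys[iy + 1], ys[iy + 1], ys[iy]))
  }
  structure(list(labels = labels, rings = rings), class = "ecoregion_layer")
}

#' @rdname make_ecoregion_grid
#' @param layer an `ecoregion_layer`.
#' @param path GeoJSON file path.
#' @export
write_ecoregions <- function(layer, path) {
  stopifnot(inherits(layer, "ecoregion_layer"))
  features <- lapply(seq_along(layer$labels), function(i) {
    ring <- layer$rings[[i]]
    coords <- lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))
    list(type = "Feature",
         properties = list(ecoregion = layer$labels[[i]]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_ecoregion_grid
#' @param label_property name of the feature property holding the ecoregion
#'   label.
#' @export
read_ecoregions <- function(path, label_property = "ecoregion") {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features) || length(gj$features) == 0) {
    stop("configuration error: empty polygon layer in ", path, call. = FALSE)
  }
  labels <- character(0)
  rings <- list()
  for (f in gj$features) {
    lab <- f$properties[[label_property]]
    if (is.null(lab)) {
      stop("configuration error: feature lacks property '", label_property,
           "'", call. = FALSE)
    }
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (p in polys) {
      outer <- p[[1]]  # outer ring; interior holes are not supported
      m <- do.call(rbind, lapply(outer, function(pt) {
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
      }))
      colnames(m) <- c("lon", "lat")
      labels <- c(labels, as.character(lab))
      rings <- c(rings, list(m))
    }
  }
  structure(list(labels = labels, rings = rings), class = "ecoregion_layer")
}
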
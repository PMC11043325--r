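#' K-means clustering with restarts
#'
#' Seeded, best-of-restarts k-means (`stats::kmeans`) on a matrix of
#' standardized covariates. Rare empty-cluster failures are retried with a
#' fresh child seed. Deterministic given `seed`.
#'
#' @param points numeric matrix (n x d), finite.
#' @param k number of clusters, `k <= n`.
#' @param seed integer seed.
#' @param n_restarts random restarts (default 25).
#' @return object of class `kmeans_result`: `cluster` (n assignments),
#'   `centers` (k x d), `within_sse`, `iterations`, `seed`.
#' @export
kmeans_cluster <- function(points, k, seed = 1L, n_restarts = 25L) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) {
    stop("input error: points must be finite", call. = FALSE)
  }
  if (nrow(points) < k) {
    stop("input error: need at least k points (n = ", nrow(points),
         ", k = ", k, ")", call. = FALSE)
  }
  if (nrow(points) == k) {
    # one point per cluster is the optimum (and stats::kmeans rejects it)
    if (anyDuplicated(points)) {
      stop("input error: k = n needs distinct points", call. = FALSE)
    }
    return(structure(list(cluster = seq_len(k), centers = points,
                          within_sse = 0, iterations = 0L,
                          seed = as.integer(seed)),
                     class = "kmeans_result"))
  }
  km <- NULL
  for (attempt in 0:9) {
    km <- with_child_seed(seed, attempt, {
      tryCatch(
        suppressWarnings(stats::kmeans(points, centers = k,
                                       nstart = n_restarts, iter.max = 100)),
        error = function(e) {
          if (grepl("empty cluster", conditionMessage(e))) NULL else stop(e)
        })
    })
    if (!is.null(km)) break
  }
  if (is.null(km)) {
    stop("estimation error: k-means produced empty clusters in all restarts",
         call. = FALSE)
  }
  structure(list(cluster = km$cluster, centers = km$centers,
                 within_sse = km$tot.withinss, iterations = km$iter,
                 seed = as.integer(seed)),
            class = "kmeans_result")
}

#' Label clusters by centroid size and flow
#'
#' Splits cluster centroids into small/large by centroid volume (first
#' column) and, when a discharge column is present, low/high by centroid
#' discharge (second column): the lower half of the centroid ranks is
#' "small" (resp. "low"). Ties are broken by the other axis and then by
#' cluster index, so labelling is deterministic even for identical
#' centroids.
#'
#' @param result a `kmeans_result` with 1-column (volume) or 2-column
#'   (volume, discharge) centers; k must be even.
#' @return character vector of length k: `"small"`/`"large"` for one
#'   column, `"small|low"` style for two.
#' @export
label_clusters <- function(result) {
  centers <- result$centers
  k <- nrow(centers)
  if (k %% 2 != 0) {
    stop("input error: cluster labelling needs an even k", call. = FALSE)
  }
  idx <- seq_len(k)
  if (ncol(centers) == 1) {
    ord <- order(centers[, 1], idx)
    size <- character(k)
    size[ord[seq_len(k / 2)]] <- "small"
    size[ord[(k / 2 + 1):k]] <- "large"
    return(size)
  }
  ord_v <- order(centers[, 1], centers[, 2], idx)
  ord_q <- order(centers[, 2], centers[, 1], idx)
  size <- flow <- character(k)
  size[ord_v[seq_len(k / 2)]] <- "small"
  size[ord_v[(k / 2 + 1):k]] <- "large"
  flow[ord_q[seq_len(k / 2)]] <- "low"
  flow[ord_q[(k / 2 + 1):k]] <- "high"
  paste(size, flow, sep = "|")
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Assign reservoirs to a classification schema
#'
#' Five schemas of ascending complexity:
#' 1. simple average — every reservoir in one class `"all"`;
#' 2. large & small — k-means (k = 2) on standardized `ln(volume + 1)`;
#' 3. size-flow — k-means (k = 4) on globally standardized
#'    `ln(volume + 1)`, `ln(discharge + 1)`;
#' 4. ecoregion — the level-II ecoregion label;
#' 5. eco-size-flow — within each ecoregion, covariates standardized
#'    within-ecoregion and k-means (k = 4); labels `"eco|size|flow"`.
#'
#' Records missing the covariates a schema needs receive the reserved
#' label `"unclassified"` (they are later imputed the global mean
#' density). Ecoregions with fewer eligible reservoirs than k form a
#' single class `"eco|all"`.
#'
#' @param records cleaned inventory tibble (with `ecoregion_l2` for
#'   schemas 4-5).
#' @param schema_id integer in 1..5.
#' @param seed integer seed for the clustering schemas.
#' @param k clusters for the size-flow split (default 4).
#' @return tibble `reservoir_id`, `schema_id`, `class_label`.
#' @export
assign_schema <- function(records, schema_id, seed = 1L, k = 4L) {
  stopifnot(length(schema_id) == 1, schema_id %in% 1:5)
  n <- nrow(records)
  label <- rep("unclassified", n)
  lv <- log1p(records$storage_volume_m3)
  lq <- log1p(records$max_discharge_m3s)

  if (schema_id == 1) {
    label <- rep("all", n)
  } else if (schema_id == 2) {
    elig <- which(!is.na(lv))
    if (length(elig) >= 2) {
      res <- kmeans_cluster(cbind(volume = zscore(lv[elig])), 2L,
                            seed = child_seed(seed, 20L))
      label[elig] <- label_clusters(res)[res$cluster]
    }
  } else if (schema_id == 3) {
    elig <- which(!is.na(lv) & !is.na(lq))
    if (length(elig) >= k) {
      res <- kmeans_cluster(cbind(volume = zscore(lv[elig]),
                                  discharge = zscore(lq[elig])), k,
                            seed = child_seed(seed, 30L))
      label[elig] <- label_clusters(res)[res$cluster]
    }
  } else if (schema_id == 4) {
    eco <- records$ecoregion_l2
    label <- ifelse(is.na(eco), "unclassified", eco)
  } else {
    eco <- records$ecoregion_l2
    if (all(is.na(eco))) {
      stop("configuration error: schema 5 needs ecoregion assignments",
           call. = FALSE)
    }
    for (e in sort(unique(eco[!is.na(eco)]))) {
      elig <- which(eco %in% e & !is.na(lv) & !is.na(lq))
      if (length(elig) >= k) {
        res <- kmeans_cluster(
          cbind(volume = zscore(lv[elig]), discharge = zscore(lq[elig])), k,
          seed = child_seed(seed, 50L + match(e, sort(unique(eco)))))
        label[elig] <- paste(e, label_clusters(res)[res$cluster], sep = "|")
      } else if (length(elig) > 0) {
        label[elig] <- paste(e, "all", sep = "|")
      }
    }
  }
  tibble::tibble(reservoir_id = records$reservoir_id,
                 schema_id = as.integer(schema_id),
                 class_label = label)
}
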
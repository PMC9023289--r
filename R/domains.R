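# Downstream spatial analyses on deconvolution output: neighborhood-aware
# k-means domain identification, core/edge/border/stroma region labels from
# the distance to a core cluster, and topic-similarity mapping of single
# cells into spots.

coords_matrix <- function(coords, spot_ids) {
  idx <- match(spot_ids, coords$spot_id)
  if (anyNA(idx)) {
    stop("coordinates missing for spots: ",
         paste(utils::head(spot_ids[is.na(idx)], 5), collapse = ", "))
  }
  cbind(x = coords$x[idx], y = coords$y[idx])
}

#' Mean composition of the neighborhood of each spot
#'
#' Averages the cell-type composition over each spot's neighbors — the `k`
#' nearest other spots (default 6, the hex-grid degree of common arrays) or
#' all spots within `radius`. A spot without neighbors keeps its own
#' composition.
#'
#' @param st_comp `spot_composition` or types x spots proportion matrix.
#' @param coords Coordinate table (`spot_id`, `x`, `y`).
#' @param k Number of nearest neighbors (ignored when `radius` is given).
#' @param radius Optional neighborhood radius in array units.
#' @return Types x spots matrix of neighborhood compositions.
#' @export
neighborhood_composition <- function(st_comp, coords, k = 6, radius = NULL) {
  ST <- as_proportions(st_comp)
  xy <- coords_matrix(coords, colnames(ST))
  J <- ncol(ST)
  D <- as.matrix(stats::dist(xy))
  out <- ST
  for (j in seq_len(J)) {
    d <- D[j, -j]
    others <- seq_len(J)[-j]
    nb <- if (is.null(radius)) {
      others[order(d)][seq_len(min(k, length(others)))]
    } else {
      others[d <= radius]
    }
    if (length(nb)) out[, j] <- rowMeans(ST[, nb, drop = FALSE])
  }
  out
}

# Seeded k-means++ center initialization (deterministic under with_seed).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (i in seq_len(k)[-1]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i, ] <- X[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[i, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Spatial domain clustering on composition plus neighborhood
#'
#' Runs k-means on the concatenation of each spot's own cell-type composition
#' (weighted `weight`) and its neighborhood composition (weighted
#' `1 - weight`); `weight = 0.5` gives the two factors equal weight,
#' `weight = 1` clusters on composition alone. Initialization is seeded
#' k-means++, so the partition is deterministic given the seed.
#'
#' @inheritParams neighborhood_composition
#' @param k_clusters Number of domains (default 6).
#' @param weight Weight of the spot's own composition in `[0, 1]`.
#' @param seed Seed.
#' @return Named integer vector of cluster ids (1..k) per spot.
#' @export
cluster_domains <- function(st_comp, coords, k_clusters = 6, weight = 0.5,
                            k = 6, radius = NULL, seed = 1) {
  stopifnot(k_clusters >= 2, weight >= 0, weight <= 1)
  ST <- as_proportions(st_comp)
  if (k_clusters > ncol(ST)) stop("k_clusters exceeds the number of spots")
  NB <- neighborhood_composition(ST, coords, k = k, radius = radius)
  X <- t(rbind(weight * ST, (1 - weight) * NB))
  with_seed(seed, {
    centers <- unique(kmeanspp_centers(X, k_clusters))
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100)
    )
    stats::setNames(km$cluster, colnames(ST))
  })
}

#' Core/edge/border/stroma region labels
#'
#' Labels the spots of a clustered slide relative to a user-chosen core
#' cluster: core spots get distance 0; every other spot's distance is the
#' Euclidean distance (array units) to its nearest core spot. Non-core spots
#' within `edge_radius` are the edge immediately surrounding the core;
#' beyond that, spots at distance `<= threshold` are the border and spots
#' farther than `threshold` are stroma (a distance exactly equal to the
#' threshold counts as border).
#'
#' @param clusters Named cluster id vector from [cluster_domains()].
#' @param coords Coordinate table covering the spots.
#' @param core_cluster Cluster id to treat as the core region.
#' @param threshold Border/stroma distance cutoff (default 4 array units).
#' @param edge_radius Edge distance cutoff (default 2 array units).
#' @return `data.frame` with `spot_id`, `cluster`, `distance_to_core`,
#'   `region` (one of `core`, `edge`, `border`, `stroma`).
#' @export
define_regions <- function(clusters, coords, core_cluster, threshold = 4,
                           edge_radius = 2) {
  spots <- names(clusters)
  xy <- coords_matrix(coords, spots)
  core <- clusters == core_cluster
  if (!any(core)) stop("core cluster ", core_cluster, " is empty")
  d <- rep(0, length(spots))
  if (any(!core)) {
    cxy <- xy[core, , drop = FALSE]
    d[!core] <- apply(xy[!core, , drop = FALSE], 1L, function(p) {
      sqrt(min((cxy[, 1] - p[1])^2 + (cxy[, 2] - p[2])^2))
    })
  }
  region <- ifelse(core, "core",
                   ifelse(d <= edge_radius, "edge",
                          ifelse(d <= threshold, "border", "stroma")))
  data.frame(spot_id = spots, cluster = unname(clusters),
             distance_to_core = d, region = region,
             stringsAsFactors = FALSE)
}

#' Map single cells into spots by topic similarity
#'
#' For each spot, apportions `n_cells` slots to cell types by
#' largest-remainder on the deconvolved proportions, then fills each type's
#' quota with the reference cells of that type whose topic profiles have the
#' highest cosine similarity to the spot's topic distribution. If a quota
#' exceeds the available cells of a type, cells are recycled with a warning.
#' Pooling the selected cells' counts dissects the spot's expression into
#' cell-type-specific profiles.
#'
#' @param cell_Z Topics x cells matrix (e.g. `model$lda$Z`).
#' @param spot_Y Topics x spots matrix (e.g. `pred$topics`).
#' @param st_comp `spot_composition` or types x spots proportions for the
#'   same spots.
#' @param labels Cell-type labels for the columns of `cell_Z`.
#' @param sc_counts Optional raw counts (genes x cells); when given, pooled
#'   per-type expression is returned per spot.
#' @param n_cells Cells mapped per spot (default 10).
#' @return List with `cells` (`data.frame`: spot_id, cell_id, cell_type,
#'   similarity) and, when `sc_counts` is given, `pooled` (list per spot of
#'   genes x types summed counts).
#' @export
map_cells_to_spots <- function(cell_Z, spot_Y, st_comp, labels,
                               sc_counts = NULL, n_cells = 10) {
  ST <- as_proportions(st_comp)
  if (nrow(cell_Z) != nrow(spot_Y)) {
    stop("cell and spot topic spaces differ (use the same model)")
  }
  labels <- labels[colnames(cell_Z)]
  if (anyNA(labels)) stop("labels missing for some cells")
  cells_by_type <- split(colnames(cell_Z), labels)
  recycled <- FALSE
  rows <- list()
  pooled <- if (!is.null(sc_counts)) vector("list", ncol(spot_Y)) else NULL
  for (j in seq_len(ncol(spot_Y))) {
    sid <- colnames(spot_Y)[j]
    quota <- largest_remainder(ST[, sid], n_cells)
    sel_ids <- character(0)
    sel_ty <- character(0)
    sel_sim <- numeric(0)
    for (ty in names(quota)[quota > 0]) {
      pool <- cells_by_type[[ty]]
      if (is.null(pool) || !length(pool)) {
        warning("no reference cells of type '", ty, "'; quota dropped")
        next
      }
      sim <- cosine_to_columns(cell_Z[, pool, drop = FALSE], spot_Y[, j])
      ord <- order(-sim, pool)
      take <- quota[[ty]]
      if (take > length(pool)) {
        recycled <- TRUE
        idx <- rep(ord, length.out = take)
      } else {
        idx <- ord[seq_len(take)]
      }
      sel_ids <- c(sel_ids, pool[idx])
      sel_ty <- c(sel_ty, rep(ty, take))
      sel_sim <- c(sel_sim, sim[idx])
    }
    rows[[j]] <- data.frame(spot_id = sid, cell_id = sel_ids,
                            cell_type = sel_ty, similarity = sel_sim,
                            stringsAsFactors = FALSE)
    if (!is.null(sc_counts)) {
      tys <- unique(sel_ty)
      pm <- vapply(tys, function(ty) {
        ids <- sel_ids[sel_ty == ty]
        rowSums(sc_counts[, ids, drop = FALSE])
      }, numeric(nrow(sc_counts)))
      pooled[[j]] <- pm
    }
  }
  if (recycled) {
    warning("some cell-type quotas exceeded the available cells; ",
            "cells were recycled")
  }
  out <- list(cells = do.call(rbind, rows))
  if (!is.null(pooled)) {
    names(pooled) <- colnames(spot_Y)
    out$pooled <- pooled
  }
  out
}
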
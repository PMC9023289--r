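# Scoring deconvolution output against ground truth: per-spot and
# per-cell-type Pearson correlation and the presence/absence-split RMSE
# (sensitivity vs specificity); marker-based signature scores for data
# without ground truth.

align_pred_truth <- function(pred, truth) {
  P <- as_proportions(pred)
  G <- as_dense(truth)
  if (is.null(rownames(G)) || is.null(colnames(G))) {
    stop("truth must carry cell-type rownames and spot colnames")
  }
  types <- intersect(rownames(P), rownames(G))
  spots <- intersect(colnames(P), colnames(G))
  if (length(types) < 2) stop("fewer than 2 shared cell types")
  if (!length(spots)) stop("no shared spots")
  list(pred = P[types, spots, drop = FALSE],
       truth = G[types, spots, drop = FALSE])
}

#' Per-spot Pearson correlation with the ground truth
#'
#' For each spot, the Pearson correlation between the predicted and true
#' cell-type proportion vectors; measures per-spot deconvolution accuracy.
#' Spots whose truth vector has zero variance (a single cell type) are
#' undefined and reported as `NaN` with a warning.
#'
#' @param pred `spot_composition` or types x spots proportion matrix.
#' @param truth Types x spots ground-truth proportion matrix.
#' @return Named numeric vector, one `r` per spot.
#' @export
spot_correlation <- function(pred, truth) {
  al <- align_pred_truth(pred, truth)
  r <- vapply(seq_len(ncol(al$pred)), function(j) {
    tv <- al$truth[, j]
    pv <- al$pred[, j]
    if (stats::sd(tv) == 0 || stats::sd(pv) == 0) return(NaN)
    stats::cor(pv, tv)
  }, numeric(1))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " spots have zero-variance proportions; r = NaN")
  }
  stats::setNames(r, colnames(al$pred))
}

#' Per-cell-type Pearson correlation with the ground truth
#'
#' For each cell type, the Pearson correlation between predicted and true
#' proportions across spots; measures how well types are distinguished.
#' Types absent (constant) everywhere are `NaN` with a warning.
#'
#' @inheritParams spot_correlation
#' @return Named numeric vector, one `r` per cell type.
#' @export
celltype_correlation <- function(pred, truth) {
  al <- align_pred_truth(pred, truth)
  r <- vapply(seq_len(nrow(al$pred)), function(i) {
    tv <- al$truth[i, ]
    pv <- al$pred[i, ]
    if (stats::sd(tv) == 0 || stats::sd(pv) == 0) return(NaN)
    stats::cor(pv, tv)
  }, numeric(1))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " cell types have constant proportions; r = NaN")
  }
  stats::setNames(r, rownames(al$pred))
}

#' Presence/absence-split RMSE per spot
#'
#' Splits the cell types of each spot by the ground truth into present
#' (`truth > 0`) and absent (`truth == 0`) groups and computes the RMSE of
#' the predicted proportions within each group. The present-group RMSE
#' measures sensitivity (recovering true positives), the absent-group RMSE
#' specificity (not inventing absent types). Empty groups yield `NaN`.
#'
#' @inheritParams spot_correlation
#' @return `data.frame` with columns `spot_id`, `rmse_present`,
#'   `rmse_absent`.
#' @export
presence_split_rmse <- function(pred, truth) {
  al <- align_pred_truth(pred, truth)
  res <- t(vapply(seq_len(ncol(al$pred)), function(j) {
    err <- al$pred[, j] - al$truth[, j]
    present <- al$truth[, j] > 0
    c(if (any(present)) sqrt(mean(err[present]^2)) else NaN,
      if (any(!present)) sqrt(mean(err[!present]^2)) else NaN)
  }, numeric(2)))
  data.frame(spot_id = colnames(al$pred),
             rmse_present = res[, 1], rmse_absent = res[, 2],
             stringsAsFactors = FALSE)
}

#' Marker-based signature scores per spot
#'
#' Scores each spot for each cell type from its marker genes, for data
#' without ground truth. `method = "sum"` sums the depth-normalized
#' expression of the marker list; `method = "bin_controlled"` subtracts the
#' mean expression of expression-matched control genes (genes binned by
#' average expression; `n_control` controls drawn from the bin of each
#' marker), the module-score style that removes depth/abundance bias.
#'
#' @param st Raw count matrix, genes x spots.
#' @param markers Named list: cell type -> marker gene vector (markers absent
#'   from `st` are dropped with a warning; a type whose list empties is an
#'   error).
#' @param method `"sum"` or `"bin_controlled"`.
#' @param nbins Expression bins for control matching (default 24).
#' @param n_control Control genes sampled per marker gene (default 100).
#' @param seed Seed for control sampling.
#' @return Types x spots score matrix.
#' @export
signature_score <- function(st, markers, method = c("sum", "bin_controlled"),
                            nbins = 24, n_control = 100, seed = 1) {
  method <- match.arg(method)
  st <- as_dense(st)
  x <- sweep(st, 2, pmax(colSums(st), 1), "/") * 1e4
  markers <- lapply(markers, function(g) {
    miss <- setdiff(g, rownames(x))
    if (length(miss)) {
      warning(length(miss), " marker genes absent from the matrix; dropped")
    }
    intersect(g, rownames(x))
  })
  empty <- names(markers)[!lengths(markers)]
  if (length(empty)) {
    stop("no markers left after filtering for: ",
         paste(empty, collapse = ", "))
  }
  if (method == "sum") {
    out <- t(vapply(markers,
                    function(g) colSums(x[g, , drop = FALSE]),
                    numeric(ncol(x))))
  } else {
    avg <- rowMeans(x)
    nb <- min(nbins, length(unique(avg)))
    bins <- cut(rank(avg, ties.method = "first"), breaks = nb, labels = FALSE)
    names(bins) <- rownames(x)
    out <- with_seed(seed, {
      t(vapply(markers, function(g) {
        ctrl <- unlist(lapply(g, function(gi) {
          pool <- names(bins)[bins == bins[gi]]
          sample(pool, min(n_control, length(pool)))
        }))
        colMeans(x[g, , drop = FALSE]) -
          colMeans(x[unique(ctrl), , drop = FALSE])
      }, numeric(ncol(x))))
    })
  }
  rownames(out) <- names(markers)
  colnames(out) <- colnames(x)
  out
}

#' Summarize deconvolution performance
#'
#' Convenience wrapper computing the three metric families and their
#' median/quartile summaries.
#'
#' @inheritParams spot_correlation
#' @return List with `per_spot` (`data.frame`), `per_type` (`data.frame`),
#'   and `summary` (medians and quartiles).
#' @export
evaluate_deconvolution <- function(pred, truth) {
  sr <- spot_correlation(pred, truth)
  tr <- celltype_correlation(pred, truth)
  rmse <- presence_split_rmse(pred, truth)
  per_spot <- data.frame(spot_id = names(sr), pearson_r = sr,
                         rmse_present = rmse$rmse_present,
                         rmse_absent = rmse$rmse_absent,
                         stringsAsFactors = FALSE, row.names = NULL)
  per_type <- data.frame(cell_type = names(tr), pearson_r = tr,
                         stringsAsFactors = FALSE, row.names = NULL)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  summary <- rbind(spot_pearson_r = qs(sr),
                   type_pearson_r = qs(tr),
                   rmse_present = qs(rmse$rmse_present),
                   rmse_absent = qs(rmse$rmse_absent))
  colnames(summary) <- c("q25", "median", "q75")
  list(per_spot = per_spot, per_type = per_type, summary = summary)
}
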
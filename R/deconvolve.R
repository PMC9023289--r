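# Applying a fitted topic model to spatial data: per-spot topic inference by
# variational fold-in, conversion of topic distributions to cell-type
# proportions, dominant-type calls and topic signature maps.

#' Convert spot topic distributions to cell-type proportions
#'
#' `ST = C %*% Y`, then each column is renormalized to sum exactly 1. Linear
#' in `Y` before the renormalization.
#'
#' @param C Types x topics matrix (columns sum to 1).
#' @param Y Topics x spots matrix (columns sum to 1).
#' @return Types x spots proportion matrix.
#' @export
deconvolve_topics <- function(C, Y) {
  if (ncol(C) != nrow(Y)) stop("C and Y topic dimensions do not conform")
  ST <- C %*% Y
  sweep(ST, 2, colSums(ST), "/")
}

#' Deconvolve spatial spots with a fitted cell-type topic model
#'
#' Normalizes the spatial counts with the training scheme (per-spot depth
#' scaling then per-gene SD division — SDs recomputed on the spatial matrix
#' by default, or reused from the single-cell reference), infers per-spot
#' topic distributions with the gene-by-topic distribution frozen, and maps
#' them to cell-type proportions through the model's cell-type-by-topic
#' table.
#'
#' @param object A `celltopic_model`.
#' @param newdata Raw spatial count matrix, genes x spots.
#' @param gene_sd `"spatial"` (default) recomputes per-gene SDs on the
#'   spatial matrix; `"reference"` reuses the single-cell SDs.
#' @param max_iter,tol Fold-in controls, see [infer_topics()].
#' @param ... Unused.
#' @return Object of class `spot_composition`: list with `proportions`
#'   (types x spots, columns sum to 1), `topics` (`Y`, topics x spots),
#'   `dominant` (per-spot argmax type) and `spot_ids`.
#' @export
predict.celltopic_model <- function(object, newdata,
                                    gene_sd = c("spatial", "reference"),
                                    max_iter = 100, tol = 1e-6, ...) {
  gene_sd <- match.arg(gene_sd)
  st <- as_dense(newdata)
  validate_expression_matrix(st, "spatial matrix")
  genes <- intersect(object$features$genes, rownames(st))
  if (!length(genes)) stop("spatial matrix shares no genes with the model")
  if (length(genes) < length(object$features$genes)) {
    warning(length(object$features$genes) - length(genes),
            " feature genes absent from the spatial matrix")
  }
  st <- st[genes, , drop = FALSE]
  keep <- colSums(st) > 0
  if (!all(keep)) {
    warning(sum(!keep), " spots have zero feature counts and get uniform topics")
  }
  sds <- if (gene_sd == "reference") object$gene_sd[genes] else NULL
  x <- matrix(0, length(genes), ncol(st), dimnames = dimnames(st))
  if (any(keep)) {
    x[, keep] <- normalize_counts(st[, keep, drop = FALSE],
                                  scale_factor = object$scale_factor,
                                  gene_sd = sds)
  }
  Y <- infer_topics(object$lda, x, max_iter = max_iter, tol = tol)
  ST <- deconvolve_topics(object$C, Y)
  structure(list(proportions = ST, topics = Y,
                 dominant = dominant_celltype(ST),
                 spot_ids = colnames(st)),
            class = "spot_composition")
}

#' Dominant cell type per spot
#'
#' Argmax over the proportion column of each spot; ties go to the
#' lexicographically first type name.
#'
#' @param st_comp A `spot_composition` or a types x spots proportion matrix.
#' @return Named character vector, spot -> type.
#' @export
dominant_celltype <- function(st_comp) {
  ST <- as_proportions(st_comp)
  STo <- ST[order(rownames(ST)), , drop = FALSE]
  stats::setNames(rownames(STo)[apply(STo, 2L, which.max)], colnames(ST))
}

#' Per-spot topic signature score
#'
#' Sums the probabilities of a set of topics in each spot; summing the topics
#' associated with one cell type gives that type's spatial signature map.
#'
#' @param Y Topics x spots matrix or a `spot_composition`.
#' @param topic_subset Topic names (or indices) to sum; must exist.
#' @return Named numeric vector in `[0, 1]`, one score per spot.
#' @export
topic_signature_map <- function(Y, topic_subset) {
  if (inherits(Y, "spot_composition")) Y <- Y$topics
  if (!length(topic_subset)) stop("topic_subset must be non-empty")
  if (is.character(topic_subset)) {
    unknown <- setdiff(topic_subset, rownames(Y))
    if (length(unknown)) {
      stop("unknown topics: ", paste(unknown, collapse = ", "))
    }
  } else if (any(topic_subset < 1 | topic_subset > nrow(Y))) {
    stop("topic indices out of range")
  }
  colSums(Y[topic_subset, , drop = FALSE])
}

as_proportions <- function(x) {
  if (inherits(x, "spot_composition")) return(x$proportions)
  if (is.matrix(x) || inherits(x, "Matrix")) return(as_dense(x))
  stop("expected a spot_composition or a proportion matrix")
}

#' @export
print.spot_composition <- function(x, ...) {
  cat("Spot composition: ", ncol(x$proportions), " spots x ",
      nrow(x$proportions), " cell types\n", sep = "")
  tab <- sort(table(x$dominant), decreasing = TRUE)
  cat("  dominant types: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.spot_composition <- function(x, ...) x$proportions

#' Scatter plot of spots colored by dominant cell type
#'
#' @param x A `spot_composition`.
#' @param coords Coordinate table (`spot_id`, `x`, `y`) covering the spots.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spot_composition <- function(x, coords, ...) {
  idx <- match(x$spot_ids, coords$spot_id)
  if (anyNA(idx)) stop("coordinates missing for some spots")
  types <- sort(unique(x$dominant))
  cols <- grDevices::hcl.colors(max(3L, length(types)), "Dark 3")
  graphics::plot(coords$x[idx], coords$y[idx],
                 col = cols[match(x$dominant, types)], pch = 16,
                 xlab = "x", ylab = "y", asp = 1, ...)
  graphics::legend("topright", legend = types,
                   col = cols[seq_along(types)], pch = 16, cex = 0.7)
  invisible(x)
}
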
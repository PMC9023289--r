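# Feature-space construction: common genes between modalities, depth + gene
# scaling, marker-gene selection by one-vs-rest Wilcoxon rank-sum, and highly
# variable gene selection.

#' Common genes between single-cell and spatial matrices
#'
#' Returns the sorted intersection of gene identifiers; the topic model is
#' trained and applied on this shared vocabulary.
#'
#' @param sc,st Expression matrices (genes as rows).
#' @return Sorted character vector of shared genes.
#' @export
intersect_genes <- function(sc, st) {
  common <- sort(intersect(rownames(sc), rownames(st)))
  if (!length(common)) {
    stop("no shared genes between the two matrices ",
         "(species or annotation mismatch?)")
  }
  common
}

#' Depth- and gene-scale normalization
#'
#' Two-step scheme applied to cells and spots alike: (1) each column is
#' divided by its total count and multiplied by `scale_factor` (counts per
#' 10k by default); (2) each gene row is divided by its standard deviation
#' across columns (population SD, no centering, so values stay non-negative
#' and can serve as fractional token weights for the topic model). Rows with
#' zero variance are set to zero.
#'
#' @param m Raw count matrix (genes x columns).
#' @param scale_factor Per-column scale after depth division. Default 10000.
#' @param gene_sd Optional precomputed per-gene SDs (e.g. from the single-cell
#'   reference) to use instead of recomputing them on `m`.
#' @return Normalized matrix; the per-gene SDs used are attached as attribute
#'   `gene_sd`.
#' @export
normalize_counts <- function(m, scale_factor = 1e4, gene_sd = NULL) {
  m <- as_dense(m)
  validate_expression_matrix(m)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("columns with zero total counts: ",
         paste(utils::head(colnames(m)[tot == 0], 5), collapse = ", "))
  }
  x <- sweep(m, 2, tot, "/") * scale_factor
  if (is.null(gene_sd)) {
    mu <- rowMeans(x)
    gene_sd <- sqrt(pmax(rowMeans(x * x) - mu * mu, 0))
    names(gene_sd) <- rownames(x)
  } else {
    gene_sd <- gene_sd[rownames(x)]
    if (anyNA(gene_sd)) stop("gene_sd missing for some genes")
  }
  pos <- gene_sd > 1e-12
  x[pos, ] <- x[pos, , drop = FALSE] / gene_sd[pos]
  x[!pos, ] <- 0
  attr(x, "gene_sd") <- gene_sd
  attr(x, "is_integer") <- FALSE
  x
}

# Vectorised one-vs-rest Wilcoxon rank-sum test over gene rows.
# Returns one-sided (greater-in-group) normal-approximation p-values with tie
# correction and continuity correction, matching wilcox.test(correct = TRUE).
rowwise_wilcox <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  N <- n1 + n2
  ranks <- t(apply(x, 1L, rank))
  r1 <- rowSums(ranks[, in_group, drop = FALSE])
  U <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tiecor <- apply(x, 1L, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tiecor / (N * (N - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  z <- (U - mu - 0.5) / sigma
  p <- stats::pnorm(z, lower.tail = FALSE)
  p[sigma == 0] <- 1
  p
}

#' Marker genes by one-vs-rest Wilcoxon test
#'
#' For each cell type, ranks genes by a one-sided Wilcoxon rank-sum test of
#' that type's cells against the rest on depth/gene-normalized expression;
#' ties on p-value are broken by descending log2 fold change, then gene id.
#' `contrasts` restricts the "rest" group for stated types, as is useful for
#' transcriptionally similar types that are best separated from each other
#' rather than from the whole dataset.
#'
#' @param sc Raw count matrix (genes x cells).
#' @param labels Named character vector of cell types.
#' @param n_top Markers kept per cell type.
#' @param contrasts Optional named list: type -> character vector of types to
#'   compare against (instead of all other cells).
#' @param normalized Optional pre-normalized matrix (skips renormalization).
#' @return Object of class `feature_genes`: sorted union of per-type top
#'   lists (`genes`), per-type ranked marker lists (`markers`), `mode` and
#'   `n_top`.
#' @export
select_marker_genes <- function(sc, labels, n_top = 500, contrasts = NULL,
                                normalized = NULL) {
  stopifnot(n_top >= 1)
  labels <- labels[colnames(sc)]
  if (anyNA(labels)) stop("labels missing for some cells")
  types <- sort(unique(labels))
  if (length(types) < 2) stop("marker selection needs at least 2 cell types")
  x <- normalized %||% normalize_counts(sc)
  cp10k <- sweep(as_dense(sc), 2, colSums(sc), "/") * 1e4
  markers <- list()
  for (ty in types) {
    rest_types <- setdiff(types, ty)
    if (!is.null(contrasts) && ty %in% names(contrasts)) {
      rest_types <- intersect(contrasts[[ty]], types)
    }
    keep <- labels %in% c(ty, rest_types)
    in_group <- labels[keep] == ty
    if (sum(in_group) < 3) {
      warning("cell type '", ty, "' has fewer than 3 cells; skipped")
      next
    }
    p <- rowwise_wilcox(x[, keep, drop = FALSE], in_group)
    lfc <- log2((rowMeans(cp10k[, keep, drop = FALSE][, in_group, drop = FALSE]) + 1) /
                (rowMeans(cp10k[, keep, drop = FALSE][, !in_group, drop = FALSE]) + 1))
    ord <- order(p, -lfc, rownames(sc))
    k <- min(n_top, nrow(sc))
    if (n_top > nrow(sc)) {
      warning("n_top (", n_top, ") exceeds gene count (", nrow(sc),
              "); returning the full ranking")
    }
    markers[[ty]] <- rownames(sc)[ord[seq_len(k)]]
  }
  if (!length(markers)) stop("no cell type had enough cells for marker selection")
  structure(list(mode = "markers",
                 genes = sort(unique(unlist(markers, use.names = FALSE))),
                 markers = markers, n_top = n_top),
            class = "feature_genes")
}

#' Highly variable genes by dispersion
#'
#' Ranks genes by the variance-to-mean dispersion of depth-scaled counts
#' (counts per 10k) and keeps the top `n_top`; constant or silent genes have
#' dispersion 0 and are never selected first.
#'
#' @param sc Raw count matrix.
#' @param n_top Genes to keep (clamped to the gene count with a warning).
#' @return Object of class `feature_genes` with `mode = "hvg"`.
#' @export
select_hvgs <- function(sc, n_top = 2000) {
  stopifnot(n_top >= 1)
  cp10k <- sweep(as_dense(sc), 2, colSums(sc), "/") * 1e4
  mu <- rowMeans(cp10k)
  v <- apply(cp10k, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (n_top > nrow(sc)) {
    warning("n_top (", n_top, ") exceeds gene count (", nrow(sc), "); clamped")
    n_top <- nrow(sc)
  }
  ord <- order(-disp, rownames(sc))
  structure(list(mode = "hvg",
                 genes = sort(rownames(sc)[ord[seq_len(n_top)]]),
                 dispersion = stats::setNames(disp, rownames(sc)),
                 n_top = n_top),
            class = "feature_genes")
}

#' Assemble the feature gene set for model training
#'
#' Combines the available strategies over the genes shared between the
#' single-cell and spatial matrices: all shared genes, per-type markers,
#' highly variable genes, or markers plus HVGs.
#'
#' @param sc,st Raw count matrices.
#' @param labels Cell-type labels for `sc` (needed for marker modes).
#' @param mode One of `"markers"`, `"all"`, `"hvg"`, `"markers_hvg"`.
#' @param n_top Markers per type and/or HVG count.
#' @param contrasts Passed to [select_marker_genes()].
#' @return `feature_genes` object restricted to shared genes.
#' @export
select_features <- function(sc, st = NULL, labels = NULL,
                            mode = c("markers", "all", "hvg", "markers_hvg"),
                            n_top = 500, contrasts = NULL) {
  mode <- match.arg(mode)
  common <- if (is.null(st)) sort(rownames(sc)) else intersect_genes(sc, st)
  sc_c <- sc[common, , drop = FALSE]
  if (mode == "all") {
    return(structure(list(mode = "all", genes = common, n_top = NA_integer_),
                     class = "feature_genes"))
  }
  if (mode == "hvg") {
    fs <- select_hvgs(sc_c, n_top)
    return(fs)
  }
  if (is.null(labels)) stop("marker modes need cell-type labels")
  fs <- select_marker_genes(sc_c, labels, n_top, contrasts)
  if (mode == "markers_hvg") {
    hv <- select_hvgs(sc_c, n_top)
    fs$genes <- sort(unique(c(fs$genes, hv$genes)))
    fs$mode <- "markers_hvg"
  }
  fs
}

#' @export
print.feature_genes <- function(x, ...) {
  cat("Feature gene set (mode = ", x$mode, "): ", length(x$genes),
      " genes\n", sep = "")
  if (!is.null(x$markers)) {
    cat("  per-type markers (n_top = ", x$n_top, "): ",
        paste(names(x$markers), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
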
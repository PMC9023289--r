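# Cell-type/topic tables derived from a trained topic model, re-annotation of
# single cells, topic-number selection, and the user-facing fitting function
# returning a classed model object.

#' Topic profile of each cell type
#'
#' Averages the topic-by-cell distribution over the cells of each type:
#' `T[k, n] = sum_m Z[k, m] A[m, n] / sum_m A[m, n]`, where `A` is the one-hot
#' label matrix. Each column is a probability distribution over topics.
#'
#' @param Z Topics x cells matrix (columns sum to 1).
#' @param labels Named character vector of cell types covering `colnames(Z)`.
#' @return Topics x types matrix `T`.
#' @export
type_topic_profile <- function(Z, labels) {
  labels <- labels[colnames(Z)]
  if (anyNA(labels)) stop("labels missing for some cells in Z")
  A <- onehot_labels(labels, colnames(Z))
  n_per_type <- colSums(A)
  if (any(n_per_type == 0)) {
    stop("cell types with zero cells: ",
         paste(colnames(A)[n_per_type == 0], collapse = ", "))
  }
  T_mat <- Z %*% A
  sweep(T_mat, 2, n_per_type, "/")
}

#' Cell-type-by-topic distribution by Bayes inversion
#'
#' Inverts the topic profile table with the cell-type prior:
#' `P[k] = sum_n T[k, n] Q[n]` (topic marginal) and
#' `C[n, k] = T[k, n] Q[n] / P[k]`, the probability that topic `k` belongs to
#' cell type `n`. Each column of `C` sums to 1.
#'
#' @param T_mat Topics x types matrix from [type_topic_profile()].
#' @param Q Cell-type prior (named, sums to 1, strictly positive); defaults
#'   to uniform if omitted.
#' @return List with `C` (types x topics), `P` (topic marginal) and `Q`.
#' @export
celltype_topic_posterior <- function(T_mat, Q = NULL) {
  N <- ncol(T_mat)
  Q <- Q %||% stats::setNames(rep(1 / N, N), colnames(T_mat))
  Q <- Q[colnames(T_mat)]
  if (anyNA(Q) || any(Q <= 0)) stop("Q must be strictly positive for all types")
  if (abs(sum(Q) - 1) > 1e-8) stop("Q must sum to 1")
  P <- as.vector(T_mat %*% Q)
  names(P) <- rownames(T_mat)
  if (any(P <= 0)) {
    stop("topics unused by every cell type: ",
         paste(names(P)[P <= 0], collapse = ", "))
  }
  C <- t(T_mat * rep(Q, each = nrow(T_mat))) / rep(P, each = ncol(T_mat))
  dimnames(C) <- list(colnames(T_mat), rownames(T_mat))
  list(C = C, P = P, Q = Q)
}

#' Re-annotate cells from topic distributions
#'
#' Scores each cell against each cell type through the topics:
#' `SC[n, m] = sum_k C[n, k] Z[k, m]`; every cell is assigned the type with
#' the largest probability (ties broken by lexicographic type name).
#'
#' @param C Types x topics matrix.
#' @param Z Topics x cells matrix.
#' @return List with `prob` (types x cells, columns sum to 1) and `labels`
#'   (named character vector of argmax types).
#' @export
annotate_cells <- function(C, Z) {
  if (ncol(C) != nrow(Z)) stop("C and Z topic dimensions do not conform")
  SC <- C %*% Z
  types <- rownames(C)[order(rownames(C))]
  SCo <- SC[order(rownames(SC)), , drop = FALSE]
  lab <- rownames(SCo)[apply(SCo, 2L, which.max)]  # which.max: first max wins
  list(prob = SC, labels = stats::setNames(lab, colnames(Z)))
}

reannotation_accuracy <- function(C, Z, labels) {
  ann <- annotate_cells(C, Z)
  mean(ann$labels == labels[names(ann$labels)])
}

#' Fit a cell-type topic model to annotated single-cell data
#'
#' End-to-end fitting: selects feature genes on the vocabulary shared with the
#' spatial data (when given), normalizes the reference counts, trains one LDA
#' model per candidate topic number, derives the cell-type/topic tables, and
#' keeps the model whose single-cell re-annotation accuracy is highest —
#' with ties going to the smallest (simplest) topic number.
#'
#' @param sc Raw count matrix, genes x cells.
#' @param labels Named character vector of cell types for the columns of `sc`.
#' @param st Optional spatial count matrix used only to restrict the gene
#'   vocabulary to shared genes.
#' @param ks Candidate topic numbers; default `{N, ceil(1.5 N), 2 N, 3 N}`
#'   for `N` cell types (values below 2 or >= the cell count are dropped).
#' @param feature_mode,n_top,contrasts Passed to [select_features()].
#' @param Q Cell-type prior; default: label frequencies in the reference.
#' @param scale_factor Normalization scale, see [normalize_counts()].
#' @param alpha,beta,passes,batch_size Passed to [train_lda()]; `alpha`
#'   defaults to `1/k` per candidate.
#' @param seed Seed controlling all stochastic steps.
#' @param verbose Report per-candidate accuracies.
#' @return Object of class `celltopic_model`; see Details.
#' @details The returned object bundles the selected `lda_fit` (`$lda`, with
#'   gene-by-topic `phi` and topic-by-cell `Z`), the topic profile per type
#'   (`$T_mat`), the Bayes-inverted cell-type-by-topic table (`$C`), the
#'   cell-type prior (`$Q`) and topic marginal (`$P`), the re-annotation of
#'   the training cells (`$annotation`), the accuracy table over all
#'   candidate topic numbers (`$accuracy`), the feature set (`$features`) and
#'   the per-gene SDs of the normalized reference (`$gene_sd`). Use
#'   [predict.celltopic_model()] to deconvolve spatial data.
#' @export
fit_celltopics <- function(sc, labels, st = NULL, ks = NULL,
                           feature_mode = "markers", n_top = 500,
                           contrasts = NULL, Q = NULL, scale_factor = 1e4,
                           alpha = NULL, beta = 0.01, passes = 20,
                           batch_size = 256, seed = 1, verbose = FALSE) {
  sc <- as_dense(sc)
  validate_expression_matrix(sc, "single-cell matrix")
  labels <- validate_labels(labels[colnames(sc)])
  types <- sort(unique(labels))
  N <- length(types)
  features <- select_features(sc, st, labels, mode = feature_mode,
                              n_top = n_top, contrasts = contrasts)
  x <- normalize_counts(sc[features$genes, , drop = FALSE],
                        scale_factor = scale_factor)
  if (is.null(ks)) {
    ks <- unique(pmax(2L, c(N, ceiling(1.5 * N), 2L * N, 3L * N)))
  }
  ks <- sort(unique(as.integer(ks)))
  ks <- ks[ks >= 2 & ks < ncol(sc)]
  if (!length(ks)) stop("no valid candidate topic numbers")
  if (is.null(Q)) {
    Q <- table(labels)[types]
    Q <- stats::setNames(as.numeric(Q) / sum(Q), types)
  } else {
    Q <- Q[types]
    if (anyNA(Q)) stop("Q must name every cell type")
    Q <- Q / sum(Q)
  }

  fits <- vector("list", length(ks))
  acc <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    lda <- train_lda(x, k, alpha = alpha %||% (1 / k), beta = beta,
                     passes = passes, batch_size = batch_size, seed = seed,
                     verbose = FALSE)
    T_mat <- type_topic_profile(lda$Z, labels)
    post <- celltype_topic_posterior(T_mat, Q)
    acc[i] <- reannotation_accuracy(post$C, lda$Z, labels)
    fits[[i]] <- list(lda = lda, T_mat = T_mat, post = post)
    if (verbose) {
      message(sprintf("k = %d: re-annotation accuracy %.4f", k, acc[i]))
    }
  }
  if (all(is.na(acc))) stop("re-annotation accuracy undefined for all candidates")
  best <- which(acc >= max(acc, na.rm = TRUE) - 1e-12)[1L]  # ks ascending: tie -> smallest
  sel <- fits[[best]]
  ann <- annotate_cells(sel$post$C, sel$lda$Z)
  structure(list(lda = sel$lda,
                 T_mat = sel$T_mat,
                 C = sel$post$C, P = sel$post$P, Q = sel$post$Q,
                 annotation = ann,
                 accuracy = data.frame(k = ks, accuracy = acc),
                 features = features,
                 gene_sd = attr(x, "gene_sd"),
                 scale_factor = scale_factor,
                 labels = labels,
                 cell_types = types,
                 call = match.call()),
            class = "celltopic_model")
}

#' Cell-type-by-topic coefficients of a fitted model
#'
#' @param object A `celltopic_model`.
#' @param ... Unused.
#' @return The types x topics matrix `C` that converts topic distributions
#'   into cell-type proportions.
#' @export
coef.celltopic_model <- function(object, ...) object$C

#' @export
print.celltopic_model <- function(x, ...) {
  k <- nrow(x$lda$phi)
  cat("Cell-type topic model\n")
  cat("  ", length(x$cell_types), " cell types, ", k, " topics, ",
      length(x$features$genes), " feature genes (mode = ", x$features$mode,
      ")\n", sep = "")
  cat("  trained on ", ncol(x$lda$Z), " cells; re-annotation accuracy ",
      sprintf("%.4f", x$accuracy$accuracy[x$accuracy$k == k]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.celltopic_model <- function(object, ...) {
  k <- nrow(object$lda$phi)
  assoc <- rownames(object$C)[apply(object$C, 2L, which.max)]
  out <- list(n_types = length(object$cell_types), k = k,
              accuracy = object$accuracy,
              topic_type = stats::setNames(assoc, colnames(object$C)),
              Q = object$Q)
  class(out) <- "summary.celltopic_model"
  out
}

#' @export
print.summary.celltopic_model <- function(x, ...) {
  cat("Cell-type topic model: ", x$n_types, " types, k = ", x$k, "\n", sep = "")
  cat("Re-annotation accuracy by candidate topic number:\n")
  print(x$accuracy, row.names = FALSE)
  cat("Dominant cell type per topic:\n")
  print(x$topic_type)
  invisible(x)
}

#' Heatmap of the cell-type-by-topic distribution
#'
#' @param x A `celltopic_model`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.celltopic_model <- function(x, ...) {
  C <- x$C
  graphics::image(seq_len(ncol(C)), seq_len(nrow(C)), t(C),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "topic", ylab = "", axes = FALSE,
                  main = "Cell-type-by-topic distribution", ...)
  graphics::axis(1, at = seq_len(ncol(C)), labels = colnames(C), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(C)), labels = rownames(C), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Topic-type association of a fitted model
#'
#' Topics are associated with the cell type holding the largest posterior
#' probability `C[n, k]`; used to build per-type topic signature maps.
#'
#' @param model A `celltopic_model`.
#' @return Named character vector: topic -> cell type.
#' @export
topic_associations <- function(model) {
  stats::setNames(rownames(model$C)[apply(model$C, 2L, which.max)],
                  colnames(model$C))
}
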
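# Latent Dirichlet allocation trained by online variational Bayes
# (Hoffman-style stochastic updates of the topic-word variational parameter),
# accepting fractional token weights so depth/SD-normalized expression can be
# used directly as bag-of-words evidence. Fold-in inference with the
# gene-by-topic distribution frozen provides topic distributions for new
# columns (spatial spots).

dirichlet_expectation <- function(a) {
  # E[log x] under Dirichlet(a), rows are independent Dirichlets
  if (is.matrix(a)) digamma(a) - digamma(rowSums(a)) else digamma(a) - digamma(sum(a))
}

# Variational E-step for a block of documents (rows of X, docs x genes).
# Returns the variational Dirichlet parameters gamma (docs x K) and, when
# requested, the sufficient statistics for the topic-word update (K x genes).
lda_estep <- function(X, expElogbeta, alpha, max_iter = 100, tol = 1e-3,
                      gamma_init = NULL, sstats = TRUE) {
  D <- nrow(X)
  K <- nrow(expElogbeta)
  gamma <- gamma_init %||%
    matrix(stats::rgamma(D * K, 100, rate = 100), D, K)
  expElogtheta <- exp(dirichlet_expectation(gamma))
  phinorm <- expElogtheta %*% expElogbeta + 1e-100
  for (it in seq_len(max_iter)) {
    gamma_new <- alpha + expElogtheta * ((X / phinorm) %*% t(expElogbeta))
    change <- mean(abs(gamma_new - gamma))
    gamma <- gamma_new
    expElogtheta <- exp(dirichlet_expectation(gamma))
    phinorm <- expElogtheta %*% expElogbeta + 1e-100
    if (change < tol) break
  }
  out <- list(gamma = gamma)
  if (sstats) {
    out$sstats <- (t(expElogtheta) %*% (X / phinorm)) * expElogbeta
  }
  out
}

# Mean per-token log likelihood proxy: sum_dv X_dv log(theta_bar beta_bar)
lda_per_token_score <- function(X, gamma, lambda) {
  theta <- gamma / rowSums(gamma)
  beta <- lambda / rowSums(lambda)
  mix <- theta %*% beta + 1e-100
  sum(X * log(mix)) / sum(X)
}

#' Train an LDA topic model by online variational Bayes
#'
#' Treats each column of `x` (a cell) as a document over the gene vocabulary;
#' `x` may hold fractional weights (normalized expression). The topic-word
#' variational parameter is updated from seeded random initialization with
#' stochastic minibatch steps and learning rate `(tau0 + t)^-kappa`; training
#' stops early when the per-token variational score changes by less than
#' `bound_tol` between passes. Given the same seed, training is deterministic.
#'
#' @param x Non-negative matrix, genes x cells, restricted to the feature
#'   genes.
#' @param k Number of topics (>= 2, < number of cells).
#' @param alpha Symmetric document-topic Dirichlet prior weight; default
#'   `1/k`.
#' @param beta Symmetric topic-gene Dirichlet prior weight; default 0.01.
#' @param passes Sweeps over the full data set. Default 20.
#' @param batch_size Cells per minibatch. Default 256.
#' @param tau0,kappa Learning-rate schedule `(tau0 + t)^-kappa`.
#' @param e_iter,e_tol Per-document E-step iteration cap and mean-change
#'   tolerance.
#' @param bound_tol Early-stopping tolerance on the per-token score change.
#' @param seed Integer seed controlling initialization and minibatch order.
#' @param verbose Print per-pass scores.
#' @return Object of class `lda_fit` with `phi` (topics x genes, rows sum
#'   to 1), `Z` (topics x cells, columns sum to 1), the raw variational
#'   parameters `lambda` and `gamma`, and the training parameters.
#' @export
train_lda <- function(x, k, alpha = 1 / k, beta = 0.01, passes = 20,
                      batch_size = 256, tau0 = 1, kappa = 0.7,
                      e_iter = 100, e_tol = 1e-3, bound_tol = 1e-4,
                      seed = 1, verbose = FALSE) {
  x <- as_dense(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty matrix")
  if (k < 2) stop("k must be at least 2")
  M <- ncol(x)
  V <- nrow(x)
  if (k >= M) stop("k (", k, ") must be smaller than the number of cells (", M, ")")
  if (any(colSums(x) == 0)) stop("cells with all-zero feature expression")
  alpha <- as.numeric(alpha)
  stopifnot(alpha > 0, beta > 0)
  X <- t(x)  # docs x genes

  with_seed(seed, {
    lambda <- matrix(stats::rgamma(k * V, 100, rate = 100), k, V)
    expElogbeta <- exp(dirichlet_expectation(lambda))
    t_step <- 0
    score_prev <- -Inf
    for (pass in seq_len(passes)) {
      ord <- sample.int(M)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      gamma_all <- matrix(NA_real_, M, k)
      for (b in batches) {
        es <- lda_estep(X[b, , drop = FALSE], expElogbeta, alpha,
                        max_iter = e_iter, tol = e_tol)
        gamma_all[b, ] <- es$gamma
        rho <- (tau0 + t_step)^(-kappa)
        lambda_hat <- beta + (M / length(b)) * es$sstats
        lambda <- (1 - rho) * lambda + rho * lambda_hat
        expElogbeta <- exp(dirichlet_expectation(lambda))
        t_step <- t_step + 1
      }
      score <- lda_per_token_score(X, gamma_all, lambda)
      if (verbose) {
        message(sprintf("pass %d/%d: per-token score %.6f", pass, passes, score))
      }
      if (is.finite(score_prev) && abs(score - score_prev) < bound_tol) break
      score_prev <- score
    }
    # Final fold-in over all cells with the converged topic-word parameter so
    # Z is consistent with phi (and with later spot inference).
    es <- lda_estep(X, expElogbeta, alpha, max_iter = e_iter, tol = 1e-6,
                    sstats = FALSE)
    gamma <- es$gamma
  })

  phi <- lambda / rowSums(lambda)
  Z <- t(gamma / rowSums(gamma))
  dimnames(phi) <- list(paste0("topic", seq_len(k)), rownames(x))
  dimnames(Z) <- list(paste0("topic", seq_len(k)), colnames(x))
  structure(list(phi = phi, Z = Z, lambda = lambda,
                 genes = rownames(x),
                 params = list(k = k, alpha = alpha, beta = beta,
                               passes = passes, batch_size = batch_size,
                               tau0 = tau0, kappa = kappa, seed = seed)),
            class = "lda_fit")
}

#' Infer topic distributions for new columns with frozen topics
#'
#' Variational fold-in: per-column topic weights are estimated with the
#' trained gene-by-topic distribution held fixed, exactly as cells were scored
#' at the end of training. Columns with all-zero feature expression get the
#' uniform distribution with a warning.
#'
#' @param model An `lda_fit` (or `celltopic_model`) object.
#' @param x_new Non-negative matrix, genes x columns, on the model's feature
#'   genes (missing genes are added as zero rows with a warning).
#' @param max_iter,tol Per-column iteration cap and convergence tolerance on
#'   the variational distribution change.
#' @return Topics x columns matrix `Y`; each column sums to 1.
#' @export
infer_topics <- function(model, x_new, max_iter = 100, tol = 1e-6) {
  if (inherits(model, "celltopic_model")) model <- model$lda
  stopifnot(inherits(model, "lda_fit"))
  x_new <- as_dense(x_new)
  missing <- setdiff(model$genes, rownames(x_new))
  if (length(missing)) {
    warning(length(missing), " model genes absent from input; treated as zero")
    zero <- matrix(0, length(missing), ncol(x_new),
                   dimnames = list(missing, colnames(x_new)))
    x_new <- rbind(x_new, zero)
  }
  x_new <- x_new[model$genes, , drop = FALSE]
  k <- nrow(model$phi)
  empty <- colSums(x_new) == 0
  if (any(empty)) {
    warning("columns with zero feature expression get uniform topics: ",
            paste(utils::head(colnames(x_new)[empty], 5), collapse = ", "))
  }
  expElogbeta <- exp(dirichlet_expectation(model$lambda))
  alpha <- model$params$alpha
  gamma0 <- matrix(1, ncol(x_new), k)  # deterministic fold-in start
  es <- lda_estep(t(x_new), expElogbeta, alpha, max_iter = max_iter,
                  tol = tol, gamma_init = gamma0, sstats = FALSE)
  Y <- t(es$gamma / rowSums(es$gamma))
  if (any(empty)) Y[, empty] <- 1 / k
  dimnames(Y) <- list(rownames(model$phi), colnames(x_new))
  Y
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("LDA topic model: ", nrow(x$phi), " topics over ", ncol(x$phi),
      " genes, trained on ", ncol(x$Z), " cells\n", sep = "")
  cat("  alpha = ", signif(x$params$alpha, 4), ", beta = ", x$params$beta,
      ", passes = ", x$params$passes, ", seed = ", x$params$seed, "\n",
      sep = "")
  invisible(x)
}
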
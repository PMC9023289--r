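# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state, so seeded package functions do not perturb the
#' user's random stream. A `NULL` seed evaluates `code` under the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) m <- as.matrix(m)
  if (!is.matrix(m)) m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

# Validate a genes x columns expression matrix: dimnames present, unique, no
# negative or missing entries.
validate_expression_matrix <- function(m, what = "matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must carry gene (row) and cell/spot (column) identifiers")
  }
  dup_r <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_r)) {
    stop(what, " has duplicated gene identifiers: ",
         paste(utils::head(dup_r, 5), collapse = ", "))
  }
  dup_c <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_c)) {
    stop(what, " has duplicated column identifiers: ",
         paste(utils::head(dup_c, 5), collapse = ", "))
  }
  if (anyNA(m)) stop(what, " contains missing values")
  if (min(m) < 0) stop(what, " contains negative values")
  invisible(m)
}

is_count_matrix <- function(m) {
  all(abs(m - round(m)) < 1e-8)
}

# Largest-remainder apportionment of n items to proportions p (named).
# Ties on remainder broken by larger proportion, then by name.
largest_remainder <- function(p, n) {
  stopifnot(n >= 0, all(p >= 0))
  if (sum(p) <= 0) stop("proportions sum to zero")
  p <- p / sum(p)
  raw <- n * p
  q <- floor(raw + 1e-12)
  left <- n - sum(q)
  if (left > 0) {
    rem <- raw - q
    ord <- order(-rem, -p, names(p) %||% seq_along(p))
    q[ord[seq_len(left)]] <- q[ord[seq_len(left)]] + 1
  }
  storage.mode(q) <- "integer"
  q
}

# Column-wise cosine similarity between one vector y and the columns of Z.
cosine_to_columns <- function(Z, y) {
  ny <- sqrt(sum(y^2))
  nz <- sqrt(colSums(Z^2))
  s <- as.vector(crossprod(Z, y)) / (nz * ny)
  s[!is.finite(s)] <- 0
  s
}

# Format numerics at 6 significant digits for TSV output.
fmt6 <- function(x) {
  if (is.numeric(x)) format(signif(x, 6), trim = TRUE, scientific = FALSE) else x
}
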
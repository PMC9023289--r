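# Shared fixtures, lazily built once per test run. The block fixture plants
# per-type marker gene blocks, so the generator itself carries the ground
# truth used by recovery tests.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

block5 <- function() cached("block5", make_block_fixture(seed = 7))

block3 <- function() {
  cached("block3",
         make_block_fixture(n_types = 3, cells_per_type = 80, seed = 9))
}

# Fitted model on the 5-type fixture at k = 10 (2 topics per type), reused by
# deconvolution, domain and acceptance tests.
model5 <- function() {
  cached("model5", {
    fx <- block5()
    suppressWarnings(fit_celltopics(fx$counts, fx$labels, ks = 10, seed = 1))
  })
}

# Hand-built tables exercised by the worked examples: two types A/B over two
# topics with prior (2/3, 1/3).
hand_tables <- function() {
  T_mat <- matrix(c(0.7, 0.3, 0.1, 0.9), 2, 2,
                  dimnames = list(c("topic1", "topic2"), c("A", "B")))
  Q <- c(A = 2 / 3, B = 1 / 3)
  list(T_mat = T_mat, Q = Q)
}

tme_types <- function() {
  c("Malignant", "CD4T", "CD8T", "Tprolif", "B", "Plasma", "Mono/Macro",
    "Mast", "Endothelial", "Fibroblasts", "Myofibroblasts")
}

tme_fixture <- function() {
  cached("tme_fixture",
         make_block_fixture(n_types = 11, genes_per_type = 20,
                            cells_per_type = 60, depth = 2000,
                            type_names = tme_types(), seed = 3))
}

# Enumerate all permutations of 1..n (used as the exhaustive OT oracle).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) out <- c(out, list(append(p, n, after = pos)))
  }
  out
}

# Strip bookkeeping attributes (is_integer, gene_sd) before strict comparison.
bare <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
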
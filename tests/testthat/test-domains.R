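grid_coords <- function(xy, prefix = "s") {
  data.frame(spot_id = paste0(prefix, seq_len(nrow(xy))),
             x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

test_that("neighborhood composition averages the nearest spots", {
  # 3 collinear spots at unit spacing, k = 2: the middle spot averages the
  # two flanks
  ST <- matrix(c(1, 0, 0.5, 0.5, 0, 1), 2, 3,
               dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  co <- grid_coords(cbind(0:2, 0))
  nb <- neighborhood_composition(ST, co, k = 2)
  expect_equal(unname(nb[, "s2"]), c((1 + 0) / 2, (0 + 1) / 2))
  # identical compositions stay identical
  ST2 <- matrix(0.5, 2, 3, dimnames = dimnames(ST))
  expect_equal(neighborhood_composition(ST2, co, k = 2), ST2)
  # a single spot keeps its own composition
  expect_equal(neighborhood_composition(ST[, 1, drop = FALSE], co[1, ], k = 2),
               ST[, 1, drop = FALSE])
})

test_that("domain clustering separates two composition blobs", {
  set.seed(51)
  n <- 40
  xy <- rbind(cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5)),
              cbind(rnorm(n, 10, 0.5), rnorm(n, 10, 0.5)))
  ST <- cbind(matrix(rep(c(0.9, 0.1), n), 2),
              matrix(rep(c(0.1, 0.9), n), 2))
  dimnames(ST) <- list(c("A", "B"), paste0("s", 1:(2 * n)))
  co <- grid_coords(xy)
  cl <- cluster_domains(ST, co, k_clusters = 2, seed = 3)
  expect_equal(length(unique(cl[1:n])), 1)
  expect_equal(length(unique(cl[(n + 1):(2 * n)])), 1)
  expect_false(cl[1] == cl[n + 1])
})

test_that("weight 1 ignores the spatial neighborhood", {
  set.seed(52)
  ST <- matrix(rgamma(40, 1), 2)
  ST <- sweep(ST, 2, colSums(ST), "/")
  dimnames(ST) <- list(c("A", "B"), paste0("s", 1:20))
  co1 <- grid_coords(cbind(runif(20), runif(20)))
  co2 <- grid_coords(cbind(runif(20) * 50, runif(20) * 50))
  cl1 <- cluster_domains(ST, co1, k_clusters = 2, weight = 1, seed = 9)
  cl2 <- cluster_domains(ST, co2, k_clusters = 2, weight = 1, seed = 9)
  expect_identical(cl1, cl2)
})

test_that("clustering is invariant to spot ordering up to label renaming", {
  set.seed(53)
  ST <- matrix(rgamma(60, 1), 3)
  ST <- sweep(ST, 2, colSums(ST), "/")
  dimnames(ST) <- list(c("A", "B", "C"), paste0("s", 1:20))
  co <- grid_coords(cbind(runif(20), runif(20)))
  cl <- cluster_domains(ST, co, k_clusters = 3, seed = 7)
  ord <- sample(20)
  co2 <- co[ord, ]
  cl2 <- cluster_domains(ST[, ord], co2, k_clusters = 3, seed = 7)[names(cl)]
  # same partition: cluster co-membership must agree
  same1 <- outer(cl, cl, "==")
  same2 <- outer(cl2, cl2, "==")
  expect_identical(same1, same2)
  expect_error(cluster_domains(ST, co, k_clusters = 21), "exceeds")
})

test_that("region labels follow the distance-to-core rules", {
  # core at x = 0..1, other spots strung out along x
  xy <- cbind(c(0, 1, 2, 3, 5, 10, 1 + 4), 0)
  co <- grid_coords(xy)
  cl <- stats::setNames(c(1, 1, 2, 2, 2, 2, 2), co$spot_id)
  reg <- define_regions(cl, co, core_cluster = 1, threshold = 4)
  expect_equal(reg$region[1:2], c("core", "core"))
  expect_equal(reg$distance_to_core[1:2], c(0, 0))
  expect_equal(reg$region[3], "edge")      # distance 1 from core
  expect_equal(reg$distance_to_core[4], 2)
  expect_equal(reg$region[5], "border")    # distance 4 exactly: tie -> border
  expect_equal(reg$distance_to_core[5], 4)
  expect_equal(reg$region[6], "stroma")    # distance 9 > 4
  expect_equal(reg$region[7], "border")
  # regions partition non-core spots
  expect_false(any(reg$region == "core" & reg$distance_to_core > 0))
  expect_true(all(reg$region %in% c("core", "edge", "border", "stroma")))
  expect_error(define_regions(cl, co, core_cluster = 99), "empty")
})

test_that("largest-remainder quotas match the brute-force apportionment", {
  q <- spotdecon:::largest_remainder(c(A = 0.55, B = 0.45), 10)
  expect_equal(unname(q), c(6L, 4L))
  expect_equal(sum(q), 10)
  # exhaustive check against the definition on random cases
  set.seed(61)
  for (rep in 1:50) {
    p <- rgamma(4, 1)
    p <- p / sum(p)
    names(p) <- c("A", "B", "C", "D")
    n <- sample(1:12, 1)
    q <- spotdecon:::largest_remainder(p, n)
    expect_equal(sum(q), n)
    expect_true(all(q >= floor(n * p) - 1e-9))
    expect_true(all(q <= ceiling(n * p) + 1e-9))
  }
})

test_that("cosine ranking is scale-invariant and selects the matching cell", {
  model <- model5()
  fx <- block5()
  Z <- model$lda$Z
  y <- Z[, 5]
  s1 <- spotdecon:::cosine_to_columns(Z, y)
  s2 <- spotdecon:::cosine_to_columns(Z * 7, y * 3)
  expect_equal(order(-s1), order(-s2))
  expect_equal(unname(which.max(s1)), 5L)
})

test_that("cell mapping fills quotas with the most similar cells", {
  # 20-cell toy with known topic profiles: brute-force oracle
  set.seed(63)
  K <- 4
  Z <- matrix(rgamma(K * 20, 1), K)
  Z <- sweep(Z, 2, colSums(Z), "/")
  colnames(Z) <- paste0("c", 1:20)
  rownames(Z) <- paste0("topic", 1:K)
  labels <- stats::setNames(rep(c("A", "B"), each = 10), colnames(Z))
  Y <- matrix(rgamma(K, 1), K)
  Y <- Y / sum(Y)
  colnames(Y) <- "s1"
  rownames(Y) <- rownames(Z)
  ST <- matrix(c(0.55, 0.45), 2, 1, dimnames = list(c("A", "B"), "s1"))
  res <- map_cells_to_spots(Z, Y, ST, labels)
  sel <- res$cells
  expect_equal(nrow(sel), 10)
  expect_equal(sum(sel$cell_type == "A"), 6)
  expect_equal(sum(sel$cell_type == "B"), 4)
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (ty in c("A", "B")) {
    pool <- names(labels)[labels == ty]
    sims <- vapply(pool, function(cid) cosim(Z[, cid], Y[, 1]), numeric(1))
    want <- names(sort(sims, decreasing = TRUE))[seq_len(sum(sel$cell_type == ty))]
    expect_setequal(sel$cell_id[sel$cell_type == ty], want)
  }
  # spot identical to one cell's profile: that cell is selected
  Y2 <- Z[, "c3", drop = FALSE]
  colnames(Y2) <- "s2"
  ST2 <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("A", "B"), "s2"))
  res2 <- map_cells_to_spots(Z, Y2, ST2, labels)
  expect_true("c3" %in% res2$cells$cell_id)
})

test_that("quota beyond the pool recycles cells and pools expression by type", {
  set.seed(64)
  Z <- matrix(rgamma(12, 1), 3)
  Z <- sweep(Z, 2, colSums(Z), "/")
  dimnames(Z) <- list(paste0("topic", 1:3), paste0("c", 1:4))
  labels <- stats::setNames(c("A", "A", "A", "B"), colnames(Z))
  Y <- Z[, 1, drop = FALSE]
  colnames(Y) <- "s1"
  ST <- matrix(c(0.2, 0.8), 2, 1, dimnames = list(c("A", "B"), "s1"))
  counts <- matrix(rpois(20, 5), 5, 4,
                   dimnames = list(paste0("g", 1:5), colnames(Z)))
  expect_warning(res <- map_cells_to_spots(Z, Y, ST, labels,
                                           sc_counts = counts, n_cells = 10),
                 "recycled")
  expect_equal(nrow(res$cells), 10)
  expect_equal(sum(res$cells$cell_type == "B"), 8)
  pooled <- res$pooled[["s1"]]
  expect_equal(sort(colnames(pooled)), c("A", "B"))
  # pooled column equals the sum of the selected cells' counts
  idsB <- res$cells$cell_id[res$cells$cell_type == "B"]
  expect_equal(unname(pooled[, "B"]),
               unname(rowSums(counts[, idsB, drop = FALSE])))
})
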
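test_that("LDA separates two disjoint gene blocks into two topics", {
  # disjoint blocks only: every gene belongs to one type's block
  fx <- make_block_fixture(n_types = 2, genes_per_type = 15,
                           cells_per_type = 40, depth = 1000, noise = 0.05,
                           background_genes = 0, seed = 21)
  x <- normalize_counts(fx$counts)
  fit <- train_lda(x, k = 2, seed = 4)
  expect_s3_class(fit, "lda_fit")
  # topic-block association: each topic's top genes lie in one planted block
  top_genes <- apply(fit$phi, 1, function(p) {
    names(sort(p, decreasing = TRUE))[1:10]
  })
  in_block1 <- colMeans(matrix(top_genes %in% fx$marker_blocks[[1]], 10))
  expect_true(any(in_block1 > 0.9) && any(in_block1 < 0.1))
  # cells load >= 0.9 on their group's topic
  dom_topic <- apply(fit$Z, 2, which.max)
  for (ty in unique(fx$labels)) {
    cells <- names(fx$labels)[fx$labels == ty]
    major <- as.integer(names(which.max(table(dom_topic[cells]))))
    expect_gte(mean(fit$Z[major, cells]), 0.9)
  }
})

test_that("LDA training is deterministic given the seed", {
  fx <- block3()
  x <- normalize_counts(fx$counts[, 1:60])
  f1 <- train_lda(x, k = 3, passes = 5, seed = 99)
  f2 <- train_lda(x, k = 3, passes = 5, seed = 99)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$Z, f2$Z)
})

test_that("identical cells get approximately equal topic loadings", {
  x <- matrix(rep(c(3, 1, 2, 5, 0.5), 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:12)))
  fit <- train_lda(x, k = 2, passes = 5, seed = 1)
  spread <- apply(fit$Z, 1, function(r) max(r) - min(r))
  expect_lt(max(spread), 0.05)
})

test_that("LDA rejects invalid shapes", {
  x <- matrix(1, 5, 3, dimnames = list(paste0("g", 1:5), paste0("c", 1:3)))
  expect_error(train_lda(x, k = 3), "smaller than the number of cells")
  expect_error(train_lda(x, k = 1), "at least 2")
  expect_error(train_lda(x[, 0], k = 2), "empty")
})

test_that("type profile T averages Z within types and is permutation-invariant", {
  # one cell per type: T column equals that cell's Z column
  Z1 <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2,
               dimnames = list(NULL, c("c1", "c2")))
  T1 <- type_topic_profile(Z1, c(c1 = "A", c2 = "B"))
  expect_equal(unname(T1), unname(Z1))
  # forced arithmetic mean
  Z <- matrix(c(0.8, 0.2, 0.6, 0.4, 0.1, 0.9), 2, 3,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  labels <- c(c1 = "A", c2 = "A", c3 = "B")
  T_mat <- type_topic_profile(Z, labels)
  expect_equal(unname(T_mat[, "A"]), c(0.7, 0.3))
  expect_equal(unname(T_mat[, "B"]), c(0.1, 0.9))
  expect_equal(colSums(T_mat), c(A = 1, B = 1))
  # shuffling cells leaves T unchanged
  ord <- c(3, 1, 2)
  expect_equal(type_topic_profile(Z[, ord], labels[ord]), T_mat)
})

test_that("Bayes inversion reproduces the hand-computed tables", {
  ht <- hand_tables()
  post <- celltype_topic_posterior(ht$T_mat, ht$Q)
  expect_equal(unname(post$P), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(unname(post$C["A", ]), c(14 / 15, 2 / 5), tolerance = 1e-10)
  expect_equal(unname(post$C["B", ]), c(1 / 15, 3 / 5), tolerance = 1e-10)
  expect_equal(unname(colSums(post$C)), c(1, 1), tolerance = 1e-12)
})

test_that("Bayes inversion handles degenerate priors and single classes", {
  T1 <- matrix(c(0.3, 0.7), 2, 1, dimnames = list(NULL, "only"))
  post <- celltype_topic_posterior(T1, c(only = 1))
  expect_equal(unname(post$C), matrix(1, 1, 2))
  # identical types with equal prior: all C entries 1/2
  T2 <- matrix(c(0.4, 0.6, 0.4, 0.6), 2, 2, dimnames = list(NULL, c("A", "B")))
  post2 <- celltype_topic_posterior(T2, c(A = 0.5, B = 0.5))
  expect_equal(unname(post2$C), matrix(0.5, 2, 2))
  # unused topic is an error
  T3 <- matrix(c(0, 1, 0, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(celltype_topic_posterior(T3, c(A = 0.5, B = 0.5)), "unused")
})

test_that("cell annotation reproduces the hand-computed scores and tie rule", {
  ht <- hand_tables()
  post <- celltype_topic_posterior(ht$T_mat, ht$Q)
  Z <- matrix(c(0.1, 0.9), 2, 1, dimnames = list(NULL, "cell"))
  ann <- annotate_cells(post$C, Z)
  expect_equal(ann$prob["A", "cell"], 0.45333, tolerance = 1e-4)
  expect_equal(ann$prob["B", "cell"], 0.54667, tolerance = 1e-4)
  expect_identical(unname(ann$labels), "B")
  # identity-like C: label = dominant topic's type
  Cid <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), NULL))
  Z2 <- matrix(c(0.3, 0.7, 0.8, 0.2), 2, 2,
               dimnames = list(NULL, c("c1", "c2")))
  expect_identical(unname(annotate_cells(Cid, Z2)$labels), c("B", "A"))
  # exact tie goes to the lexicographically first type
  Ctie <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                 dimnames = list(c("zeta", "alpha"), NULL))
  expect_identical(unname(annotate_cells(Ctie, Z2)$labels),
                   c("alpha", "alpha"))
})

test_that("probability tables conserve mass and invert algebraically", {
  model <- model5()
  fx <- block5()
  Z <- model$lda$Z
  T_mat <- model$T_mat
  C <- model$C
  expect_lt(max(abs(colSums(T_mat) - 1)), 1e-8)
  expect_lt(max(abs(colSums(C) - 1)), 1e-8)
  expect_lt(max(abs(colSums(Z) - 1)), 1e-8)
  SC <- annotate_cells(C, Z)$prob
  expect_lt(max(abs(colSums(SC) - 1)), 1e-8)
  # T_kn = C_nk P_k / Q_n recovers T
  T_back <- t(C * rep(model$P, each = nrow(C))) /
    rep(model$Q[colnames(T_mat)], each = nrow(T_mat))
  expect_equal(T_back, T_mat, tolerance = 1e-10)
})

test_that("re-annotation accuracy is high at k = 2x the number of types", {
  model <- model5()
  fx <- block5()
  acc <- mean(model$annotation$labels == fx$labels[names(model$annotation$labels)])
  expect_gte(acc, 0.95)
})

test_that("topic-number selection prefers the simplest model among ties", {
  fx <- block5()
  m <- suppressWarnings(fit_celltopics(fx$counts, fx$labels, ks = c(5, 10),
                                       seed = 1))
  expect_equal(m$accuracy$accuracy[1], m$accuracy$accuracy[2])
  expect_equal(nrow(m$lda$phi), 5)
})

test_that("accuracy at k >= n_types dominates an undersized model", {
  fx <- block3()
  m <- suppressWarnings(fit_celltopics(fx$counts, fx$labels,
                                       ks = c(2, 3, 6, 9), seed = 1))
  acc <- stats::setNames(m$accuracy$accuracy, m$accuracy$k)
  expect_true(all(acc[c("3", "6", "9")] >= acc["2"]))
  best <- max(acc)
  expect_equal(nrow(m$lda$phi),
               min(m$accuracy$k[m$accuracy$accuracy >= best - 1e-12]))
})

test_that("fitted model exposes the modelling-idiom surface", {
  model <- model5()
  expect_s3_class(model, "celltopic_model")
  expect_identical(coef(model), model$C)
  expect_output(print(model), "Cell-type topic model")
  s <- summary(model)
  expect_s3_class(s, "summary.celltopic_model")
  expect_length(s$topic_type, nrow(model$lda$phi))
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(model))
  grDevices::dev.off()
})
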
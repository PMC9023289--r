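test_that("down-sampling conserves totals and never exceeds the input", {
  v <- c(a = 100L, b = 0L, c = 50L, d = 3L)
  expect_identical(downsample_counts(v, 200, seed = 1), v)
  out <- downsample_counts(v, 60, seed = 1)
  expect_equal(sum(out), 60)
  expect_true(all(out <= v))
  expect_true(all(out >= 0))
  expect_error(downsample_counts(v, -1), "non-negative")
})

test_that("down-sampling is hypergeometric: mass shares are preserved", {
  # one gene holds 50% of the input; after sampling 10000 of 40000 molecules
  # its share stays 50% within the 99% hypergeometric interval
  v <- c(big = 20000, rep(100, 200))
  out <- downsample_counts(v, 10000, seed = 5)
  n_draw <- 10000
  p <- 0.5
  sdev <- sqrt(n_draw * p * (1 - p) * (sum(v) - n_draw) / (sum(v) - 1))
  ci <- 2.58 * sdev
  expect_lt(abs(out[["big"]] - n_draw * p), ci)
})

test_that("random spots mix 2-10 cells and record exact truth", {
  fx <- block3()
  sim <- simulate_random_spots(fx$counts, fx$labels, n_spots = 50, seed = 2)
  expect_equal(ncol(sim$counts), 50)
  ncells <- lengths(sim$provenance)
  expect_true(all(ncells >= 2 & ncells <= 10))
  expect_lt(max(abs(colSums(sim$truth) - 1)), 1e-12)
  for (j in c(1, 17, 50)) {
    cells <- sim$provenance[[j]]
    expect_equal(unname(sim$truth[, j]),
                 as.numeric(table(factor(fx$labels[cells],
                                         levels = rownames(sim$truth))) /
                              length(cells)))
    v <- rowSums(fx$counts[, cells, drop = FALSE])
    if (sum(v) <= 25000) {
      expect_equal(unname(sim$counts[, j]), unname(v))
    } else {
      expect_equal(sum(sim$counts[, j]), 20000)
      expect_true(all(sim$counts[, j] <= v))
    }
  }
  expect_error(simulate_random_spots(fx$counts, fx$labels, 5,
                                     cells_max = ncol(fx$counts) + 1),
               "cells_max")
})

test_that("the UMI cap down-samples spots above 25000 to exactly 20000", {
  # deep fixture so 10-cell spots exceed the cap; shallow spots stay intact
  fx <- make_block_fixture(n_types = 2, cells_per_type = 20, depth = 4000,
                           seed = 13)
  sim <- simulate_random_spots(fx$counts, fx$labels, n_spots = 40,
                               cells_min = 8, cells_max = 10, seed = 3)
  totals <- colSums(sim$counts)
  raw <- vapply(sim$provenance,
                function(cells) sum(fx$counts[, cells]), numeric(1))
  expect_true(all(totals[raw > 25000] == 20000))
  expect_true(any(raw > 25000))
  expect_equal(unname(totals[raw <= 25000]), raw[raw <= 25000])
})

test_that("depth series shares truth, hits requested depths, and nests", {
  fx <- block3()
  depths <- c(4000, 2000, 1000)
  series <- simulate_depth_series(fx$counts, fx$labels, n_spots = 25,
                                  cells_per_spot = 10, depths = depths,
                                  seed = 6)
  expect_named(series, paste0("depth", depths))
  base_tot <- vapply(series[[1]]$provenance,
                     function(cells) sum(fx$counts[, cells]), numeric(1))
  for (d in seq_along(depths)) {
    tot <- colSums(series[[d]]$counts)
    expect_equal(unname(tot), unname(pmin(depths[d], base_tot)))
    expect_identical(series[[d]]$truth, series[[1]]$truth)
  }
  # nested mode: shallower levels are contained in deeper ones
  expect_true(all(series[["depth1000"]]$counts <= series[["depth2000"]]$counts))
  expect_true(all(series[["depth2000"]]$counts <= series[["depth4000"]]$counts))
})

test_that("TME compartments have the designed sizes and exclusions", {
  fx <- tme_fixture()
  sim <- simulate_tme(fx$counts, fx$labels, seed = 5)
  expect_equal(unname(table(sim$region)[c("TC", "IM", "TS", "TLS")]),
               rep(250L, 4), ignore_attr = TRUE)
  # types without a mark in a compartment column never appear there
  expect_true(all(sim$truth["Malignant", sim$region == "TLS"] == 0))
  expect_true(all(sim$truth["Fibroblasts", sim$region == "TC"] == 0))
  expect_true(all(sim$truth["B", sim$region == "TC"] == 0))
  expect_true(all(sim$truth["Mast", sim$region == "TLS"] == 0))
  expect_lt(max(abs(colSums(sim$truth) - 1)), 1e-12)
  # fixed-mean fractions sit near their designed values
  tc <- sim$region == "TC"
  expect_equal(mean(sim$truth["Malignant", tc]), 0.5, tolerance = 0.05)
  expect_equal(mean(sim$truth["CD8T", tc]), 0.3, tolerance = 0.05)
})

test_that("declared pairs are co-localized with correlation near 0.7", {
  fx <- tme_fixture()
  sim <- simulate_tme(fx$counts, fx$labels, seed = 5)
  pairs <- list(TC = c("Malignant", "CD8T"),
                IM = c("Malignant", "Fibroblasts"),
                TLS = c("CD4T", "B"))
  for (rg in names(pairs)) {
    idx <- sim$region == rg
    r <- stats::cor(sim$truth[pairs[[rg]][1], idx],
                    sim$truth[pairs[[rg]][2], idx])
    expect_lt(abs(r - 0.7), 0.1)
  }
})

test_that("every simulated spot equals the down-sampled sum of its cells", {
  fx <- tme_fixture()
  sim <- simulate_tme(fx$counts, fx$labels, seed = 5)
  set.seed(1)
  for (j in sample(ncol(sim$counts), 20)) {
    v <- rowSums(fx$counts[, sim$provenance[[j]], drop = FALSE])
    if (sum(v) <= 25000) {
      expect_equal(unname(sim$counts[, j]), unname(v))
    } else {
      expect_equal(sum(sim$counts[, j]), 20000)
      expect_true(all(sim$counts[, j] <= v))
    }
  }
})

test_that("infeasible compartment rules are rejected", {
  fx <- block3()
  bad <- list(list(region = "X", n_spots = 10,
                   fixed = c(type1 = 0.7, type2 = 0.5),
                   pair = c("type1", "type2"), free = "type3"))
  expect_error(simulate_tme(fx$counts, fx$labels, rules = bad), "infeasible")
  unknown <- list(list(region = "X", n_spots = 10,
                       fixed = c(ghost = 0.3, type2 = 0.3),
                       pair = c("ghost", "type2"), free = "type3"))
  expect_error(simulate_tme(fx$counts, fx$labels, rules = unknown), "ghost")
})

test_that("the block fixture is reproducible and shaped as designed", {
  f1 <- make_block_fixture(n_types = 5, genes_per_type = 20, seed = 42)
  f2 <- make_block_fixture(n_types = 5, genes_per_type = 20, seed = 42)
  expect_identical(f1$counts, f2$counts)
  expect_identical(f1$labels, f2$labels)
  expect_equal(length(unlist(f1$marker_blocks)), 100)
  expect_equal(nrow(f1$counts), 200)  # 100 markers + 100 background genes
  expect_equal(unname(colSums(f1$counts)[1:3]), rep(2000, 3))
  # a type's marker block is enriched in its own cells
  own <- mean(f1$counts[f1$marker_blocks[["type1"]], f1$labels == "type1"])
  other <- mean(f1$counts[f1$marker_blocks[["type1"]], f1$labels != "type1"])
  expect_gt(own, 3 * other)
})
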
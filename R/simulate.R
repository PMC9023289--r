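# Ground-truth spot simulators: fully random cell mixtures, a
# sequencing-depth series, and a structured tumor-microenvironment design with
# co-localized cell-type pairs; plus the labeled block-marker fixture used as
# a stand-in single-cell reference throughout the test suite.

#' Down-sample a count vector to a target total
#'
#' Draws `target` molecules without replacement from the multiset of observed
#' molecules (multivariate hypergeometric), so the output sum is exactly
#' `min(target, sum(v))` and the output never exceeds the input elementwise.
#'
#' @param v Non-negative integer vector.
#' @param target Target total count.
#' @param seed Optional seed.
#' @return Integer vector of the same length and names as `v`.
#' @export
downsample_counts <- function(v, target, seed = NULL) {
  if (target < 0) stop("target must be non-negative")
  if (any(v < 0) || any(abs(v - round(v)) > 1e-8)) {
    stop("v must hold non-negative integer counts")
  }
  nm <- names(v)
  v <- stats::setNames(as.integer(round(v)), nm)
  total <- sum(v)
  if (target >= total) return(v)
  with_seed(seed, {
    out <- integer(length(v))
    rest <- total
    need <- as.integer(target)
    for (i in which(v > 0L)) {
      if (need == 0L) break
      x <- stats::rhyper(1L, v[i], rest - v[i], need)
      out[i] <- x
      need <- need - x
      rest <- rest - v[i]
    }
    names(out) <- names(v)
    out
  })
}

new_sim_spots <- function(counts, truth, provenance, region = NULL) {
  structure(list(counts = counts, truth = truth, provenance = provenance,
                 region = region),
            class = "sim_spots")
}

#' @export
print.sim_spots <- function(x, ...) {
  cat("Simulated spots: ", ncol(x$counts), " spots x ", nrow(x$counts),
      " genes, ", nrow(x$truth), " cell types\n", sep = "")
  if (!is.null(x$region)) {
    print(table(x$region))
  }
  invisible(x)
}

aggregate_cells <- function(sc, cells) {
  if (length(cells) == 1L) sc[, cells] else rowSums(sc[, cells, drop = FALSE])
}

truth_from_cells <- function(cells, labels, types) {
  tab <- table(factor(labels[cells], levels = types))
  as.numeric(tab) / length(cells)
}

#' Simulate fully random spot mixtures
#'
#' Each spot aggregates the raw counts of a uniform random number of cells
#' (between `cells_min` and `cells_max`) sampled without replacement from the
#' reference; spots exceeding `umi_cap` total counts are down-sampled to
#' `umi_target`. The ground truth is the cell-type frequency among the
#' selected cells.
#'
#' @param sc Raw integer count matrix, genes x cells.
#' @param labels Cell-type labels for the columns of `sc`.
#' @param n_spots Number of spots to simulate.
#' @param cells_min,cells_max Range of cells per spot (default 2-10).
#' @param umi_cap,umi_target Cap/down-sampling rule (default: spots over
#'   25000 total counts are down-sampled to 20000).
#' @param seed Seed.
#' @return A `sim_spots` object: `counts` (genes x spots), `truth`
#'   (types x spots), `provenance` (list of source cell ids).
#' @export
simulate_random_spots <- function(sc, labels, n_spots, cells_min = 2,
                                  cells_max = 10, umi_cap = 25000,
                                  umi_target = 20000, seed = 1) {
  sc <- as_dense(sc)
  labels <- labels[colnames(sc)]
  if (anyNA(labels)) stop("labels missing for some cells")
  if (cells_max > ncol(sc)) stop("cells_max exceeds the number of cells")
  types <- sort(unique(labels))
  with_seed(seed, {
    counts <- matrix(0, nrow(sc), n_spots)
    truth <- matrix(0, length(types), n_spots)
    prov <- vector("list", n_spots)
    for (j in seq_len(n_spots)) {
      ncell <- if (cells_min == cells_max) cells_min
               else sample(seq.int(cells_min, cells_max), 1L)
      cells <- sample(colnames(sc), ncell)
      v <- aggregate_cells(sc, cells)
      if (sum(v) > umi_cap) v <- downsample_counts(v, umi_target)
      counts[, j] <- v
      truth[, j] <- truth_from_cells(cells, labels, types)
      prov[[j]] <- cells
    }
    dimnames(counts) <- list(rownames(sc),
                             paste0("spot", seq_len(n_spots)))
    dimnames(truth) <- list(types, colnames(counts))
    new_sim_spots(counts, truth, prov)
  })
}

#' Simulate a sequencing-depth series
#'
#' Generates one base set of spots (`cells_per_spot` random cells each,
#' aggregated without a cap) and down-samples every spot to each requested
#' depth. In the default nested mode each depth level is a subsample of the
#' previous (shallower levels are contained in deeper ones); independent mode
#' subsamples each level from the base counts. Ground truth is shared across
#' levels. Spots whose base total is below a depth keep their own total, with
#' a warning.
#'
#' @param sc,labels,seed As in [simulate_random_spots()].
#' @param n_spots Number of spots (default 1000).
#' @param cells_per_spot Cells aggregated per spot (default 10).
#' @param depths Depth levels, default `c(20000, 15000, 10000, 5000, 2500,
#'   1000)`.
#' @param nested Nested subsampling across levels (default `TRUE`).
#' @return Named list of `sim_spots`, one per depth (names `"depth<d>"`),
#'   all sharing `truth` and `provenance`.
#' @export
simulate_depth_series <- function(sc, labels, n_spots = 1000,
                                  cells_per_spot = 10,
                                  depths = c(20000, 15000, 10000, 5000,
                                             2500, 1000),
                                  nested = TRUE, seed = 1) {
  base <- simulate_random_spots(sc, labels, n_spots,
                                cells_min = cells_per_spot,
                                cells_max = cells_per_spot,
                                umi_cap = Inf, seed = seed)
  depths <- sort(depths, decreasing = TRUE)
  with_seed(seed + 1L, {
    out <- vector("list", length(depths))
    names(out) <- paste0("depth", depths)
    prev <- base$counts
    shallow <- 0L
    for (d in seq_along(depths)) {
      src <- if (nested) prev else base$counts
      cur <- src
      for (j in seq_len(ncol(src))) {
        tot <- sum(src[, j])
        if (tot <= depths[d]) {
          shallow <- shallow + 1L
        } else {
          cur[, j] <- downsample_counts(src[, j], depths[d])
        }
      }
      out[[d]] <- new_sim_spots(cur, base$truth, base$provenance)
      prev <- cur
    }
    if (shallow > 0L) {
      warning(shallow, " spot/depth combinations had totals below the ",
              "requested depth and were kept at their own totals")
    }
    out
  })
}

#' Default tumor-microenvironment simulation rules
#'
#' Encodes the structured design of a typical tumor tissue: tumor core (TC),
#' invasive margin (IM), tumor stroma (TS, split into two co-localization
#' variants) and tertiary lymphoid structure (TLS). Each compartment fixes
#' the mean fractions of one correlated cell-type pair, allows a stated set
#' of further types with random fractions, and excludes everything else.
#'
#' @return List of compartment rules (region, n_spots, fixed fractions, the
#'   correlated pair, allowed free types).
#' @export
tme_default_rules <- function() {
  list(
    list(region = "TC", n_spots = 250,
         fixed = c(Malignant = 0.5, CD8T = 0.3),
         pair = c("Malignant", "CD8T"),
         free = c("CD4T", "Mono/Macro", "Mast")),
    list(region = "IM", n_spots = 250,
         fixed = c(Malignant = 0.3, Fibroblasts = 0.3),
         pair = c("Malignant", "Fibroblasts"),
         free = c("CD4T", "CD8T", "Tprolif", "B", "Plasma", "Mono/Macro",
                  "Mast", "Endothelial", "Myofibroblasts")),
    list(region = "TS", n_spots = 125,
         fixed = c(Fibroblasts = 0.5, CD4T = 0.3),
         pair = c("Fibroblasts", "CD4T"),
         free = c("CD8T", "Tprolif", "Plasma", "Endothelial",
                  "Myofibroblasts")),
    list(region = "TS", n_spots = 125,
         fixed = c(Fibroblasts = 0.5, B = 0.3),
         pair = c("Fibroblasts", "B"),
         free = c("CD8T", "Tprolif", "Plasma", "Endothelial",
                  "Myofibroblasts")),
    list(region = "TLS", n_spots = 250,
         fixed = c(CD4T = 0.3, B = 0.4),
         pair = c("CD4T", "B"),
         free = c("CD8T", "Plasma", "Endothelial"))
  )
}

# Draw per-spot fractions for one compartment rule. The correlated pair is
# drawn from a bivariate logit-normal whose latent correlation is calibrated
# at generation time (bisection on reused normal draws, monotone in the
# latent correlation) so that the realized Pearson correlation of the
# integer-realized proportions targets rho. Free types share the residual
# mass via a symmetric Dirichlet.
draw_compartment_fractions <- function(rule, rho, cells_per_spot,
                                       logit_scale = 0.25) {
  n <- rule$n_spots
  fixed <- rule$fixed
  if (sum(fixed) >= 1) stop("infeasible rule: fixed fractions sum to >= 1")
  free <- rule$free
  if (!length(free)) stop("each compartment rule needs free (random) types")
  z1 <- stats::rnorm(n)
  e <- stats::rnorm(n)
  dir_raw <- if (length(free)) {
    matrix(stats::rgamma(n * length(free), 1, 1), n, length(free))
  } else NULL
  mu <- stats::qlogis(fixed[rule$pair])

  realize <- function(r_z) {
    z2 <- r_z * z1 + sqrt(1 - r_z^2) * e
    f1 <- stats::plogis(mu[1] + logit_scale * z1)
    f2 <- stats::plogis(mu[2] + logit_scale * z2)
    over <- (f1 + f2) > 0.99
    scl <- ifelse(over, 0.99 / (f1 + f2), 1)
    f1 <- f1 * scl
    f2 <- f2 * scl
    frac <- matrix(0, n, length(fixed) + length(free))
    colnames(frac) <- c(rule$pair, free)
    frac[, 1] <- f1
    frac[, 2] <- f2
    w <- dir_raw / rowSums(dir_raw)
    frac[, free] <- w * (1 - f1 - f2)
    picks <- t(apply(frac, 1L, largest_remainder, n = cells_per_spot))
    colnames(picks) <- colnames(frac)
    picks
  }
  realized_cor <- function(r_z) {
    p <- realize(r_z) / cells_per_spot
    stats::cor(p[, 1], p[, 2])
  }
  lo <- 0
  hi <- 0.999
  if (realized_cor(hi) < rho) {
    r_z <- hi
  } else {
    for (it in 1:25) {
      mid <- (lo + hi) / 2
      if (realized_cor(mid) < rho) lo <- mid else hi <- mid
    }
    r_z <- (lo + hi) / 2
  }
  realize(r_z)
}

#' Simulate the structured tumor-microenvironment dataset
#'
#' Generates compartments of spots with fixed-mean correlated cell-type pairs
#' and random fractions for the allowed free types; cell types not named in a
#' compartment's rule never appear there. Per-spot proportions are realized
#' as integer cell picks (`cells_per_spot` cells, largest-remainder
#' apportionment), cells are drawn from the reference per type, and counts
#' are aggregated and capped as in [simulate_random_spots()]. The realized
#' Pearson correlation of each declared pair is calibrated to `rho`.
#'
#' @param sc,labels,seed As in [simulate_random_spots()].
#' @param rules Compartment rules; default [tme_default_rules()].
#' @param rho Target co-localization correlation (default 0.7).
#' @param cells_per_spot Cells realized per spot (default 10).
#' @param umi_cap,umi_target Down-sampling rule.
#' @return A `sim_spots` object with per-spot compartment labels in
#'   `$region`.
#' @export
simulate_tme <- function(sc, labels, rules = tme_default_rules(), rho = 0.7,
                         cells_per_spot = 10, umi_cap = 25000,
                         umi_target = 20000, seed = 1) {
  sc <- as_dense(sc)
  labels <- labels[colnames(sc)]
  if (anyNA(labels)) stop("labels missing for some cells")
  types <- sort(unique(labels))
  used <- unique(unlist(lapply(rules, function(r) c(names(r$fixed), r$free))))
  unknown <- setdiff(used, types)
  if (length(unknown)) {
    stop("rule cell types absent from labels: ",
         paste(unknown, collapse = ", "))
  }
  cells_by_type <- split(colnames(sc), labels)
  with_seed(seed, {
    blocks <- lapply(rules, function(rule) {
      picks <- draw_compartment_fractions(rule, rho, cells_per_spot)
      n <- nrow(picks)
      counts <- matrix(0, nrow(sc), n)
      truth <- matrix(0, length(types), n, dimnames = list(types, NULL))
      prov <- vector("list", n)
      for (j in seq_len(n)) {
        cells <- character(0)
        for (ty in colnames(picks)) {
          kk <- picks[j, ty]
          if (kk == 0L) next
          pool <- cells_by_type[[ty]]
          if (kk > length(pool)) {
            warning("cell type '", ty, "' has fewer cells than requested; ",
                    "sampling with replacement")
            cells <- c(cells, sample(pool, kk, replace = TRUE))
          } else {
            cells <- c(cells, sample(pool, kk))
          }
        }
        v <- aggregate_cells(sc, cells)
        if (sum(v) > umi_cap) v <- downsample_counts(v, umi_target)
        counts[, j] <- v
        prov[[j]] <- cells
      }
      # realized truth from the integer picks; types not in the rule stay 0
      truth[colnames(picks), ] <- t(picks) / cells_per_spot
      list(counts = counts, truth = truth, prov = prov,
           region = rep(rule$region, n))
    })
    counts <- do.call(cbind, lapply(blocks, `[[`, "counts"))
    truth <- do.call(cbind, lapply(blocks, `[[`, "truth"))
    prov <- do.call(c, lapply(blocks, `[[`, "prov"))
    region <- do.call(c, lapply(blocks, `[[`, "region"))
    colnames(counts) <- paste0("spot", seq_len(ncol(counts)))
    rownames(counts) <- rownames(sc)
    colnames(truth) <- colnames(counts)
    new_sim_spots(counts, truth, prov, region)
  })
}

#' Labeled block-marker single-cell fixture
#'
#' Generates a synthetic annotated scRNA-seq-like reference in which each
#' cell type owns a private block of high-rate marker genes on top of a
#' shared background: the expression profile of a type gives its own
#' `genes_per_type` markers `marker_strength` times the baseline weight, and
#' a `noise` fraction of each cell's reads is redistributed uniformly over
#' all genes. Counts are multinomial draws of `depth` reads per cell, so the
#' planted marker blocks are the ground truth for marker selection and
#' topic-recovery tests.
#'
#' @param n_types Number of cell types.
#' @param genes_per_type Private marker genes per type.
#' @param cells_per_type Cells per type.
#' @param depth Reads per cell.
#' @param noise Uniform leakage fraction in `[0, 1)` (default 0.1).
#' @param background_genes Shared background genes (default 100).
#' @param marker_strength Rate multiplier of a type's own markers (default 8).
#' @param type_names Optional cell-type names (default `type1..type_n`).
#' @param seed Seed.
#' @return List with `counts` (genes x cells), `labels` (named character
#'   vector) and `marker_blocks` (list of planted marker genes per type).
#' @export
make_block_fixture <- function(n_types = 5, genes_per_type = 20,
                               cells_per_type = 100, depth = 2000,
                               noise = 0.1, background_genes = 100,
                               marker_strength = 8, type_names = NULL,
                               seed = 1) {
  stopifnot(n_types >= 2, genes_per_type >= 1, cells_per_type >= 1,
            depth >= 1, noise >= 0, noise < 1)
  types <- type_names %||% paste0("type", seq_len(n_types))
  stopifnot(length(types) == n_types)
  G <- n_types * genes_per_type + background_genes
  genes <- sprintf("g%03d", seq_len(G))
  blocks <- split(genes[seq_len(n_types * genes_per_type)],
                  rep(seq_len(n_types), each = genes_per_type))
  names(blocks) <- types
  with_seed(seed, {
    counts <- matrix(0L, G, n_types * cells_per_type)
    labels <- character(ncol(counts))
    cellnames <- character(ncol(counts))
    j <- 0L
    for (t_i in seq_len(n_types)) {
      w <- rep(1, G)
      w[genes %in% blocks[[t_i]]] <- marker_strength
      p <- (1 - noise) * w / sum(w) + noise / G
      for (ci in seq_len(cells_per_type)) {
        j <- j + 1L
        counts[, j] <- stats::rmultinom(1L, depth, p)
        labels[j] <- types[t_i]
        cellnames[j] <- sprintf("%s_c%03d", types[t_i], ci)
      }
    }
    dimnames(counts) <- list(genes, cellnames)
    storage.mode(counts) <- "double"
    list(counts = counts,
         labels = stats::setNames(labels, cellnames),
         marker_blocks = blocks)
  })
}
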
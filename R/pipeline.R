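# End-to-end workflow runner: executes the simulate / train / deconvolve /
# evaluate / domains / align stages in dependency order from a flat config
# (list or YAML file), writes every result as TSV under the output directory,
# and skips stages whose inputs and parameters are unchanged (checksum
# stamps).

#' Write a fitted model as a directory of TSV tables
#'
#' Persists `phi`, `lambda`, `Z`, `T`, `C`, and the `Q`/`P` vectors plus the
#' accuracy table and feature list as plain TSV files, so a model can be
#' reloaded without binary artifacts.
#'
#' @param model A `celltopic_model`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_model_dir <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(m, f) {
    tab <- data.frame(id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    # full precision: the model must round-trip
    utils::write.table(tab, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  lam <- model$lda$lambda
  dimnames(lam) <- dimnames(model$lda$phi)
  wt(model$lda$phi, "phi.tsv")
  wt(lam, "lambda.tsv")
  wt(model$lda$Z, "Z.tsv")
  wt(model$T_mat, "T.tsv")
  wt(model$C, "C.tsv")
  write_result_table(data.frame(cell_type = names(model$Q), Q = model$Q,
                                stringsAsFactors = FALSE),
                     file.path(dir, "Q.tsv"))
  write_result_table(data.frame(topic = names(model$P), P = model$P,
                                stringsAsFactors = FALSE),
                     file.path(dir, "P.tsv"))
  write_result_table(model$accuracy, file.path(dir, "accuracy.tsv"))
  writeLines(model$features$genes, file.path(dir, "feature_genes.txt"))
  params <- model$lda$params
  yaml::write_yaml(c(params, list(scale_factor = model$scale_factor,
                                  feature_mode = model$features$mode)),
                   file.path(dir, "params.yaml"))
  write_result_table(data.frame(gene = names(model$gene_sd),
                                sd = model$gene_sd,
                                stringsAsFactors = FALSE),
                     file.path(dir, "gene_sd.tsv"))
  invisible(dir)
}

read_tsv_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Load a model directory written by [write_model_dir()]
#'
#' Rebuilds a `celltopic_model` sufficient for prediction (the training data
#' itself is not stored).
#'
#' @param dir Model directory.
#' @return A `celltopic_model`.
#' @export
read_model_dir <- function(dir) {
  phi <- read_tsv_matrix(file.path(dir, "phi.tsv"))
  lambda <- read_tsv_matrix(file.path(dir, "lambda.tsv"))
  Z <- read_tsv_matrix(file.path(dir, "Z.tsv"))
  T_mat <- read_tsv_matrix(file.path(dir, "T.tsv"))
  C <- read_tsv_matrix(file.path(dir, "C.tsv"))
  qtab <- utils::read.table(file.path(dir, "Q.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  ptab <- utils::read.table(file.path(dir, "P.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  params <- yaml::read_yaml(file.path(dir, "params.yaml"))
  sdtab <- utils::read.table(file.path(dir, "gene_sd.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  acc <- utils::read.table(file.path(dir, "accuracy.tsv"), sep = "\t",
                           header = TRUE)
  genes <- readLines(file.path(dir, "feature_genes.txt"))
  lda <- structure(list(phi = phi, Z = Z, lambda = lambda, genes = genes,
                        params = params),
                   class = "lda_fit")
  structure(list(lda = lda, T_mat = T_mat, C = C,
                 P = stats::setNames(ptab$P, ptab$topic),
                 Q = stats::setNames(qtab$Q, qtab$cell_type),
                 accuracy = acc,
                 features = structure(list(mode = params$feature_mode,
                                           genes = genes,
                                           n_top = NA_integer_),
                                      class = "feature_genes"),
                 gene_sd = stats::setNames(sdtab$sd, sdtab$gene),
                 scale_factor = params$scale_factor,
                 cell_types = rownames(C)),
            class = "celltopic_model")
}

stage_stamp <- function(outdir, stage, inputs, params) {
  files <- inputs[file.exists(inputs)]
  sums <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  paste(c(stage, sort(sums),
          utils::capture.output(utils::str(params))), collapse = "\n")
}

stage_done <- function(outdir, stage, stamp, outputs) {
  sfile <- file.path(outdir, paste0(".", stage, ".stamp"))
  all(file.exists(outputs)) && file.exists(sfile) &&
    identical(paste(readLines(sfile), collapse = "\n"), stamp)
}

mark_stage <- function(outdir, stage, stamp) {
  writeLines(stamp, file.path(outdir, paste0(".", stage, ".stamp")))
}

#' Run the end-to-end workflow from a config
#'
#' Executes the requested stages in dependency order. The config is a flat
#' named list (or the path of a YAML file holding one) with keys:
#' `outdir`, `seed`, `stages` (subset of `simulate`, `train`, `deconvolve`,
#' `evaluate`, `domains`, `align`), input paths (`sc_matrix`, `sc_labels`,
#' `st_matrix`, `st_coords`, `truth`, `layer_dirs`), and stage parameters
#' (`sim_mode` = random/tme/depth, `n_spots`, `k_list`, `n_top`,
#' `feature_mode`, `k_clusters`, `weight`, `core_cluster`, `threshold`,
#' `lambda`, `z_spacing`). Completed stages whose inputs and parameters are
#' unchanged are skipped; each stage logs its parameters and the seed.
#'
#' @param config Named list or YAML file path.
#' @param verbose Log stage execution.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg), !is.null(cfg$outdir), !is.null(cfg$stages))
  outdir <- cfg$outdir
  seed <- cfg$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[spotdecon seed=", seed, "] ", ...)
  known <- c("simulate", "train", "deconvolve", "evaluate", "domains", "align")
  stages <- intersect(known, cfg$stages)
  if (!setequal(stages, cfg$stages)) {
    stop("unknown stages: ",
         paste(setdiff(cfg$stages, known), collapse = ", "))
  }

  run_stage <- function(stage, inputs, params, outputs, fun) {
    stamp <- stage_stamp(outdir, stage, inputs, c(params, seed = seed))
    if (stage_done(outdir, stage, stamp, outputs)) {
      say("stage '", stage, "': up to date, skipped")
      return(invisible(NULL))
    }
    say("stage '", stage, "': running (",
        paste(names(params), unlist(lapply(params, paste, collapse = ",")),
              sep = "=", collapse = ", "), ")")
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      record <- file.path(outdir, paste0(stage, ".error.yaml"))
      yaml::write_yaml(list(stage = stage, error = conditionMessage(e),
                            time = format(Sys.time())), record)
      stop("stage '", stage, "' failed (see ", record, "): ",
           conditionMessage(e), call. = FALSE)
    })
    mark_stage(outdir, stage, stamp)
    invisible(NULL)
  }

  if ("simulate" %in% stages) {
    mode <- cfg$sim_mode %||% "random"
    params <- list(sim_mode = mode, n_spots = cfg$n_spots %||% 200)
    outs <- file.path(outdir, c("sim_counts.tsv", "sim_truth.tsv"))
    run_stage("simulate", c(cfg$sc_matrix, cfg$sc_labels), params, outs, function() {
      sc <- read_matrix(cfg$sc_matrix)
      labels <- read_labels(cfg$sc_labels, sc)
      sim <- switch(mode,
        random = simulate_random_spots(sc, labels,
                                       n_spots = params$n_spots, seed = seed),
        tme = simulate_tme(sc, labels, seed = seed),
        depth = simulate_depth_series(sc, labels,
                                      n_spots = params$n_spots,
                                      seed = seed)[[1]],
        stop("unknown sim_mode: ", mode))
      write_matrix(sim$counts, outs[1])
      write_result_table(sim$truth, outs[2])
      if (!is.null(sim$region)) {
        write_result_table(data.frame(spot_id = colnames(sim$counts),
                                      region = sim$region),
                           file.path(outdir, "sim_regions.tsv"))
      }
    })
  }

  model_dir <- file.path(outdir, "model")
  if ("train" %in% stages) {
    params <- list(k_list = cfg$k_list, n_top = cfg$n_top %||% 500,
                   feature_mode = cfg$feature_mode %||% "markers")
    st_path <- cfg$st_matrix %||% file.path(outdir, "sim_counts.tsv")
    outs <- file.path(model_dir, c("phi.tsv", "C.tsv", "accuracy.tsv"))
    run_stage("train", c(cfg$sc_matrix, cfg$sc_labels, st_path), params, outs,
              function() {
      sc <- read_matrix(cfg$sc_matrix)
      labels <- read_labels(cfg$sc_labels, sc)
      st <- if (file.exists(st_path)) read_matrix(st_path) else NULL
      model <- fit_celltopics(sc, labels, st = st, ks = cfg$k_list,
                              feature_mode = params$feature_mode,
                              n_top = params$n_top, seed = seed)
      write_model_dir(model, model_dir)
    })
  }

  pred_paths <- file.path(outdir, c("st_proportions.tsv", "st_topics.tsv",
                                    "st_dominant.tsv"))
  if ("deconvolve" %in% stages) {
    st_path <- cfg$st_matrix %||% file.path(outdir, "sim_counts.tsv")
    run_stage("deconvolve", c(st_path, file.path(model_dir, "phi.tsv")),
              list(), pred_paths, function() {
      model <- read_model_dir(model_dir)
      st <- read_matrix(st_path)
      pred <- predict(model, st)
      write_result_table(pred$proportions, pred_paths[1])
      write_result_table(pred$topics, pred_paths[2])
      write_result_table(data.frame(spot_id = names(pred$dominant),
                                    cell_type = pred$dominant),
                         pred_paths[3])
    })
  }

  if ("evaluate" %in% stages) {
    truth_path <- cfg$truth %||% file.path(outdir, "sim_truth.tsv")
    outs <- file.path(outdir, c("eval_per_spot.tsv", "eval_per_type.tsv",
                                "eval_summary.tsv"))
    run_stage("evaluate", c(pred_paths[1], truth_path), list(), outs,
              function() {
      pred <- read_tsv_matrix(pred_paths[1])
      truth <- read_tsv_matrix(truth_path)
      ev <- evaluate_deconvolution(pred, truth)
      write_result_table(ev$per_spot, outs[1])
      write_result_table(ev$per_type, outs[2])
      write_result_table(data.frame(metric = rownames(ev$summary),
                                    ev$summary, check.names = FALSE),
                         outs[3])
    })
  }

  if ("domains" %in% stages) {
    params <- list(k_clusters = cfg$k_clusters %||% 6,
                   weight = cfg$weight %||% 0.5,
                   core_cluster = cfg$core_cluster,
                   threshold = cfg$threshold %||% 4)
    outs <- file.path(outdir, "domains.tsv")
    run_stage("domains", c(pred_paths[1], cfg$st_coords), params, outs,
              function() {
      comp <- read_tsv_matrix(pred_paths[1])
      coords <- read_coordinates(cfg$st_coords)
      cl <- cluster_domains(comp, coords, k_clusters = params$k_clusters,
                            weight = params$weight, seed = seed)
      if (!is.null(params$core_cluster)) {
        reg <- define_regions(cl, coords, params$core_cluster,
                              threshold = params$threshold)
      } else {
        reg <- data.frame(spot_id = names(cl), cluster = unname(cl),
                          distance_to_core = NA_real_, region = NA_character_,
                          stringsAsFactors = FALSE)
      }
      write_result_table(reg, outs)
    })
  }

  if ("align" %in% stages) {
    stopifnot(!is.null(cfg$layer_dirs), length(cfg$layer_dirs) >= 2)
    params <- list(lambda = cfg$lambda %||% 0.1,
                   z_spacing = cfg$z_spacing %||% 1)
    outs <- file.path(outdir, "stack_3d.tsv")
    ins <- unlist(lapply(cfg$layer_dirs,
                         function(d) file.path(d, c("topics.tsv",
                                                    "coords.tsv"))))
    run_stage("align", ins, params, outs, function() {
      layers <- lapply(seq_along(cfg$layer_dirs), function(k) {
        d <- cfg$layer_dirs[[k]]
        slide_layer(read_tsv_matrix(file.path(d, "topics.tsv")),
                    read_coordinates(file.path(d, "coords.tsv")),
                    id = basename(d), z_index = k)
      })
      stk <- stack_layers(layers, lambda = params$lambda,
                          z_spacing = params$z_spacing)
      write_result_table(stk$coordinates, outs)
    })
  }

  invisible(outdir)
}
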
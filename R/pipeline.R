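#' Assemble a pipeline configuration
#'
#' A flat, per-stage configuration for [run_pipeline()]. Unknown keys are
#' errors (typo protection). The configuration round-trips losslessly
#' through JSON.
#'
#' @param qc a [qc_thresholds()].
#' @param backspin a [backspin_params()].
#' @param binarization a [binarization_thresholds()].
#' @param n_features variable genes per BackSPIN node.
#' @param marker_draws,marker_warmup MCMC sizes per gene.
#' @param seed master seed; every stage derives its own substream.
#' @param stages character subset of
#'   `c("qc", "backspin", "binarization", "cluster_correlation")` executed
#'   in dependency order.
#' @param consistency_filter apply [filter_inconsistent_cells()] with a
#'   second BackSPIN parameterization (default FALSE, as in the stem-cell
#'   datasets where it could bias abundances).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            backspin = backspin_params(),
                            binarization = binarization_thresholds(),
                            n_features = 500, marker_draws = 400,
                            marker_warmup = 400, seed = 1L,
                            stages = c("qc", "backspin", "binarization",
                                       "cluster_correlation"),
                            consistency_filter = FALSE) {
  known <- c("qc", "backspin", "binarization", "cluster_correlation")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(qc = qc, backspin = backspin, binarization = binarization,
                 n_features = n_features, marker_draws = marker_draws,
                 marker_warmup = marker_warmup, seed = as.integer(seed),
                 stages = stages, consistency_filter = consistency_filter),
            class = "pipeline_config")
}

stage_manifest <- function(dir, stage, inputs, seed, outputs) {
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("cellspin")),
                   seed = seed,
                   input_md5 = as.list(setNames(unname(tools::md5sum(inputs)),
                                                basename(inputs))),
                   output_md5 = as.list(setNames(unname(tools::md5sum(outputs)),
                                                 basename(outputs))))
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run the clustering pipeline end to end
#'
#' Executes the requested stages in dependency order
#' (qc -> backspin -> binarization -> cluster_correlation), writing every
#' artifact plus a per-stage manifest (stage, input/output md5 hashes,
#' seed, package version) under `out_dir`. All randomness flows from
#' `config$seed` through named per-stage substreams, so the same config
#' and seed reproduce identical manifests. A stage failure halts the run
#' with the failing stage named; partial outputs are retained.
#'
#' @param counts genes x cells count matrix.
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return invisibly, a list with the run directory and per-stage results
#'   (`counts_qc`, `tree`, `labels`, `markers`, `cluster_correlation`).
#' @export
run_pipeline <- function(counts, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  res <- list(dir = out_dir)
  run_stage <- function(stage, f) {
    tryCatch(f(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  input_path <- file.path(out_dir, "input")
  write_counts_mtx(counts, input_path)
  in_files <- file.path(input_path, c("matrix.mtx", "genes.tsv", "cells.tsv"))

  m <- counts
  if ("qc" %in% config$stages) {
    run_stage("qc", function() {
      m <<- filter_cells_by_molecules(m, config$qc)
      m <<- filter_low_count_genes(m, config$qc)
      qc_dir <- file.path(out_dir, "qc")
      write_counts_mtx(m, qc_dir)
      report <- attr(m, "qc_report")
      jsonlite::write_json(list(cells_in = ncol(counts), cells_out = ncol(m),
                                genes_in = nrow(counts), genes_out = nrow(m),
                                median_molecules = median(colSums(m))),
                           file.path(out_dir, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_manifest(out_dir, "qc", in_files, config$seed,
                     file.path(qc_dir, c("matrix.mtx", "genes.tsv", "cells.tsv")))
    })
    res$counts_qc <- m
  }
  if ("backspin" %in% config$stages) {
    run_stage("backspin", function() {
      tree <- backspin(m, config$backspin, n_features = config$n_features,
                       seed = derive_seed(config$seed, 11L))
      res$tree <<- tree
      res$labels <<- cluster_tree_labels(tree)
      tree_path <- file.path(out_dir, "tree.json")
      write_cluster_tree_json(tree, tree_path)
      labels_path <- file.path(out_dir, "leaf_labels.tsv")
      write.table(data.frame(cell = names(res$labels),
                             cluster = unname(res$labels)),
                  labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
      stage_manifest(out_dir, "backspin", in_files, config$seed,
                     c(tree_path, labels_path))
    })
  }
  if ("binarization" %in% config$stages) {
    run_stage("binarization", function() {
      mk <- fit_markers(m, res$labels, config$binarization,
                        n_warmup = config$marker_warmup,
                        n_draws = config$marker_draws,
                        seed = derive_seed(config$seed, 21L))
      res$markers <<- mk
      bin_path <- file.path(out_dir, "binary_patterns.tsv")
      write.table(mk$binary, bin_path, sep = "\t", quote = FALSE,
                  col.names = NA)
      map_path <- file.path(out_dir, "map_profile.csv")
      write.table(mk$map_profile, map_path, sep = ",", quote = FALSE,
                  col.names = NA)
      stage_manifest(out_dir, "binarization",
                     file.path(out_dir, "leaf_labels.tsv"), config$seed,
                     c(bin_path, map_path))
    })
  }
  if ("cluster_correlation" %in% config$stages) {
    run_stage("cluster_correlation", function() {
      ok <- stats::complete.cases(res$markers$binary)
      cc <- cluster_correlation_matrix(m, res$labels,
                                       res$markers$binary[ok, , drop = FALSE],
                                       config$backspin,
                                       seed = derive_seed(config$seed, 31L))
      res$cluster_correlation <<- cc
      cc_path <- file.path(out_dir, "cluster_correlation.csv")
      write.table(cc$S, cc_path, sep = ",", quote = FALSE, col.names = NA)
      stage_manifest(out_dir, "cluster_correlation",
                     file.path(out_dir, "binary_patterns.tsv"),
                     config$seed, cc_path)
    })
  }
  invisible(res)
}
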
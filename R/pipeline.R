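#' Assemble a pipeline configuration
#'
#' Collects stage parameters, input locations (or a simulation config) and
#' stage toggles for [run_pipeline()]. A seed is mandatory because the random
#' control (and, when enabled, the simulation) is stochastic.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param simulate a [sim_config()] to generate the inputs, or `NULL` to read
#'   them from `rna_dir`/`adt_dir`.
#' @param rna_dir,adt_dir MTX directories (ignored when `simulate` is given).
#' @param signatures named list of [gene_signature()], or a GMT path; when
#'   `NULL` and `simulate` is given, the planted ground-truth signatures are
#'   scored.
#' @param hashtag_prefix regular expression selecting hashtag rows of the
#'   antibody matrix.
#' @param stages character vector of stages to run, in pipeline order; a
#'   subset disables the omitted stages (e.g. drop `"qc"` to let downstream
#'   stages consume every called cell).
#' @param min_counts,ratio,doublet_positive_threshold demultiplexing rule.
#' @param min_rna,max_mito_frac,min_adt,isotype_positive_threshold QC rule.
#' @param n_iter random-control iterations.
#' @param score_mode `"cell"` or `"pseudobulk"` for the per-sample comparison.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            simulate = sim_config(seed = seed),
                            rna_dir = NULL, adt_dir = NULL, signatures = NULL,
                            hashtag_prefix = "^Hashtag",
                            stages = c("callcells", "demux", "qc", "score",
                                       "quantify"),
                            min_counts = 10, ratio = 2.0,
                            doublet_positive_threshold = 10,
                            min_rna = 500, max_mito_frac = 0.10,
                            min_adt = 500, isotype_positive_threshold = 10,
                            n_iter = 1000, score_mode = "cell") {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory: the random control and simulation are stochastic")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `simulate` mapping is
#' passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate) && is.list(raw$simulate))
    raw$simulate <- do.call(sim_config, raw$simulate)
  do.call(pipeline_config, raw)
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on one experiment
#'
#' Executes cell calling, demultiplexing, QC, normalization and centering,
#' signature scoring and quantification in order, writing per-stage artifacts
#' (stamped CSV/TSV tables) and a machine-readable JSON run log (parameters,
#' seed, package version, per-stage barcode counts) under `out_dir`. Any
#' stage error aborts with the stage name; artifacts of completed stages and
#' the run log persist.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results (`called`,
#'   `demux`, `qc`, `scores`, `frequencies`, `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              params = .param_hash(config),
              package_version = as.character(utils::packageVersion("trmsig")),
              stages = list())
  write_log <- function() jsonlite::write_json(
    log, file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  on.exit(write_log())

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", log, generate_droplet_experiment(config$simulate))
    rna <- sim$rna; adt <- sim$adt; truth <- sim$truth
    utils::write.csv(truth$barcodes,
                     file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  } else {
    rna <- .stage("read", log, read_counts_mtx(config$rna_dir))
    adt <- .stage("read", log, read_counts_mtx(config$adt_dir))
  }
  log$stages$input <- list(barcodes = ncol(rna), genes = nrow(rna),
                           antibody_features = nrow(adt))

  cells <- colnames(rna)
  if ("callcells" %in% config$stages) {
    cells <- .stage("callcells", log, call_cells(rna, adt))
    writeLines(cells, file.path(out_dir, "called_barcodes.tsv"))
    curve <- rank_barcodes(rna)
    write_result_csv(curve, file.path(out_dir, "rank_curve.csv"),
                     config$seed, config)
    log$stages$callcells <- list(
      called = length(cells),
      rna_threshold = attr(cells, "rna_threshold"),
      adt_threshold = attr(cells, "adt_threshold"))
  }
  rna <- rna[, cells, drop = FALSE]
  adt <- adt[, cells, drop = FALSE]

  dmx <- NULL
  if ("demux" %in% config$stages) {
    tags <- grep(config$hashtag_prefix, rownames(adt), value = TRUE)
    dmx <- .stage("demux", log, demultiplex(
      adt[tags, , drop = FALSE], min_counts = config$min_counts,
      ratio = config$ratio,
      doublet_positive_threshold = config$doublet_positive_threshold))
    write_result_csv(dmx, file.path(out_dir, "demux.csv"),
                     config$seed, config)
    singlets <- dmx$barcode[!dmx$assignment %in% c("DOUBLET", "UNASSIGNED")]
    log$stages$demux <- list(
      singlets = length(singlets),
      doublets = sum(dmx$assignment == "DOUBLET"),
      unassigned = sum(dmx$assignment == "UNASSIGNED"))
    rna <- rna[, singlets, drop = FALSE]
    adt <- adt[, singlets, drop = FALSE]
  }

  qc <- NULL
  if ("qc" %in% config$stages) {
    qc <- .stage("qc", log, filter_cells(
      rna, adt, min_rna = config$min_rna,
      max_mito_frac = config$max_mito_frac, min_adt = config$min_adt,
      isotype_positive_threshold = config$isotype_positive_threshold))
    writeLines(qc$kept, file.path(out_dir, "kept_barcodes.tsv"))
    jsonlite::write_json(qc[c("removed", "skipped", "thresholds", "n_input")],
                         file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    log$stages$qc <- list(kept = length(qc$kept),
                          removed = as.list(qc$removed))
    rna <- rna[, qc$kept, drop = FALSE]
    adt <- adt[, qc$kept, drop = FALSE]
  }

  scores <- NULL
  freqs <- NULL
  if (any(c("score", "quantify") %in% config$stages)) {
    expr <- center_genes(normalize_and_log(rna, mode = "cp10k"))
    # group labels: planted truth groups when simulating, else demux samples
    groups <- if (!is.null(truth)) {
      stats::setNames(truth$barcodes$group, truth$barcodes$barcode)[colnames(rna)]
    } else if (!is.null(dmx)) {
      stats::setNames(dmx$assignment, dmx$barcode)[colnames(rna)]
    } else stop("no grouping available: enable demux or simulate")
    keep <- !is.na(groups)
    expr_g <- expr[, keep, drop = FALSE]
    attr(expr_g, "centered") <- TRUE
    groups <- groups[keep]

    if ("score" %in% config$stages) {
      sigs <- config$signatures
      if (is.character(sigs)) sigs <- read_gmt(sigs)
      if (is.null(sigs) && !is.null(truth)) sigs <- truth$signatures
      if (is.null(sigs)) stop("no signatures to score")
      scores <- .stage("score", log, do.call(rbind, lapply(sigs, function(s)
        score_signature_adjusted(expr_g, s, groups,
                                 n_iter = config$n_iter,
                                 seed = config$seed))))
      rownames(scores) <- NULL
      write_result_csv(scores, file.path(out_dir, "signature_scores.csv"),
                       config$seed, config)
      log$stages$score <- list(signatures = length(sigs),
                               groups = length(unique(groups)))
    }
    if ("quantify" %in% config$stages) {
      conditions <- if (!is.null(dmx))
        stats::setNames(dmx$assignment, dmx$barcode)[names(groups)]
      else groups
      freqs <- .stage("quantify", log,
                      cluster_frequencies(groups, conditions))
      write_result_csv(freqs, file.path(out_dir, "cluster_frequencies.csv"),
                       config$seed, config)
      log$stages$quantify <- list(conditions = length(unique(conditions)))
    }
  }

  invisible(list(called = cells, demux = dmx, qc = qc, scores = scores,
                 frequencies = freqs, truth = truth, log = log))
}
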
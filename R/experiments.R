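#' Planted-signature recovery experiment
#'
#' Repeatedly simulates a two-group droplet experiment in which group 1
#' carries a planted up-gene program at a given log2 effect size, scores the
#' planted signature in both groups (control-adjusted), and records both
#' adjusted scores. Used to verify that enrichment scoring separates a
#' planted transcriptional state from a null group and that the score grows
#' with effect size.
#'
#' @param n_reps replicates per effect size.
#' @param effects numeric vector of log2 fold-change effect sizes.
#' @param seed base seed; replicate `r` of effect `e` uses an offset seed.
#' @param n_cells,n_genes,genes_per_group simulation size (kept modest: the
#'   score operates on tens to hundreds of cells per group).
#' @param n_iter random-control iterations per replicate.
#' @return data.frame: `effect`, `replicate`, `adjusted_planted`,
#'   `adjusted_null`.
#' @export
planted_recovery_experiment <- function(n_reps = 100, effects = 2, seed = 1L,
                                        n_cells = 100, n_genes = 300,
                                        genes_per_group = 20, n_iter = 100) {
  out <- vector("list", length(effects) * n_reps)
  k <- 0L
  for (ei in seq_along(effects)) {
    for (r in seq_len(n_reps)) {
      s <- as.integer(seed + 1000L * ei + r)
      cfg <- sim_config(seed = s, n_cells = n_cells, n_empty_droplets = 50,
                        n_genes = n_genes, genes_per_group = genes_per_group,
                        signature_effect = effects[ei], doublet_fraction = 0,
                        mito_high_fraction = 0, sticky_fraction = 0)
      sim <- generate_droplet_experiment(cfg)
      tr <- sim$truth$barcodes
      cells <- tr$barcode[tr$is_cell]
      expr <- center_genes(normalize_and_log(sim$rna[, cells, drop = FALSE]))
      groups <- stats::setNames(tr$group[match(cells, tr$barcode)], cells)
      res <- score_signature_adjusted(expr, sim$truth$signatures$group1,
                                      groups, n_iter = n_iter, seed = s)
      k <- k + 1L
      out[[k]] <- data.frame(
        effect = effects[ei], replicate = r,
        adjusted_planted = res$adjusted_score[res$group == "group1"],
        adjusted_null = res$adjusted_score[res$group == "group2"])
    }
  }
  do.call(rbind, out)
}

#' Trajectory divergence experiment
#'
#' Repeatedly builds a staged reference, derives per-timepoint signatures
#' against naive, and scores a "fully differentiated" query group (expressing
#' every stage program) against an "early-arrested" group (first stage only).
#' Records both groups' adjusted scores against the latest-stage signature —
#' the qualitative divergence expected when only one group completes
#' differentiation.
#'
#' @param n_reps replicates.
#' @param seed base seed.
#' @param n_timepoints,genes_per_stage,n_genes,samples_per_stage reference
#'   size.
#' @param n_query_cells cells per query group.
#' @param n_iter random-control iterations per timepoint.
#' @return data.frame: `replicate`, `full_last`, `early_last` (adjusted
#'   scores on the latest-stage signature).
#' @export
trajectory_divergence_experiment <- function(n_reps = 100, seed = 1L,
                                             n_timepoints = 3,
                                             genes_per_stage = 20,
                                             n_genes = 600,
                                             samples_per_stage = 20,
                                             n_query_cells = 40,
                                             n_iter = 100) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- as.integer(seed + r)
    cfg <- sim_config(seed = s, n_genes = n_genes, signature_effect = 2)
    ref <- generate_staged_reference(n_timepoints, genes_per_stage, cfg,
                                     samples_per_stage = samples_per_stage)
    expr <- normalize_and_log(ref$counts)
    sigs <- suppressWarnings(
      build_timepoint_signatures(expr, ref$stages, "naive",
                                 top_n = genes_per_stage, direction = "up"))
    stages <- names(ref$truth$planted)
    full <- simulate_stage_query(ref, stages, n_query_cells, cfg,
                                 seed = s + 500000L)
    early <- simulate_stage_query(ref, stages[1], n_query_cells, cfg,
                                  seed = s + 1000000L)
    q <- cbind(full, early)
    colnames(q) <- sprintf("q%04d", seq_len(ncol(q)))
    qexpr <- center_genes(normalize_and_log(q))
    groups <- stats::setNames(rep(c("full", "early"), each = n_query_cells),
                              colnames(q))
    last_sig <- sigs[[length(sigs)]]
    res <- score_signature_adjusted(qexpr, last_sig, groups, n_iter = n_iter,
                                    seed = s)
    out[[r]] <- data.frame(
      replicate = r,
      full_last = res$adjusted_score[res$group == "full"],
      early_last = res$adjusted_score[res$group == "early"])
  }
  do.call(rbind, out)
}

#' Null calibration of adjusted scores on exchangeable genes
#'
#' Draws an exchangeable-gene count matrix (every gene the same
#' negative-binomial law), normalizes, centers, and scores `n_signatures`
#' random signatures — each with its own random-gene-set control — for one of
#' two equal cell groups. Under exchangeability the adjusted scores are
#' centered on zero; the experiment returns them for calibration checks.
#'
#' @param n_cells,n_genes matrix size.
#' @param n_signatures random signatures to score.
#' @param n_up,n_down genes per random signature.
#' @param n_iter control iterations per signature.
#' @param seed base seed.
#' @return numeric vector of `n_signatures` adjusted scores (group A).
#' @export
null_calibration_experiment <- function(n_cells = 200, n_genes = 500,
                                        n_signatures = 200, n_up = 20,
                                        n_down = 20, n_iter = 1000,
                                        seed = 1L) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = 5, size = 10),
                   n_genes, n_cells,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   sprintf("c%04d", seq_len(n_cells))))
  expr <- center_genes(normalize_and_log(counts))
  groups <- stats::setNames(rep(c("A", "B"), length.out = n_cells),
                            colnames(expr))
  genes <- rownames(expr)
  vapply(seq_len(n_signatures), function(i) {
    set.seed(seed + 10000L + i)
    gs <- sample(genes, n_up + n_down)
    sig <- gene_signature(paste0("rand", i), gs[seq_len(n_up)],
                          gs[n_up + seq_len(n_down)])
    res <- score_signature_adjusted(expr, sig, groups, n_iter = n_iter,
                                    seed = seed + 20000L + i)
    res$adjusted_score[res$group == "A"]
  }, numeric(1))
}
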
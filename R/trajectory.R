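#' Build ordered per-timepoint signatures from a staged reference
#'
#' For each non-naive stage of a staged reference (e.g. epidermal TRM
#' harvested at successive days post infection), derives the top differentially
#' expressed genes of that stage versus the naive stage and returns the
#' signatures in stage order — the "top 100 DEGs of each timepoint versus
#' naive" construction used for developmental trajectory scoring.
#'
#' @param reference_expr genes x samples log-expression matrix of the staged
#'   reference.
#' @param stage_labels stage label per sample (factor level order, else order
#'   of first appearance, fixes the timepoint order).
#' @param naive_label label of the naive stage.
#' @param top_n genes per direction per timepoint signature.
#' @param direction `"both"` or `"up"`, passed to [derive_signature()].
#' @param min_abs_lfc minimum absolute log fold-change.
#' @return named list of [gene_signature()] objects, one per non-naive stage,
#'   in stage order.
#' @export
build_timepoint_signatures <- function(reference_expr, stage_labels,
                                       naive_label = "naive", top_n = 100,
                                       direction = c("both", "up"),
                                       min_abs_lfc = 0.25) {
  direction <- match.arg(direction)
  if (length(stage_labels) != ncol(reference_expr))
    stop("one stage label per reference sample required")
  lv <- if (is.factor(stage_labels)) levels(stage_labels)
        else unique(as.character(stage_labels))
  if (!naive_label %in% lv)
    stop("naive stage '", naive_label, "' absent from the reference")
  stages <- setdiff(lv, naive_label)
  if (!length(stages)) stop("reference needs at least one non-naive stage")
  labels <- stats::setNames(as.character(stage_labels),
                            colnames(reference_expr))
  sigs <- lapply(stages, function(s) {
    sig <- derive_signature(reference_expr, labels, s, naive_label,
                            top_n = top_n, min_abs_lfc = min_abs_lfc,
                            direction = direction)
    sig$name <- s
    sig
  })
  stats::setNames(sigs, stages)
}

#' Score groups along an ordered series of timepoint signatures
#'
#' For every group and every timepoint signature, computes the
#' control-adjusted signature score with its cell-level confidence interval
#' and the random-gene-set baseline (the control mean, the "gray line").
#' Timepoint order is preserved from the signature list.
#'
#' @param query_expr centered genes x cells matrix of the query cells.
#' @param groups group labels named by barcode.
#' @param timepoint_signatures named ordered list from
#'   [build_timepoint_signatures()] (or any list of [gene_signature()]).
#' @param n_iter random-control iterations per timepoint.
#' @param seed base seed; timepoint `k` uses `seed + k - 1`.
#' @return tidy data.frame of class `trajectory_profile`: `group`,
#'   `timepoint` (factor in trajectory order), `adjusted_score`, `ci_low`,
#'   `ci_high`, `random_baseline` (control mean), `raw_score`, `control_sd`,
#'   `n_cells`.
#' @export
score_trajectory <- function(query_expr, groups, timepoint_signatures,
                             n_iter = 1000, seed = 1L) {
  if (!length(timepoint_signatures)) stop("no timepoint signatures given")
  if (inherits(timepoint_signatures, "gene_signature"))
    timepoint_signatures <- list(timepoint_signatures)
  tp_names <- vapply(timepoint_signatures, function(s) s$name, character(1))
  rows <- lapply(seq_along(timepoint_signatures), function(k) {
    res <- score_signature_adjusted(query_expr, timepoint_signatures[[k]],
                                    groups, n_iter = n_iter,
                                    seed = seed + k - 1L)
    data.frame(group = res$group, timepoint = tp_names[k],
               adjusted_score = res$adjusted_score, ci_low = res$ci_low,
               ci_high = res$ci_high, random_baseline = res$control_mean,
               raw_score = res$raw_score, control_sd = res$control_sd,
               n_cells = res$n_cells, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$timepoint <- factor(out$timepoint, levels = tp_names)
  class(out) <- c("trajectory_profile", "data.frame")
  out
}
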
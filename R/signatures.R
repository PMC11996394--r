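#' Construct a gene signature
#'
#' A named set of up-regulated genes and (optionally) down-regulated genes
#' defining one reference transcriptional state.
#'
#' @param name signature label.
#' @param up_genes character vector of up-genes (non-empty; duplicates
#'   removed).
#' @param down_genes character vector of down-genes (may be empty). Must be
#'   disjoint from `up_genes`.
#' @return list of class `gene_signature` with elements `name`, `up_genes`,
#'   `down_genes`.
#' @export
gene_signature <- function(name, up_genes, down_genes = character(0)) {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (!length(up_genes)) stop("signature '", name, "' has no up genes")
  if (length(intersect(up_genes, down_genes)))
    stop("signature '", name, "': up and down gene sets overlap")
  structure(list(name = as.character(name), up_genes = up_genes,
                 down_genes = down_genes), class = "gene_signature")
}

#' Normalize counts and log-transform
#'
#' Two modes. `"cp10k"` (default, appropriate for UMI matrices) scales each
#' cell to 10,000 total counts and applies `log2(x + 1)`. `"tpm"` (for bulk
#' tables with gene lengths) computes transcripts per million — length-rate
#' normalization to one million — then `log2(TPM + 1)`.
#'
#' @param counts genes x cells (or genes x samples) non-negative count
#'   matrix with gene row names.
#' @param mode `"cp10k"` or `"tpm"`.
#' @param gene_lengths named numeric vector of gene lengths in bases,
#'   required for `"tpm"`.
#' @param scale_factor library-size target for `"cp10k"`.
#' @return dense genes x cells matrix of log2 expression with attributes
#'   `normalization` and `centered = FALSE`.
#' @export
normalize_and_log <- function(counts, mode = c("cp10k", "tpm"),
                              gene_lengths = NULL, scale_factor = 1e4) {
  mode <- match.arg(mode)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- as.matrix(counts)
  totals <- colSums(m)
  if (mode == "cp10k") {
    sf <- ifelse(totals > 0, scale_factor / totals, 0)
    norm <- sweep(m, 2, sf, `*`)
  } else {
    if (is.null(gene_lengths))
      stop("tpm mode requires gene lengths")
    missing_len <- setdiff(rownames(m), names(gene_lengths))
    if (length(missing_len))
      stop("gene lengths missing for: ",
           paste(utils::head(missing_len, 5), collapse = ", "))
    rate <- m / (gene_lengths[rownames(m)] / 1e3)
    rate_tot <- colSums(rate)
    norm <- sweep(rate, 2, ifelse(rate_tot > 0, 1e6 / rate_tot, 0), `*`)
  }
  out <- log2(norm + 1)
  attr(out, "normalization") <- if (mode == "cp10k") "log2_cp10k1" else "log2_tpm1"
  attr(out, "centered") <- FALSE
  out
}

#' Center expression for each gene across all cells
#'
#' Subtracts each gene's mean over all cells (samples), the centering step the
#' signature score is defined on. Re-centering an already centered matrix is a
#' contract violation: it warns and returns the input unchanged.
#'
#' @param expr genes x cells log-expression matrix (e.g. from
#'   [normalize_and_log()]).
#' @return the centered matrix with attribute `centered = TRUE`.
#' @export
center_genes <- function(expr) {
  if (isTRUE(attr(expr, "centered"))) {
    warning("matrix is already centered; returning unchanged")
    return(expr)
  }
  out <- as.matrix(expr) - rowMeans(as.matrix(expr))
  attr(out, "normalization") <- attr(expr, "normalization")
  attr(out, "centered") <- TRUE
  out
}

# per-cell signature score on a centered matrix: mean over up genes minus
# mean over down genes (0 when the down set is empty)
.cell_scores <- function(expr, up, down) {
  up_idx <- intersect(up, rownames(expr))
  down_idx <- intersect(down, rownames(expr))
  if (!length(up_idx)) return(NULL)
  up_part <- colMeans(expr[up_idx, , drop = FALSE])
  down_part <- if (length(down_idx))
    colMeans(expr[down_idx, , drop = FALSE]) else 0
  list(score = up_part - down_part,
       n_up = length(up_idx), n_down = length(down_idx))
}

.check_centered <- function(expr) {
  if (!isTRUE(attr(expr, "centered")))
    stop("expression matrix must be gene-centered (see center_genes())")
}

.split_groups <- function(expr, groups) {
  if (is.null(names(groups))) {
    if (length(groups) != ncol(expr))
      stop("groups must be named by barcode or match the number of cells")
    names(groups) <- colnames(expr)
  }
  absent <- setdiff(names(groups), colnames(expr))
  if (length(absent))
    stop("barcodes absent from expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  split(match(names(groups), colnames(expr)), as.character(groups))
}

#' Raw signature score per group
#'
#' The signature score of a group is the mean over its cells of the per-cell
#' score: mean centered expression over the signature's up-genes minus the
#' mean over its down-genes ("mean up-gene z-score minus mean down-gene
#' z-score" on gene-centered data). Signature genes absent from the matrix are
#' dropped and counted. The 95% confidence interval is the normal
#' approximation over the group's cells (mean +/- 1.96 SE).
#'
#' @param expr centered genes x cells matrix from [center_genes()].
#' @param signature a [gene_signature()].
#' @param groups cell grouping: a vector of labels named by barcode (or
#'   aligned to columns).
#' @return data.frame with one row per group: `group`, `signature`,
#'   `raw_score`, `se`, `ci_low`, `ci_high`, `n_cells`, `n_up_used`,
#'   `n_down_used`.
#' @export
score_signature <- function(expr, signature, groups) {
  .check_centered(expr)
  stopifnot(inherits(signature, "gene_signature"))
  cs <- .cell_scores(expr, signature$up_genes, signature$down_genes)
  if (is.null(cs))
    stop("no up genes of signature '", signature$name,
         "' are present in the expression matrix")
  idx <- .split_groups(expr, groups)
  rows <- lapply(names(idx), function(g) {
    s <- cs$score[idx[[g]]]
    se <- if (length(s) > 1) stats::sd(s) / sqrt(length(s)) else 0
    data.frame(group = g, signature = signature$name,
               raw_score = mean(s), se = se,
               ci_low = mean(s) - 1.96 * se, ci_high = mean(s) + 1.96 * se,
               n_cells = length(s), n_up_used = cs$n_up,
               n_down_used = cs$n_down, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Random-gene-set control for signature scores
#'
#' Repeats the signature score with uniformly sampled gene sets of the same
#' sizes (`n_up` up, `n_down` down; sampled without replacement within an
#' iteration, real signature genes not excluded from the pool) and returns the
#' per-group mean and sd of the random scores. Subtracting this control
#' removes size- and coverage-dependent bias. Deterministic given `seed`.
#'
#' @param expr centered genes x cells matrix.
#' @param n_up,n_down random set sizes (typically the number of signature
#'   genes used).
#' @param groups cell grouping as in [score_signature()].
#' @param n_iter number of random sets (>= 2).
#' @param seed integer seed.
#' @return data.frame per group: `group`, `control_mean`, `control_sd`,
#'   `n_iter`, `seed`.
#' @export
random_control <- function(expr, n_up, n_down = 0, groups, n_iter = 1000,
                           seed = 1L) {
  .check_centered(expr)
  if (n_up < 1) stop("n_up must be >= 1")
  if (n_iter < 2) stop("n_iter must be >= 2")
  ng <- nrow(expr)
  if (n_up + n_down > ng)
    stop("n_up + n_down exceeds the number of genes (", ng, ")")
  idx <- .split_groups(expr, groups)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = length(idx),
                  dimnames = list(NULL, names(idx)))
  for (it in seq_len(n_iter)) {
    gs <- sample.int(ng, n_up + n_down)
    up_part <- colMeans(expr[gs[seq_len(n_up)], , drop = FALSE])
    down_part <- if (n_down > 0)
      colMeans(expr[gs[n_up + seq_len(n_down)], , drop = FALSE]) else 0
    s <- up_part - down_part
    draws[it, ] <- vapply(idx, function(i) mean(s[i]), numeric(1))
  }
  data.frame(group = colnames(draws),
             control_mean = unname(colMeans(draws)),
             control_sd = unname(apply(draws, 2, stats::sd)),
             n_iter = n_iter, seed = seed,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Control-adjusted signature score per group
#'
#' Computes the raw signature score and the random-gene-set control with
#' matching set sizes, and reports the adjusted score `raw - control_mean`
#' with the cell-level confidence interval shifted accordingly.
#'
#' @inheritParams score_signature
#' @inheritParams random_control
#' @return data.frame per group: `group`, `signature`, `raw_score`,
#'   `control_mean`, `control_sd`, `adjusted_score`, `ci_low`, `ci_high`,
#'   `n_cells`, `n_up_used`, `n_down_used`, `n_random_iter`, `seed`.
#' @export
score_signature_adjusted <- function(expr, signature, groups, n_iter = 1000,
                                     seed = 1L) {
  raw <- score_signature(expr, signature, groups)
  ctrl <- random_control(expr, n_up = raw$n_up_used[1],
                         n_down = raw$n_down_used[1], groups = groups,
                         n_iter = n_iter, seed = seed)
  out <- merge(raw, ctrl, by = "group", sort = FALSE)
  out$adjusted_score <- out$raw_score - out$control_mean
  out$ci_low <- out$ci_low - out$control_mean
  out$ci_high <- out$ci_high - out$control_mean
  out$n_random_iter <- out$n_iter
  out[, c("group", "signature", "raw_score", "control_mean", "control_sd",
          "adjusted_score", "ci_low", "ci_high", "n_cells", "n_up_used",
          "n_down_used", "n_random_iter", "seed")]
}

#' Signature scores comparing two conditions, per cell or pseudobulk
#'
#' In `"pseudobulk"` mode cells are collapsed to one mean centered profile per
#' condition before scoring (each condition then contributes a single
#' "sample"); in `"cell"` mode cells are scored individually and summarized
#' per condition with a cell-level confidence interval. The mode is recorded
#' in the output.
#'
#' @param expr centered genes x cells matrix.
#' @param condition condition labels named by barcode (two or more
#'   conditions, each non-empty).
#' @param signatures a list of [gene_signature()] objects.
#' @param mode `"pseudobulk"` or `"cell"`.
#' @param n_iter,seed random-control settings.
#' @return tidy data.frame: one row per condition x signature with the
#'   columns of [score_signature_adjusted()] plus `mode`.
#' @export
pseudobulk_scores <- function(expr, condition, signatures,
                              mode = c("pseudobulk", "cell"),
                              n_iter = 1000, seed = 1L) {
  mode <- match.arg(mode)
  .check_centered(expr)
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  idx <- .split_groups(expr, condition)
  if (any(lengths(idx) == 0L)) stop("every condition needs at least one cell")
  if (length(idx) < 2L) stop("need at least two conditions")

  if (mode == "pseudobulk") {
    prof <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE]),
                   numeric(nrow(expr)))
    attr(prof, "centered") <- TRUE   # column-collapse preserves gene centering
    score_expr <- prof
    score_groups <- stats::setNames(colnames(prof), colnames(prof))
  } else {
    score_expr <- expr
    score_groups <- condition
  }
  out <- do.call(rbind, lapply(seq_along(signatures), function(k)
    score_signature_adjusted(score_expr, signatures[[k]], score_groups,
                             n_iter = n_iter, seed = seed)))
  out$mode <- mode
  out
}

# Vectorized two-sided rank-sum (Wilcoxon / Mann-Whitney) test per gene with
# tie correction and normal approximation; matches
# wilcox.test(exact = FALSE, correct = FALSE).
rank_sum_test <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2); N <- n1 + n2
  stats_per_gene <- function(v) {
    r <- rank(v)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    v_u <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- if (v_u > 0) (U - n1 * n2 / 2) / sqrt(v_u) else 0
    c(U = U, z = z)
  }
  res <- t(apply(cbind(as.matrix(x1), as.matrix(x2)), 1, stats_per_gene))
  data.frame(gene = rownames(x1), statistic = res[, "U"], z = res[, "z"],
             p = 2 * stats::pnorm(-abs(res[, "z"])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive a gene signature by differential expression against a reference
#'
#' Ranks genes by a two-sided rank-sum test comparing one group against a
#' reference group (e.g. naive T cells) on log expression. Up-genes are the
#' `top_n` most significant genes with positive mean log fold-change passing
#' `min_abs_lfc`, down-genes the `top_n` with negative. Per-gene centering
#' offsets cancel, so centered or uncentered log expression give the same
#' signature.
#'
#' @param expr genes x cells/samples log-expression matrix.
#' @param groups labels named by barcode/sample.
#' @param group,reference_group labels of the contrast (each >= 3 cells).
#' @param top_n genes per direction.
#' @param min_abs_lfc minimum absolute mean log fold-change.
#' @param direction `"both"` (up and down sets) or `"up"` (up-genes only).
#' @return a [gene_signature()] named `<group>_vs_<reference_group>`; if
#'   fewer than `top_n` genes qualify in a direction the signature is shorter
#'   and carries a `warning` attribute. Attribute `stats` holds the per-gene
#'   test table.
#' @export
derive_signature <- function(expr, groups, group, reference_group,
                             top_n = 100, min_abs_lfc = 0.25,
                             direction = c("both", "up")) {
  direction <- match.arg(direction)
  idx <- .split_groups(expr, groups)
  for (g in c(group, reference_group)) {
    if (!g %in% names(idx)) stop("group '", g, "' not found")
    if (length(idx[[g]]) < 3L) stop("group '", g, "' has fewer than 3 cells")
  }
  x1 <- as.matrix(expr[, idx[[group]], drop = FALSE])
  x2 <- as.matrix(expr[, idx[[reference_group]], drop = FALSE])
  de <- rank_sum_test(x1, x2)
  de$lfc <- rowMeans(x1) - rowMeans(x2)
  qual <- de[abs(de$lfc) >= min_abs_lfc, ]
  pick <- function(side) {
    d <- qual[sign(qual$lfc) == side, ]
    d <- d[order(-abs(d$z), d$gene), ]
    utils::head(d$gene, top_n)
  }
  up <- pick(1)
  down <- if (direction == "both") pick(-1) else character(0)
  if (!length(up))
    stop("no qualifying up genes for '", group, "' vs '", reference_group, "'")
  sig <- gene_signature(paste0(group, "_vs_", reference_group),
                        up_genes = up, down_genes = down)
  short <- length(up) < top_n ||
    (direction == "both" && length(down) < top_n)
  if (short) {
    msg <- paste0("fewer than top_n = ", top_n, " qualifying genes (",
                  length(up), " up, ", length(down), " down)")
    warning(msg)
    attr(sig, "warning") <- msg
  }
  attr(sig, "stats") <- de
  sig
}
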
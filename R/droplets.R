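#' Rank barcodes by total count
#'
#' Sorts barcodes by total UMI (or antibody) count, descending, with stable
#' lexicographic tie-breaking by barcode identifier. The resulting curve is
#' the input to inflection-point cell calling.
#'
#' @param counts features x barcodes count matrix (sparse or dense) with
#'   barcode column names.
#' @return a data.frame of class `rank_curve` with columns `rank`, `total`,
#'   `barcode`, ordered by decreasing `total`.
#' @export
rank_barcodes <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (is.null(colnames(counts))) stop("counts must carry barcode column names")
  if (all(totals == 0)) stop("no populated barcodes")
  ord <- order(-totals, colnames(counts), method = "radix")
  out <- data.frame(rank = seq_along(ord), total = unname(totals[ord]),
                    barcode = colnames(counts)[ord], stringsAsFactors = FALSE)
  class(out) <- c("rank_curve", "data.frame")
  out
}

#' Locate the inflection point of a barcode rank curve
#'
#' Finds the steepest drop of the smoothed log10(total) versus log10(rank)
#' curve — the inflection separating cell-containing droplets from ambient
#' droplets — within a rank search window. The first derivative between
#' consecutive ranks is assigned to the lower rank (the bottom of the drop),
#' so on a two-plateau curve the returned threshold is the lower plateau's
#' total and "strictly above threshold" calls exactly the upper plateau.
#'
#' @param curve a [rank_barcodes()] result.
#' @param min_rank,max_rank search window in rank space; defaults exclude the
#'   unstable extreme head (first 10 ranks) and tail (beyond 99% of populated
#'   barcodes). `max_rank = NULL` uses the default.
#' @param window centered moving-average window (in distinct total values)
#'   used to smooth log-total before differentiation. Tied totals are first
#'   collapsed to one point per distinct value at its mean rank: raw UMI
#'   curves are step-like and per-rank derivatives degenerate on ties.
#' @param slope_tol a drop is only accepted when the steepest smoothed
#'   log-log slope is below this value; a curve without a drop clearly
#'   steeper than power-law decay has no inflection.
#' @param tail_quantile candidate points with totals below this quantile of
#'   the positive totals are excluded: at single-digit totals the curve is
#'   dominated by integer quantization steps whose log-log slopes are
#'   artifacts, not the cell/ambient boundary. Quantiles scale with the
#'   totals, so calling stays invariant under rescaling.
#' @return the total-count threshold (numeric scalar) with attribute `rank`,
#'   the rank at which it was found. Barcodes with total strictly above the
#'   threshold are called cells.
#' @export
find_inflection <- function(curve, min_rank = 10L, max_rank = NULL,
                            window = 21L, slope_tol = -2,
                            tail_quantile = 0.05) {
  stopifnot(inherits(curve, "rank_curve") || is.data.frame(curve))
  pos <- curve$total > 0
  total <- curve$total[pos]
  n <- length(total)
  if (n < 2L) stop("rank curve has fewer than 2 populated barcodes")
  if (is.null(max_rank)) max_rank <- max(2L, floor(0.99 * n))
  max_rank <- min(max_rank, n)
  if (min_rank >= max_rank)
    stop("min_rank must be below max_rank (<= populated barcodes)")

  # collapse ties: one point per distinct total at its mean rank, so the
  # derivative is defined (UMI curves are step functions of the rank)
  uniq <- unique(total)                       # descending, totals are sorted
  mean_rank <- vapply(split(seq_len(n), match(total, uniq)), mean, numeric(1))
  m <- length(uniq)
  if (m < 2L) stop("no inflection found: curve is flat")

  x <- log10(mean_rank)
  y <- log10(uniq)
  w <- min(as.integer(window), if (m %% 2L == 1L) m else m - 1L)
  if (w >= 3L) {
    ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]            # keep raw values at the edges
  } else ys <- y

  d <- diff(ys) / diff(x)                    # slope between points i and i+1
  step <- diff(y)                            # raw drop between distinct totals
  floor_total <- stats::quantile(total, tail_quantile, names = FALSE)
  cand <- seq_len(m - 1L)
  cand <- cand[mean_rank[cand + 1L] >= min_rank &
                 mean_rank[cand + 1L] <= max_rank &
                 uniq[cand + 1L] >= floor_total]
  if (!length(cand)) stop("search window contains no ranks")
  dmin <- min(d[cand])
  # an inflection is either a steep smoothed log-log slope or an outright
  # cliff: a more-than-threefold drop between consecutive distinct totals
  # (long plateaus dilute the log-rank slope of a genuine cliff)
  cliff <- min(step[cand]) <= log10(1 / 3)
  if (!is.finite(dmin) || (dmin > slope_tol && !cliff))
    stop("no inflection found: steepest log-log slope ",
         format(dmin, digits = 3), " does not exceed tolerance ", slope_tol)
  at <- if (dmin <= slope_tol) cand[which.min(d[cand])] + 1L
        else cand[which.min(step[cand])] + 1L
  structure(uniq[at], rank = mean_rank[at])
}

#' Call cell-containing barcodes from RNA and antibody count curves
#'
#' Cells are droplets with high RNA *and* high total antibody counts: the set
#' of barcodes above the RNA rank-curve inflection threshold intersected with
#' the set above the antibody-curve threshold.
#'
#' @param counts genes x barcodes RNA count matrix.
#' @param adt_counts antibody-tags x barcodes count matrix sharing the
#'   barcode space.
#' @param ... passed to [find_inflection()] (window, search bounds).
#' @return character vector of called cell barcodes (possibly empty, with a
#'   warning). Attributes `rna_threshold` and `adt_threshold` record the two
#'   inflection thresholds.
#' @export
call_cells <- function(counts, adt_counts, ...) {
  shared <- intersect(colnames(counts), colnames(adt_counts))
  if (!length(shared))
    stop("RNA and antibody matrices have disjoint barcode spaces")
  counts <- counts[, shared, drop = FALSE]
  adt_counts <- adt_counts[, shared, drop = FALSE]
  rna_curve <- rank_barcodes(counts)
  adt_curve <- rank_barcodes(adt_counts)
  thr_rna <- find_inflection(rna_curve, ...)
  thr_adt <- find_inflection(adt_curve, ...)
  rna_cells <- rna_curve$barcode[rna_curve$total > thr_rna]
  adt_cells <- adt_curve$barcode[adt_curve$total > thr_adt]
  called <- intersect(rna_cells, adt_cells)
  if (!length(called))
    warning("no barcode passes both the RNA and antibody thresholds")
  structure(sort(called), rna_threshold = as.numeric(thr_rna),
            adt_threshold = as.numeric(thr_adt))
}
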
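#' Quality-control filtering of called cells
#'
#' Applies the four exclusion rules used for droplet single-cell QC: cells are
#' removed when they have fewer than `min_rna` RNA counts, over
#' `max_mito_frac` of counts mapping to mitochondrial genes (dead cells),
#' fewer than `min_adt` total antibody (TotalSeq-C) counts, or positivity for
#' two isotype controls (non-specific antibody binding). The filters are
#' conjunctive — a cell is kept iff it passes all four — and attrition is
#' tallied per filter against the full input, so a cell failing two filters is
#' counted under both. Boundary conventions follow the wording: "fewer than
#' 500" removes 499 and keeps 500; "over 10%" keeps a fraction of exactly
#' 0.10.
#'
#' @param counts genes x barcodes RNA count matrix.
#' @param adt_counts antibody-tags x barcodes count matrix over the same
#'   barcodes.
#' @param mito_genes character vector of mitochondrial gene names; by default
#'   genes matching the mouse `^mt-` prefix. If empty, the mitochondrial
#'   filter is skipped with a warning and recorded as skipped.
#' @param isotype_controls character vector of isotype-control feature names
#'   in `adt_counts`; if empty the isotype filter is skipped (recorded).
#' @param min_rna minimum RNA counts ("fewer than `min_rna`" removed).
#' @param max_mito_frac mitochondrial fraction strictly above which a cell is
#'   removed.
#' @param min_adt minimum total antibody counts.
#' @param isotype_positive_threshold count at or above which an isotype
#'   channel is positive; a cell with two or more positive isotype controls
#'   is removed.
#' @return list of class `qc_report`: `kept` (barcodes passing all filters),
#'   `removed` (per-filter removal counts: `low_rna`, `high_mito`, `low_adt`,
#'   `isotype_double_positive`), `skipped` (filters not applied),
#'   `thresholds`, `n_input`.
#' @export
filter_cells <- function(counts, adt_counts,
                         mito_genes = grep("^mt-", rownames(counts), value = TRUE),
                         isotype_controls = grep("^Isotype", rownames(adt_counts),
                                                 value = TRUE),
                         min_rna = 500, max_mito_frac = 0.10, min_adt = 500,
                         isotype_positive_threshold = 10) {
  bcs <- colnames(counts)
  if (is.null(bcs) || is.null(colnames(adt_counts)))
    stop("count matrices must carry barcode column names")
  if (!setequal(bcs, colnames(adt_counts)))
    stop("RNA and antibody matrices cover different barcodes")
  adt_counts <- adt_counts[, bcs, drop = FALSE]
  bad_iso <- setdiff(isotype_controls, rownames(adt_counts))
  if (length(bad_iso))
    stop("isotype controls absent from antibody matrix: ",
         paste(bad_iso, collapse = ", "))

  rna_total <- Matrix::colSums(counts)
  adt_total <- Matrix::colSums(adt_counts)
  skipped <- character(0)

  low_rna <- rna_total < min_rna
  low_adt <- adt_total < min_adt

  mito_genes <- intersect(mito_genes, rownames(counts))
  if (length(mito_genes) == 0L) {
    warning("no mitochondrial genes found; mitochondrial filter skipped")
    skipped <- c(skipped, "high_mito")
    high_mito <- rep(FALSE, length(bcs))
  } else {
    mito_total <- Matrix::colSums(counts[mito_genes, , drop = FALSE])
    frac <- ifelse(rna_total > 0, mito_total / rna_total, 0)
    high_mito <- frac > max_mito_frac
  }

  if (length(isotype_controls) == 0L) {
    warning("no isotype controls given; isotype filter skipped")
    skipped <- c(skipped, "isotype_double_positive")
    iso_dp <- rep(FALSE, length(bcs))
  } else {
    pos <- Matrix::colSums(adt_counts[isotype_controls, , drop = FALSE] >=
                             isotype_positive_threshold)
    iso_dp <- pos >= 2
  }

  keep <- !(low_rna | high_mito | low_adt | iso_dp)
  out <- list(
    kept = bcs[keep],
    removed = c(low_rna = sum(low_rna), high_mito = sum(high_mito),
                low_adt = sum(low_adt), isotype_double_positive = sum(iso_dp)),
    skipped = skipped,
    thresholds = list(min_rna = min_rna, max_mito_frac = max_mito_frac,
                      min_adt = min_adt,
                      isotype_positive_threshold = isotype_positive_threshold),
    n_input = length(bcs))
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "cells in,", length(x$kept), "kept\n")
  cat("removed per filter (tallied independently):\n")
  for (nm in names(x$removed))
    cat(sprintf("  %-24s %d%s\n", nm, x$removed[[nm]],
                if (nm %in% x$skipped) " (skipped)" else ""))
  invisible(x)
}
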
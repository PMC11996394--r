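#' Assign cells to samples from hashtag counts
#'
#' Implements the threshold rule used for hashtag demultiplexing: a cell is
#' assigned to the hashtag with the highest signal provided that signal has at
#' least `min_counts` counts and is more than `ratio` times the second most
#' abundant hashtag. Droplets containing two hashtags — both the top and the
#' second tag at or above `doublet_positive_threshold` while the top is not
#' more than `ratio` times the second — are labelled `DOUBLET` and excluded
#' from assignment. Everything else is `UNASSIGNED`. The rule operates on raw
#' counts; no normalization is applied. Ties for the top tag at or above the
#' positivity threshold are doublets.
#'
#' @param hashtag_counts hashtags x barcodes count matrix (hashtag rows only),
#'   restricted to called cells.
#' @param sample_map optional named character vector mapping hashtag feature
#'   name to sample label; defaults to the hashtag names themselves.
#' @param min_counts minimum top-tag count for assignment ("at least" = `>=`).
#' @param ratio the top tag must exceed `ratio` x second tag (strict `>`,
#'   "more than double").
#' @param doublet_positive_threshold count at or above which a tag is
#'   considered positive when testing for two-hashtag droplets.
#' @return data.frame of class `demux_result` with columns `barcode`,
#'   `assignment` (sample label, `"DOUBLET"` or `"UNASSIGNED"`), `top_tag`,
#'   `top_count`, `second_count`.
#' @export
demultiplex <- function(hashtag_counts, sample_map = NULL, min_counts = 10,
                        ratio = 2.0, doublet_positive_threshold = 10) {
  if (nrow(hashtag_counts) < 2L)
    stop("demultiplexing rule requires >= 2 hashtags")
  tags <- rownames(hashtag_counts)
  if (is.null(tags)) stop("hashtag_counts must carry hashtag row names")
  if (is.null(sample_map)) sample_map <- stats::setNames(tags, tags)
  missing_tags <- setdiff(tags, names(sample_map))
  if (length(missing_tags))
    stop("sample_map lacks tags: ", paste(missing_tags, collapse = ", "))

  m <- as.matrix(hashtag_counts)
  n <- ncol(m)
  assignment <- character(n); top_tag <- character(n)
  top_count <- numeric(n); second_count <- numeric(n)
  for (j in seq_len(n)) {
    cj <- m[, j]
    ord <- order(cj, decreasing = TRUE)
    c1 <- cj[ord[1L]]; c2 <- cj[ord[2L]]
    top_tag[j] <- tags[ord[1L]]
    top_count[j] <- c1; second_count[j] <- c2
    singlet <- c1 >= min_counts && c1 > ratio * c2
    if (c1 >= doublet_positive_threshold && c2 >= doublet_positive_threshold &&
        !(c1 > ratio * c2)) {
      assignment[j] <- "DOUBLET"
    } else if (singlet) {
      assignment[j] <- unname(sample_map[top_tag[j]])
    } else {
      assignment[j] <- "UNASSIGNED"
    }
  }
  out <- data.frame(barcode = colnames(m), assignment = assignment,
                    top_tag = top_tag, top_count = top_count,
                    second_count = second_count, stringsAsFactors = FALSE)
  class(out) <- c("demux_result", "data.frame")
  out
}
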
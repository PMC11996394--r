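#' Cluster frequencies by condition
#'
#' Tabulates, for each condition, the number and within-condition fraction of
#' cells in each transcriptional cluster (the percentage-of-cells-per-cluster
#' comparison between treatment sites). Clusters absent from a condition are
#' reported with zero.
#'
#' @param clusters cluster label per barcode (named, or aligned with
#'   `conditions`).
#' @param conditions condition label per barcode.
#' @return data.frame: `condition`, `cluster`, `count`, `fraction`; fractions
#'   sum to 1 within each condition.
#' @export
cluster_frequencies <- function(clusters, conditions) {
  if (length(clusters) != length(conditions))
    stop("clusters and conditions must cover the same barcodes")
  if (!is.null(names(clusters)) && !is.null(names(conditions))) {
    if (!setequal(names(clusters), names(conditions)))
      stop("clusters and conditions must cover the same barcodes")
    conditions <- conditions[names(clusters)]
  }
  if (any(is.na(clusters)) || any(is.na(conditions)))
    stop("every barcode needs both a cluster and a condition label")
  # factors keep their levels, so a declared-but-empty condition is an error
  tab <- table(condition = conditions, cluster = clusters)
  if (any(rowSums(tab) == 0))
    stop("empty condition: ",
         paste(rownames(tab)[rowSums(tab) == 0], collapse = ", "))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[names(df) == "Freq"] <- "count"
  totals <- stats::setNames(rowSums(tab), rownames(tab))
  df$fraction <- df$count / totals[df$condition]
  df[order(df$condition, df$cluster), c("condition", "cluster", "count",
                                        "fraction")]
}

#' Epidermal cell density per mm^2
#'
#' Averages per-image cell counts over equal-area fields — by protocol three
#' randomly placed 1 mm^2 images per epidermal sheet — giving cells per mm^2
#' as representative of the sheet. Unequal field areas are rejected unless
#' explicitly allowed, in which case the pooled density
#' `sum(counts) / sum(areas)` is returned.
#'
#' @param per_image_counts non-negative cell counts, one per image.
#' @param area_per_image field area(s) in mm^2 (scalar or per image).
#' @param allow_unequal permit unequal field areas.
#' @return cells per mm^2 (numeric scalar).
#' @export
epidermal_density <- function(per_image_counts, area_per_image = 1,
                              allow_unequal = FALSE) {
  if (any(per_image_counts < 0)) stop("counts must be non-negative")
  areas <- rep_len(area_per_image, length(per_image_counts))
  if (any(areas <= 0)) stop("areas must be positive")
  if (!allow_unequal && length(unique(areas)) > 1L)
    stop("unequal field areas; protocol specifies equal fields ",
         "(set allow_unequal = TRUE to pool)")
  sum(per_image_counts) / sum(areas)
}

.t_result <- function(statistic, p, df, estimate) {
  list(statistic = unname(statistic), p_value = unname(p), df = unname(df),
       estimate = unname(estimate))
}

#' Two-tailed paired Student's t test
#'
#' For left/right flank comparisons within animals. Degenerate inputs follow
#' the convention: zero-variance differences give p = 1 when the means are
#' equal (statistic 0) and p = 0 (infinite statistic) when they are not.
#'
#' @param x,y paired measurement vectors of equal length >= 2.
#' @return list: `statistic`, `p_value`, `df`, `estimate` (mean difference).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (mean(d) == 0) return(.t_result(0, 1, length(d) - 1, 0))
    return(.t_result(sign(mean(d)) * Inf, 0, length(d) - 1, mean(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  .t_result(tt$statistic, tt$p.value, tt$parameter, tt$estimate)
}

#' Two-tailed unpaired Student's t test
#'
#' Classic equal-variance Student's t for between-animal comparisons.
#'
#' @param x,y measurement vectors, each of length >= 2.
#' @param var_equal pool variances (Student's test); `FALSE` gives Welch.
#' @return list: `statistic`, `p_value`, `df`, `estimate` (mean difference).
#' @export
unpaired_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (stats::sd(c(x, y)) == 0) {
    return(.t_result(0, 1, length(x) + length(y) - 2, 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  .t_result(tt$statistic, tt$p.value, tt$parameter,
            tt$estimate[1] - tt$estimate[2])
}

#' Dunnett many-to-one comparisons against a single control
#'
#' Compares each treatment group to one control with familywise error control
#' (two-sided Dunnett test: single-step adjustment over the correlated
#' multivariate-t of the contrasts, evaluated by `multcomp`'s integration of
#' the multivariate t distribution). With a single treatment it reduces to the
#' pooled two-sample Student's t decision.
#'
#' @param control numeric vector, the control group (>= 2 values).
#' @param treatments named list of numeric vectors (each >= 2 values).
#' @param seed optional seed: the multivariate-t probabilities are evaluated
#'   by randomized quasi-Monte-Carlo, so a seed makes the adjusted p values
#'   reproducible to that tolerance.
#' @return data.frame per treatment: `treatment`, `estimate` (treatment minus
#'   control mean), `statistic`, `p_unadjusted` (pooled two-sample t),
#'   `p_adjusted` (Dunnett).
#' @export
many_to_one <- function(control, treatments, seed = NULL) {
  if (!is.list(treatments)) treatments <- list(treatment = treatments)
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))))
    names(treatments) <- paste0("treatment", seq_along(treatments))
  if (length(control) < 2L || any(lengths(treatments) < 2L))
    stop("each group needs >= 2 values")
  y <- c(control, unlist(treatments, use.names = FALSE))
  g <- factor(rep(c("control", names(treatments)),
                  c(length(control), lengths(treatments))),
              levels = c("control", names(treatments)))
  if (stats::sd(y) == 0) {
    return(data.frame(treatment = names(treatments), estimate = 0,
                      statistic = 0, p_unadjusted = 1, p_adjusted = 1,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
  if (!is.null(seed)) set.seed(seed)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)   # single-step (Dunnett) adjustment
  # unadjusted analogue: same contrasts and pooled error, no multiplicity
  p_un <- 2 * stats::pt(-abs(unname(sm$test$tstat)), stats::df.residual(fit))
  data.frame(treatment = names(treatments),
             estimate = unname(sm$test$coefficients),
             statistic = unname(sm$test$tstat),
             p_unadjusted = pmin(pmax(as.numeric(p_un), 0), 1),
             p_adjusted = pmin(pmax(as.numeric(sm$test$pvalues), 0), 1),
             stringsAsFactors = FALSE)
}
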
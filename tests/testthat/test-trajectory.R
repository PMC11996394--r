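# one staged reference shared across trajectory tests
staged_ref <- function(seed = 61, n_timepoints = 3, genes_per_stage = 20,
                       n_genes = 600, samples_per_stage = 20, effect = 2) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    signature_effect = effect)
  ref <- generate_staged_reference(n_timepoints, genes_per_stage, cfg,
                                   samples_per_stage = samples_per_stage)
  expr <- normalize_and_log(ref$counts)
  labels <- stats::setNames(as.character(ref$stages), colnames(ref$counts))
  list(ref = ref, expr = expr, labels = labels, cfg = cfg)
}

test_that("timepoint signatures recover planted stage programs in order", {
  fx <- staged_ref()
  sigs <- suppressWarnings(
    build_timepoint_signatures(fx$expr, fx$ref$stages, "naive", top_n = 20,
                               direction = "up"))
  expect_identical(names(sigs), names(fx$ref$truth$planted))
  for (s in names(sigs))
    expect_gte(mean(fx$ref$truth$planted[[s]] %in% sigs[[s]]$up_genes), 0.9)
})

test_that("duplicated stages yield near-identical signatures", {
  fx <- staged_ref()
  # append a copy of the first timepoint's samples under a new label
  s1 <- names(fx$ref$truth$planted)[1]
  cols <- names(fx$labels)[fx$labels == s1]
  dup_expr <- cbind(fx$expr, fx$expr[, cols])
  colnames(dup_expr) <- c(colnames(fx$expr), paste0("dup_", cols))
  labels <- c(fx$labels,
              stats::setNames(rep("dup", length(cols)), paste0("dup_", cols)))
  a <- suppressWarnings(derive_signature(dup_expr, labels, s1, "naive",
                                         top_n = 20, direction = "up"))
  b <- suppressWarnings(derive_signature(dup_expr, labels, "dup", "naive",
                                         top_n = 20, direction = "up"))
  expect_gte(length(intersect(a$up_genes, b$up_genes)) /
               length(union(a$up_genes, b$up_genes)), 0.8)
})

test_that("a missing naive stage and an oversized top_n are handled", {
  fx <- staged_ref()
  expect_error(build_timepoint_signatures(fx$expr, fx$ref$stages,
                                          "no-such-stage"), "naive")
  sigs <- suppressWarnings(
    build_timepoint_signatures(fx$expr, fx$ref$stages, "naive", top_n = 500))
  expect_true(all(vapply(sigs, function(s) length(s$up_genes), 1L) < 500))
  # the shortfall is recorded on each signature
  expect_true(all(vapply(sigs, function(s)
    grepl("fewer than top_n", attr(s, "warning")), logical(1))))
})

test_that("trajectory scores separate full from arrested differentiation", {
  fx <- staged_ref()
  sigs <- suppressWarnings(
    build_timepoint_signatures(fx$expr, fx$ref$stages, "naive", top_n = 20,
                               direction = "up"))
  stages <- names(fx$ref$truth$planted)
  full <- simulate_stage_query(fx$ref, stages, 40, fx$cfg, seed = 71)
  early <- simulate_stage_query(fx$ref, stages[1], 40, fx$cfg, seed = 72)
  q <- cbind(full, early)
  colnames(q) <- sprintf("q%03d", seq_len(ncol(q)))
  expr <- center_genes(normalize_and_log(q))
  groups <- stats::setNames(rep(c("full", "early"), each = 40), colnames(q))
  prof <- score_trajectory(expr, groups, sigs, n_iter = 100, seed = 81)
  expect_s3_class(prof, "trajectory_profile")
  expect_identical(levels(prof$timepoint), stages)
  last <- prof[prof$timepoint == stages[length(stages)], ]
  expect_gt(last$adjusted_score[last$group == "full"],
            last$adjusted_score[last$group == "early"])
  expect_error(score_trajectory(expr, c(ghost = "g"), sigs),
               "absent")
})

test_that("a query with no planted programs scores at the randomized baseline", {
  fx <- staged_ref()
  sigs <- suppressWarnings(
    build_timepoint_signatures(fx$expr, fx$ref$stages, "naive", top_n = 20,
                               direction = "up"))
  null <- simulate_stage_query(fx$ref, character(0), 60, fx$cfg, seed = 73)
  expr <- center_genes(normalize_and_log(null))
  groups <- stats::setNames(rep(c("nullA", "nullB"), 30), colnames(expr))
  prof <- score_trajectory(expr, groups, sigs, n_iter = 200, seed = 82)
  se <- (prof$ci_high - prof$ci_low) / (2 * 1.96)
  expect_true(all(abs(prof$adjusted_score) <= 3 * (prof$control_sd + se)))
})

test_that("single-signature trajectories reduce to a plain adjusted score", {
  expr <- null_centered_matrix(80, 30, seed = 62)
  sig <- gene_signature("d05", paste0("g", 1:10))
  groups <- stats::setNames(rep(c("A", "B"), 15), colnames(expr))
  prof <- score_trajectory(expr, groups, list(sig), n_iter = 50, seed = 3)
  ref <- score_signature_adjusted(expr, sig, groups, n_iter = 50, seed = 3)
  expect_equal(prof$adjusted_score, ref$adjusted_score)
  expect_equal(prof$random_baseline, ref$control_mean)
})

test_that("profiles are invariant to cell order and additive over groups", {
  expr <- null_centered_matrix(60, 24, seed = 63)
  sig <- gene_signature("t", paste0("g", 1:8), paste0("g", 9:12))
  groups <- stats::setNames(rep(c("A", "B"), each = 12), colnames(expr))
  perm <- sample(ncol(expr))
  expr_p <- expr[, perm]
  attr(expr_p, "centered") <- TRUE
  a <- score_signature(expr, sig, groups)
  b <- score_signature(expr_p, sig, groups[colnames(expr_p)])
  expect_equal(a$raw_score, b$raw_score)
  # merging groups gives the cell-count-weighted mean of their scores
  merged <- stats::setNames(rep("AB", 24), colnames(expr))
  m <- score_signature(expr, sig, merged)
  w <- sum(a$raw_score * a$n_cells) / sum(a$n_cells)
  expect_equal(m$raw_score, w, tolerance = 1e-12)
})
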
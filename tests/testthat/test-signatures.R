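test_that("signature construction enforces disjoint non-empty sets", {
  expect_error(gene_signature("s", character(0)), "no up genes")
  expect_error(gene_signature("s", c("a", "b"), c("b")), "overlap")
  s <- gene_signature("s", c("a", "a", "b"))
  expect_identical(s$up_genes, c("a", "b"))
})

test_that("cp10k normalization has its closed form on uniform counts", {
  m <- toy_counts(matrix(7, nrow = 5, ncol = 3))
  norm <- normalize_and_log(m, "cp10k")
  expect_equal(unname(norm[1, 1]), log2(1e4 / 5 + 1))
  expect_true(all(abs(norm - norm[1, 1]) < 1e-12))
  z <- toy_counts(matrix(c(0, 10), 2, 1))
  expect_equal(unname(normalize_and_log(z, "cp10k")[1, 1]), 0)
})

test_that("TPM matches the hand-computed length-rate formula", {
  m <- toy_counts(matrix(c(10, 10), 2, 1), genes = c("gA", "gB"))
  lengths <- c(gA = 1000, gB = 2000)
  norm <- normalize_and_log(m, "tpm", gene_lengths = lengths)
  expect_equal(unname(2^norm[, 1] - 1), c(666666.67, 333333.33),
               tolerance = 1e-6)
  expect_error(normalize_and_log(m, "tpm"), "gene lengths")
})

test_that("gene centering is exact, flagged, and idempotent with a warning", {
  m <- toy_counts(matrix(c(1, 2, 3), nrow = 1, ncol = 3))
  cm <- center_genes(m)
  expect_equal(unname(cm[1, ]), c(-1, 0, 1))
  expect_true(attr(cm, "centered"))
  expect_warning(cm2 <- center_genes(cm), "already centered")
  expect_equal(unname(cm2[1, ]), unname(cm[1, ]))
  big <- null_centered_matrix(50, 30, seed = 2)
  expect_lt(max(abs(rowMeans(big))), 1e-8)
})

test_that("the score formula is forced on constructed cells", {
  expr <- as_centered(toy_counts(rbind(u1 = 1, u2 = 1, d1 = -1, d2 = -1)))
  sig <- gene_signature("s", c("u1", "u2"), c("d1", "d2"))
  res <- score_signature(expr, sig, c(bc1 = "g"))
  expect_equal(res$raw_score, 2)
  # duplicated content in up and down cancels
  expr2 <- as_centered(toy_counts(rbind(a = 0.7, b = -0.3, a2 = 0.7,
                                        b2 = -0.3)))
  sig2 <- gene_signature("sym", c("a", "b"), c("a2", "b2"))
  expect_equal(score_signature(expr2, sig2, c(bc1 = "g"))$raw_score, 0)
  # missing up genes are dropped and counted; none present is an error
  sig3 <- gene_signature("partial", c("u1", "ghost"))
  res3 <- score_signature(expr, sig3, c(bc1 = "g"))
  expect_equal(res3$n_up_used, 1)
  sig4 <- gene_signature("absent", "ghost")
  expect_error(score_signature(expr, sig4, c(bc1 = "g")), "absent")
})

test_that("scores equal an element-wise brute-force recomputation", {
  for (seed in 1:25) {
    set.seed(seed)
    ng <- sample(3:10, 1); nc <- sample(2:10, 1)
    expr <- center_genes(matrix(rnorm(ng * nc), ng, nc,
                                dimnames = list(paste0("g", 1:ng),
                                                paste0("c", 1:nc))))
    up <- sample(rownames(expr), sample(1:2, 1))
    down <- sample(setdiff(rownames(expr), up), sample(0:2, 1))
    groups <- stats::setNames(sample(c("A", "B"), nc, replace = TRUE),
                              colnames(expr))
    if (length(unique(groups)) < 2) groups[1] <- setdiff(c("A", "B"), groups)
    sig <- gene_signature("t", up, down)
    got <- score_signature(expr, sig, groups)
    want <- brute_force_score(expr, up, down, groups[colnames(expr)])
    for (g in got$group)
      expect_equal(got$raw_score[got$group == g], want[[g]],
                   tolerance = 1e-10)
  }
})

test_that("scores are invariant to gene and cell order, shifts of one gene, and scale linearly", {
  expr <- null_centered_matrix(40, 25, seed = 3)
  sig <- gene_signature("t", paste0("g", 1:5), paste0("g", 6:9))
  groups <- stats::setNames(rep(c("A", "B"), c(12, 13)), colnames(expr))
  base <- score_signature(expr, sig, groups)
  perm <- expr[sample(nrow(expr)), sample(ncol(expr))]
  attr(perm, "centered") <- TRUE
  expect_equal(score_signature(perm, sig, groups)$raw_score, base$raw_score)
  # adding a constant to one gene across all cells disappears in centering
  raw <- null_centered_matrix(40, 25, seed = 3)
  attr(raw, "centered") <- FALSE
  shifted <- raw; shifted["g3", ] <- shifted["g3", ] + 5
  expect_equal(score_signature(center_genes(shifted), sig, groups)$raw_score,
               score_signature(center_genes(raw), sig, groups)$raw_score,
               tolerance = 1e-10)
  # linearity
  scaled <- expr * 3; attr(scaled, "centered") <- TRUE
  expect_equal(score_signature(scaled, sig, groups)$raw_score,
               3 * base$raw_score, tolerance = 1e-10)
})

test_that("the random control is seeded, bounded, and calibrated on nulls", {
  expr <- null_centered_matrix(100, 40, seed = 4)
  groups <- stats::setNames(rep(c("A", "B"), each = 20), colnames(expr))
  a <- random_control(expr, 5, 3, groups, n_iter = 2, seed = 9)
  b <- random_control(expr, 5, 3, groups, n_iter = 2, seed = 9)
  expect_identical(a, b)
  expect_error(random_control(expr, 80, 30, groups), "exceeds")
  cal <- random_control(expr, 10, 10, groups, n_iter = 500, seed = 10)
  expect_true(all(abs(cal$control_mean) < 3 * cal$control_sd / sqrt(500)
                  + 1e-12))
})

test_that("adjusted scores subtract the control exactly and bracket within the CI", {
  fx <- planted_fixture(seed = 51)
  res <- score_signature_adjusted(fx$expr, fx$sim$truth$signatures$group1,
                                  fx$groups, n_iter = fx$n_iter, seed = 1)
  expect_equal(res$adjusted_score, res$raw_score - res$control_mean)
  expect_true(all(res$ci_low <= res$adjusted_score + 1e-12 &
                  res$adjusted_score <= res$ci_high + 1e-12))
  # the planted group outscores the unplanted group on its own signature
  expect_gt(res$adjusted_score[res$group == "group1"],
            res$adjusted_score[res$group == "group2"])
})

test_that("pseudobulk mode collapses before scoring and reduces to cell mode for single cells", {
  expr <- null_centered_matrix(60, 10, seed = 6)
  sig <- gene_signature("t", paste0("g", 1:6), paste0("g", 7:10))
  cond <- stats::setNames(rep(c("A", "B"), each = 5), colnames(expr))
  # identical populations: duplicate the same cells under both labels
  dup <- cbind(expr[, 1:5], expr[, 1:5])
  colnames(dup) <- paste0("c", 1:10)
  attr(dup, "centered") <- TRUE
  same <- pseudobulk_scores(dup, cond, list(sig), mode = "pseudobulk",
                            n_iter = 50, seed = 2)
  expect_equal(diff(same$adjusted_score), 0, tolerance = 1e-12)
  # one cell per condition: pseudobulk equals cell mode
  one <- expr[, 1:2]
  attr(one, "centered") <- TRUE
  cond1 <- stats::setNames(c("A", "B"), colnames(one))
  pb <- pseudobulk_scores(one, cond1, list(sig), mode = "pseudobulk",
                          n_iter = 50, seed = 3)
  cm <- pseudobulk_scores(one, cond1, list(sig), mode = "cell",
                          n_iter = 50, seed = 3)
  expect_equal(pb$adjusted_score, cm$adjusted_score, tolerance = 1e-12)
  expect_error(pseudobulk_scores(expr, stats::setNames(rep("A", 10),
                                                       colnames(expr)),
                                 list(sig)), "two conditions")
})

test_that("pseudobulk separates planted from null condition", {
  fx <- planted_fixture(seed = 52)
  res <- pseudobulk_scores(fx$expr, fx$groups,
                           list(fx$sim$truth$signatures$group1),
                           mode = "pseudobulk", n_iter = fx$n_iter, seed = 4)
  expect_gt(res$adjusted_score[res$group == "group1"],
            res$adjusted_score[res$group == "group2"])
  expect_identical(unique(res$mode), "pseudobulk")
})

test_that("the vectorized rank-sum test matches wilcox.test", {
  set.seed(7)
  x1 <- matrix(rnorm(20 * 8), 20, 8,
               dimnames = list(paste0("g", 1:20), NULL))
  x2 <- matrix(rnorm(20 * 9, 0.5), 20, 9,
               dimnames = list(paste0("g", 1:20), NULL))
  x1[3, ] <- round(x1[3, ])  # provoke ties
  x2[3, ] <- round(x2[3, ])
  got <- trmsig:::rank_sum_test(x1, x2)
  for (i in seq_len(20)) {
    ref <- stats::wilcox.test(x1[i, ], x2[i, ], exact = FALSE,
                              correct = FALSE)
    expect_equal(got$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic[i], unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("derived signatures recover planted genes and respect the ranking contract", {
  fx <- planted_fixture(seed = 53, n_cells = 120, signature_effect = 2)
  truth_up <- fx$sim$truth$signatures$group1$up_genes
  sig <- suppressWarnings(
    derive_signature(fx$expr, fx$groups, "group1", "group2",
                     top_n = length(truth_up), direction = "up"))
  expect_gte(mean(truth_up %in% sig$up_genes), 0.9)
  # top_n = 1 picks the single most significant qualifying up gene
  one <- suppressWarnings(derive_signature(fx$expr, fx$groups, "group1",
                                           "group2", top_n = 1,
                                           direction = "up"))
  st <- attr(sig, "stats")
  qual <- st[st$lfc >= 0.25, ]
  expect_identical(one$up_genes, qual$gene[which.max(abs(qual$z))])
  # a group literally identical to its reference: every fold-change is zero,
  # nothing clears the gate at any min_abs_lfc > 0
  dup <- cbind(fx$expr[, 1:20], fx$expr[, 1:20])
  colnames(dup) <- paste0("c", 1:40)
  attr(dup, "centered") <- TRUE
  same_groups <- stats::setNames(rep(c("A", "B"), each = 20), colnames(dup))
  expect_error(suppressWarnings(
    derive_signature(dup, same_groups, "A", "B", top_n = 50,
                     min_abs_lfc = 0.01)),
    "no qualifying up genes")
})
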
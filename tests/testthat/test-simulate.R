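test_that("degenerate configurations are rejected with the violated bound", {
  expect_error(sim_config(n_cells = 0), "no cells to simulate")
  expect_error(sim_config(empty_mean_counts = 3000),
               "empty_mean_counts < cell_mean_counts")
  expect_error(sim_config(hashtag_signal = 15, hashtag_background = 5),
               "hashtag_signal > 2")
  expect_error(sim_config(n_hashtags = 1), ">= 2")
  expect_error(sim_config(doublet_fraction = 1), "\\[0, 1\\)")
})

test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(seed = 42, n_cells = 40, n_empty_droplets = 60,
                    n_genes = 120, genes_per_group = 10)
  a <- generate_droplet_experiment(cfg)
  b <- generate_droplet_experiment(cfg)
  expect_identical(a$rna, b$rna)
  expect_identical(a$adt, b$adt)
  expect_identical(a$truth$barcodes, b$truth$barcodes)
})

test_that("emitted matrices are non-negative integers aligned to identifiers", {
  cfg <- sim_config(seed = 5, n_cells = 30, n_empty_droplets = 40,
                    n_genes = 100, genes_per_group = 10)
  sim <- generate_droplet_experiment(cfg)
  for (m in list(sim$rna, sim$adt)) {
    expect_true(all(m@x >= 0))
    expect_true(all(m@x == round(m@x)))
    expect_identical(colnames(m), sim$truth$barcodes$barcode)
  }
  expect_equal(ncol(sim$rna), cfg$n_cells + cfg$n_empty_droplets)
  expect_equal(nrow(sim$rna), cfg$n_genes)
  # every barcode appears exactly once; doublets carry two sample labels
  expect_false(anyDuplicated(sim$truth$barcodes$barcode) > 0)
  dbl <- sim$truth$barcodes$sample_of_origin == "DOUBLET"
  dbl[is.na(dbl)] <- FALSE
  expect_true(all(!is.na(sim$truth$barcodes$sample_a[dbl])))
  expect_true(all(!is.na(sim$truth$barcodes$sample_b[dbl])))
})

test_that("mean total counts of singlet cells track the configured depth", {
  cfg <- sim_config(seed = 1, n_cells = 500, n_empty_droplets = 5000,
                    cell_mean_counts = 2000, empty_mean_counts = 50)
  sim <- generate_droplet_experiment(cfg)
  tr <- sim$truth$barcodes
  singlets <- tr$is_cell & tr$sample_of_origin != "DOUBLET"
  mean_cell <- mean(Matrix::colSums(sim$rna)[singlets])
  expect_lt(abs(mean_cell - 2000) / 2000, 0.05)
  mean_empty <- mean(Matrix::colSums(sim$rna)[!tr$is_cell])
  expect_lt(abs(mean_empty - 50) / 50, 0.10)
})

test_that("clean high-depth cells nearly all pass QC at default thresholds", {
  cfg <- sim_config(seed = 9, n_cells = 200, n_empty_droplets = 50,
                    n_genes = 500, genes_per_group = 20,
                    cell_mean_counts = 5000, doublet_fraction = 0,
                    mito_high_fraction = 0, sticky_fraction = 0)
  sim <- generate_droplet_experiment(cfg)
  cells <- sim$truth$barcodes$barcode[sim$truth$barcodes$is_cell]
  qc <- filter_cells(sim$rna[, cells], sim$adt[, cells])
  expect_gte(length(qc$kept) / length(cells), 0.99)
})

test_that("staged reference plants exactly genes_per_stage genes per stage", {
  ref <- generate_staged_reference(2, 10, sim_config(seed = 3, n_genes = 200))
  expect_length(ref$truth$planted, 2)
  expect_true(all(lengths(ref$truth$planted) == 10))
  expect_false(any(duplicated(unlist(ref$truth$planted))))
  expect_identical(levels(ref$stages)[1], "naive")
  expect_equal(ncol(ref$counts), length(ref$stages))
})

test_that("a zero-effect reference has no planted signal", {
  cfg <- sim_config(seed = 8, n_genes = 300, signature_effect = 0)
  ref <- generate_staged_reference(2, 15, cfg, samples_per_stage = 15)
  expr <- normalize_and_log(ref$counts)
  labels <- stats::setNames(as.character(ref$stages), colnames(ref$counts))
  # planted and non-planted genes are exchangeable: no gene clears the
  # fold-change gate against naive beyond chance
  for (s in names(ref$truth$planted)) {
    res <- tryCatch(
      suppressWarnings(derive_signature(expr, labels, s, "naive",
                                        top_n = 15, min_abs_lfc = 0.25)),
      error = function(e) NULL)
    overlap <- if (is.null(res)) 0
               else sum(ref$truth$planted[[s]] %in% res$up_genes)
    expect_lte(overlap, 3)   # no better than chance
  }
})

test_that("planted stage programs are recoverable at effect 2", {
  cfg <- sim_config(seed = 13, n_genes = 600, signature_effect = 2)
  ref <- generate_staged_reference(3, 20, cfg, samples_per_stage = 20)
  expr <- normalize_and_log(ref$counts)
  labels <- stats::setNames(as.character(ref$stages), colnames(ref$counts))
  for (s in names(ref$truth$planted)) {
    sig <- suppressWarnings(derive_signature(expr, labels, s, "naive",
                                             top_n = 20, direction = "up"))
    expect_gte(mean(ref$truth$planted[[s]] %in% sig$up_genes), 0.9)
  }
})

test_that("stage queries express only the requested programs", {
  cfg <- sim_config(seed = 17, n_genes = 400)
  ref <- generate_staged_reference(2, 15, cfg, samples_per_stage = 10)
  q <- simulate_stage_query(ref, names(ref$truth$planted)[1], n_cells = 20,
                            config = cfg, seed = 2)
  expect_identical(rownames(q), names(ref$truth$gene_means))
  expect_true(all(q >= 0) && all(q == round(q)))
  expect_error(simulate_stage_query(ref, "no-such-stage", config = cfg),
               "unknown stages")
})
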
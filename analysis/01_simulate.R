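#!/usr/bin/env Rscript
# Stage 1 — simulate the inputs every later stage consumes:
#  (a) a hashtag-multiplexed droplet experiment (real cells + empty droplets
#      + doublets + dying cells) with known ground truth, written as
#      MatrixMarket matrices, and
#  (b) a staged bulk reference of TRM differentiation (naive + ordered
#      timepoints with planted stage programs) for trajectory scoring.

suppressMessages(library(trmsig))

seed <- 2026L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
message("simulating droplet experiment: ", cfg$n_cells, " cells + ",
        cfg$n_empty_droplets, " empty droplets, ", cfg$n_genes, " genes, ",
        cfg$n_hashtags, " hashtags")
sim <- generate_droplet_experiment(cfg)

write_counts_mtx(sim$rna, file.path(out, "rna"))
write_counts_mtx(sim$adt, file.path(out, "adt"))
utils::write.csv(sim$truth$barcodes, file.path(out, "ground_truth.csv"),
                 row.names = FALSE)
write_gmt(sim$truth$signatures, file.path(out, "planted_signatures.gmt"))

tr <- sim$truth$barcodes
message("  doublets: ", sum(tr$sample_of_origin == "DOUBLET", na.rm = TRUE),
        ", high-mito cells: ", sum(tr$is_high_mito),
        ", sticky cells: ", sum(tr$is_sticky))

ref_cfg <- sim_config(seed = seed + 1L, n_genes = 1000)
ref <- generate_staged_reference(4, 50, ref_cfg, samples_per_stage = 20)
message("staged reference: stages ",
        paste(levels(ref$stages), collapse = " -> "),
        ", 50 planted genes per stage")
# samples x genes table with a stage-label column, the on-disk convention
# for bulk reference sets
ref_tab <- data.frame(sample = colnames(ref$counts),
                      stage = as.character(ref$stages),
                      t(ref$counts), check.names = FALSE)
utils::write.csv(ref_tab, file.path(out, "staged_reference.csv"),
                 row.names = FALSE)
utils::write.csv(
  data.frame(stage = rep(names(ref$truth$planted),
                         lengths(ref$truth$planted)),
             gene = unlist(ref$truth$planted)),
  file.path(out, "reference_planted_genes.csv"), row.names = FALSE)

message("wrote ", out)
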
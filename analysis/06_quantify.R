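#!/usr/bin/env Rscript
# Stage 6 — quantification statistics: cluster frequencies by treatment-site
# condition, epidermal cell densities from per-image counts, and the
# declared hypothesis tests (two-tailed paired/unpaired Student's t,
# Dunnett many-to-one).

suppressMessages(library(trmsig))

seed <- 2026L
dat <- "results/data"
out <- "results"
kept <- readLines(file.path(out, "kept_barcodes.tsv"))
dmx <- read_result_csv(file.path(out, "demux.csv"))
truth <- utils::read.csv(file.path(dat, "ground_truth.csv"))

clusters <- stats::setNames(truth$group[match(kept, truth$barcode)], kept)
assign <- stats::setNames(dmx$assignment, dmx$barcode)[kept]
condition <- stats::setNames(
  ifelse(as.integer(sub("sample", "", assign)) <= 2,
         "site_antigen", "site_bystander"), kept)

freq <- cluster_frequencies(clusters, condition)
write_result_csv(freq, file.path(out, "cluster_frequencies.csv"), seed)
message("cluster frequencies by condition:")
print(freq, digits = 3)

# epidermal density workflow: three 1-mm^2 images per flank per animal,
# paired left (antigen) / right (bystander) flanks
set.seed(seed)
n_animals <- 10
left <- vapply(seq_len(n_animals), function(i)
  epidermal_density(rpois(3, 60)), numeric(1))
right <- vapply(seq_len(n_animals), function(i)
  epidermal_density(rpois(3, 45)), numeric(1))
dens <- data.frame(animal = seq_len(n_animals), antigen_site = left,
                   bystander_site = right)
write_result_csv(dens, file.path(out, "epidermal_density.csv"), seed)
pt <- paired_t(left, right)
message(sprintf("paired t (left vs right flank densities): t = %.2f, p = %.3g",
                pt$statistic, pt$p_value))

ut <- unpaired_t(left, right)
message(sprintf("unpaired Student's t (between groups): t = %.2f, p = %.3g",
                ut$statistic, ut$p_value))

# Dunnett: each treated flank group against an untreated control
ctrl <- vapply(seq_len(n_animals), function(i)
  epidermal_density(rpois(3, 20)), numeric(1))
dn <- many_to_one(ctrl, list(antigen = left, bystander = right), seed = seed)
write_result_csv(dn, file.path(out, "dunnett_densities.csv"), seed)
message("Dunnett many-to-one vs untreated control:")
print(dn, digits = 3)
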
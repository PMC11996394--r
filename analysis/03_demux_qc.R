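#!/usr/bin/env Rscript
# Stage 3 — assign called cells to their sample of origin from hashtag
# counts (top tag with >= 10 counts and more than double the runner-up;
# two-positive droplets are doublets and excluded), then apply the four QC
# filters: < 500 RNA counts, > 10% mitochondrial counts, < 500 antibody
# counts, or double-positive isotype controls.

suppressMessages(library(trmsig))

seed <- 2026L
dat <- "results/data"
out <- "results"
rna <- read_counts_mtx(file.path(dat, "rna"))
adt <- read_counts_mtx(file.path(dat, "adt"))
called <- readLines(file.path(out, "called_barcodes.tsv"))

tags <- grep("^Hashtag", rownames(adt), value = TRUE)
samples <- sub("Hashtag", "sample", tags)
dmx <- demultiplex(adt[tags, called], stats::setNames(samples, tags))
write_result_csv(dmx, file.path(out, "demux.csv"), seed)
message("demultiplexed ", nrow(dmx), " cells: ",
        sum(!dmx$assignment %in% c("DOUBLET", "UNASSIGNED")), " singlets, ",
        sum(dmx$assignment == "DOUBLET"), " doublets, ",
        sum(dmx$assignment == "UNASSIGNED"), " unassigned")

singlets <- dmx$barcode[!dmx$assignment %in% c("DOUBLET", "UNASSIGNED")]
qc <- filter_cells(rna[, singlets], adt[, singlets])
print(qc)
writeLines(qc$kept, file.path(out, "kept_barcodes.tsv"))
jsonlite::write_json(qc[c("removed", "skipped", "thresholds", "n_input")],
                     file.path(out, "qc_report.json"), auto_unbox = TRUE,
                     pretty = TRUE)
message("kept ", length(qc$kept), " of ", qc$n_input, " singlets")
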
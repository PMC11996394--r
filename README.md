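# trmsig

Droplet processing and gene-signature enrichment scoring for
hashtag-multiplexed single-cell experiments on epidermal CD8+
tissue-resident memory T cells (TRM), built for the question of whether TRM
at a skin site containing cognate antigen become transcriptionally more
fully differentiated than bystander TRM at an inflamed site without it.

The pipeline covers, as tested R functions plus a numbered analysis
workflow:

1. **Cell calling** — inflection-point detection on the barcode rank curve
   (smoothed log-total vs log-rank), intersecting RNA and antibody
   (TotalSeq-C) thresholds (`rank_barcodes`, `find_inflection`,
   `call_cells`).
2. **Hashtag demultiplexing** — a cell is assigned to its top hashtag when
   that tag has ≥ 10 counts and more than double the second tag; droplets
   with two positive hashtags are doublets and excluded (`demultiplex`).
3. **Quality control** — remove cells with < 500 RNA counts, > 10%
   mitochondrial counts, < 500 antibody counts, or two positive isotype
   controls (`filter_cells`).
4. **Signature scoring** — on per-gene-centered log expression, the score of
   a signature with up-genes *U* and down-genes *D* in cell *c* is

   *score(c) = mean<sub>g∈U</sub> x<sub>gc</sub> − mean<sub>g∈D</sub>
   x<sub>gc</sub>*,

   averaged over a group's cells with a 95% CI, minus a random-gene-set
   control of matching size (`score_signature_adjusted`,
   `pseudobulk_scores`, `derive_signature`).
5. **Trajectory scoring** — per-timepoint signatures (top DEGs of each
   staged-reference timepoint vs naive) scored in order with a randomized
   baseline (`build_timepoint_signatures`, `score_trajectory`).
6. **Quantification** — cluster frequencies by condition, epidermal
   densities (cells/mm²), paired/unpaired two-tailed Student's t and
   Dunnett many-to-one tests (`cluster_frequencies`, `epidermal_density`,
   `paired_t`, `unpaired_t`, `many_to_one`).

A negative-binomial synthetic-data generator with known ground truth
(`sim_config`, `generate_droplet_experiment`, `generate_staged_reference`,
`simulate_stage_query`) makes every stage testable end to end; its defaults
(500 cells at ~2,000 UMI, 5,000 empty droplets at ~50 UMI, 4 hashtags,
signal 200 vs background 5, 5% doublets) are the study conditions of the
whole test suite. See the methods vignette
(`vignettes/trm-signature-workflow.Rmd`) for the model, parameter and
design-decision details.

## Worked example

```r
library(trmsig)

sim <- generate_droplet_experiment(sim_config(seed = 2026))
called <- call_cells(sim$rna, sim$adt)
tags <- grep("^Hashtag", rownames(sim$adt), value = TRUE)
dmx <- demultiplex(sim$adt[tags, called])
singlets <- dmx$barcode[!dmx$assignment %in% c("DOUBLET", "UNASSIGNED")]
qc <- filter_cells(sim$rna[, singlets], sim$adt[, singlets])

expr <- center_genes(normalize_and_log(sim$rna[, qc$kept]))
groups <- with(sim$truth$barcodes, setNames(group, barcode))[qc$kept]
score_signature_adjusted(expr, sim$truth$signatures$group2, groups,
                         n_iter = 1000, seed = 2026)
```

Running the full workflow (`Rscript analysis/01_simulate.R` …
`analysis/06_quantify.R`) prints, at these seeds:

* calling: `called 496 cells`, `precision 1.000, recall 0.992` against
  truth;
* demultiplexing: `472 singlets, 24 doublets, 0 unassigned`;
* QC: `kept 421 of 472 singlets` (32 high-mito, 20 isotype double-positive
  among the removals);
* scoring: the group carrying the planted program scores `adjusted_score =
  0.671` on its own signature versus `−0.714` for the other group, with the
  random control within ±0.008 of zero;
* trajectory: the fully differentiated query group scores `0.62–0.64` on the
  three late timepoint signatures where the early-arrested group sits at
  `−0.62 to −0.64`, while the early-arrested group is slightly ahead
  (`0.173` vs `−0.173`) at the first timepoint it actually expresses — the
  early/late divergence the trajectory analysis is built to detect;
* quantification: the planted site-biased cluster reaches a within-site
  fraction of `0.587` at the antigen site versus `0.321` at the bystander
  site.

Adjusted scores are population-relative (gene-centered), so a positive score
means "this group expresses the signature more than the other scored cells";
the random baseline near zero shows the size-matched control removes
coverage bias.

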
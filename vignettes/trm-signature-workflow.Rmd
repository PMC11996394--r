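---
title: "Signature scoring and droplet processing for epidermal TRM single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature scoring and droplet processing for epidermal TRM single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmsig)
```

## The problem

Skin CD8+ tissue-resident memory T cells (TRM) formed at a site of cognate
antigen differ transcriptionally from bystander TRM recruited by inflammation
alone. In a hashtag-multiplexed droplet single-cell experiment, cells from
several skin sites are pooled, sequenced together, and must be recovered
computationally: cell-containing droplets separated from ambient ones,
each cell assigned back to its sample by its hashtag, low-quality cells
removed, and the surviving cells scored for enrichment of reference
transcriptional states — TRM cores, activation, circulating memory — and for
their position along a staged differentiation time course. `trmsig`
implements that analysis as a tested pipeline, together with a synthetic-data
generator with known ground truth so every stage can be verified without any
external dataset.

The package is organized as an analysis workflow: `analysis/01_simulate.R`
through `analysis/06_quantify.R` are thin narrative drivers that call the
package functions and write tables under `results/`; all computation lives in
the package and is exercised by the test suite.

## Cell calling

Barcodes are ranked by total count (`rank_barcodes()`, descending, ties
broken lexicographically so the order is reproducible), and
`find_inflection()` locates the steepest drop of smoothed log10(total)
against log10(rank) — the boundary between the cell plateau and the ambient
plateau. `call_cells()` intersects the barcodes above the RNA threshold with
those above the total-antibody (TotalSeq-C) threshold: a cell must have high
counts in both modalities.

Numerical choices, all exposed as arguments:

* **Tie collapsing.** UMI curves are step functions; derivatives per rank
  degenerate on ties. The curve is first collapsed to one point per distinct
  total at its mean rank.
* **Smoothing.** A centered moving average over 21 distinct values before
  differentiation; raw curves are too jagged for a pointwise derivative.
* **Search window.** Ranks below 10 and above 99% of populated barcodes are
  excluded: curvature estimates are unstable at the extremes.
* **Quantization floor.** Candidate points with totals below the 5% quantile
  of positive totals are excluded. At single-digit totals the log-log curve
  is dominated by integer steps (5 to 4 to 3) whose slopes are artifacts of
  quantization, not a cell/ambient boundary. A quantile scales with the
  totals, so calling is invariant under rescaling all counts.
* **Flatness tolerance.** An inflection requires either a smoothed log-log
  slope below -2 (clearly steeper than power-law decay, whose rounded curves
  show artifact slopes near -1.7) or an outright cliff — a more-than-threefold
  drop between consecutive distinct totals, which a long plateau would
  otherwise dilute in rank space. Curves with neither raise
  "no inflection found".
* **Calling convention.** Barcodes strictly above the threshold total are
  cells, so on a two-plateau curve exactly the upper plateau is called.

## Demultiplexing

`demultiplex()` implements the threshold rule on raw hashtag counts: a cell
is assigned to its top hashtag if that tag has at least `min_counts = 10`
counts and more than `ratio = 2` times the second tag ("at least" is `>=`,
"more than double" is strict `>`). Droplets containing two hashtags — both
top tags at or above `doublet_positive_threshold = 10` while the top is not
more than double the second — are `DOUBLET`; ties for the top tag at or above
the positivity threshold are doublets; everything else is `UNASSIGNED`. No
normalization (CLR or otherwise) precedes thresholding: the rule is stated on
counts. The doublet definition replaces clustering-based doublet detection
with a deterministic two-positive rule; whether the 10-count assignment floor
also serves as the doublet positivity threshold is a free choice, so the two
are separate parameters with equal defaults.

## Quality control

`filter_cells()` applies four conjunctive exclusion rules, each tallied
independently against the full input so per-filter attrition is comparable
(a cell failing two filters counts under both; the kept set is the
conjunction, not the complement of the sum):

| filter | rule | boundary |
|---|---|---|
| low RNA | total RNA counts < 500 | 499 removed, 500 kept |
| dying cell | mitochondrial fraction > 0.10 | exactly 0.10 kept |
| low antibody | total TotalSeq-C counts < 500 | 499 removed, 500 kept |
| non-specific binding | >= 2 isotype controls at/above 10 counts | one positive isotype kept |

Boundary conventions are the literal reading of "fewer than" and "over".
Mitochondrial genes default to the mouse `^mt-` prefix; an empty
mitochondrial or isotype set skips that filter with a warning and records the
skip. The isotype positivity threshold is not something the QC rules
quantify on their own, so it defaults to the demultiplexing positivity floor
(10 counts) for consistent count-scale semantics, and is configurable.

## The signature score

Expression is normalized per cell to 10,000 counts and log2(x+1)-transformed
(`normalize_and_log()`, mode `"cp10k"`; mode `"tpm"` computes
length-corrected transcripts per million for bulk tables with gene lengths —
TPM is undefined for UMI data without length correction, which is why cp10k
is the UMI default). Each gene is then centered across all cells
(`center_genes()`).

For a signature with up-genes U and down-genes D, the per-cell score is

    score(c) = mean_{g in U} x_gc - mean_{g in D} x_gc

on the centered matrix, and a group's raw score is the mean over its cells,
with a normal-approximation 95% confidence interval over those cells (a
bootstrap interval would be a drop-in alternative; the normal interval is
what the mean-and-CI presentation implies). Signature genes absent from the
matrix are dropped and counted in `n_up_used`/`n_down_used`; a signature with
no up-genes present is an error.

Centering is used as the "z-score" operation: the defining pipeline centers
each gene across cells and averages, without scaling to unit variance.
`trmsig` follows that literal pipeline. Scores are therefore invariant to
adding a constant to any gene and linear in the expression values, properties
the tests assert; per-gene variance scaling can be applied by the caller
before scoring if strict z-scores are wanted.

**Random-gene-set control.** `random_control()` rescores `n_iter = 1000`
uniformly drawn gene sets of the same sizes (without replacement within an
iteration) and returns the per-group mean and sd; the adjusted score is
`raw - control_mean` (`score_signature_adjusted()`). The control removes
size- and coverage-dependent bias. Two free choices, both documented rather
than silent: the true signature genes stay in the sampling pool (excluding
them changes the control by less than sampling error on exchangeable
fixtures, and keeping them avoids a data-dependent pool), and the iteration
count defaults to 1000 with a mandatory seed, so results are exactly
reproducible.

**Per-cluster versus pseudobulk.** Whether a group is scored by averaging
per-cell scores or by scoring a collapsed per-group mean profile is genuinely
ambiguous between a per-cluster view and a condition-level pseudobulk view,
so `pseudobulk_scores()` implements both and labels the mode in its output:
`"cell"` averages per-cell scores within each condition; `"pseudobulk"`
collapses cells to one mean centered profile per condition first. For
one-cell conditions the two coincide (asserted in tests).

**Deriving signatures.** `derive_signature()` ranks genes by a two-sided
rank-sum (Wilcoxon) test of group versus reference on log expression
(vectorized with tie correction and normal approximation; verified against
`stats::wilcox.test` in tests), excludes genes with absolute mean log
fold-change below `min_abs_lfc = 0.25`, and takes the `top_n = 100` most
significant genes per direction. With zero qualifying up-genes it errors (a
signature must have up-genes); with fewer than `top_n` it returns a shorter
signature carrying a `warning` attribute.

## Trajectory scoring

`build_timepoint_signatures()` derives one signature per reference stage
against the naive stage — the "top differentially expressed genes of each
timepoint versus naive" construction — preserving stage order.
`score_trajectory()` then computes the adjusted score and confidence interval
of each query group against every timepoint signature, with the per-timepoint
control mean reported as `random_baseline` (the gray-line counterpart).
Whether "top N differentially expressed genes" means an undirected set or a
split by direction is not fixed by the construction, so direction handling is
a flag (`"both"` by default when down-genes qualify, `"up"` for up-only
signatures). Because scores are computed on the gene-centered query matrix,
they are relative within the query population: a group can only score high
against a signature if it expresses those genes more than the other query
cells do, which is exactly the divergence the trajectory analysis reads out.

## Quantification statistics

* `cluster_frequencies()`: counts and within-condition fractions of cells per
  transcriptional cluster, explicit zeros for absent clusters; an optional
  chi-square on the counts is left to the caller — the pipeline reports
  fractions.
* `epidermal_density()`: mean cells per mm^2 over equal-area fields (three
  1-mm^2 images per epidermal sheet by protocol); unequal areas are rejected
  unless explicitly pooled.
* `paired_t()` / `unpaired_t()`: two-tailed Student's t tests (equal-variance
  pooling for the unpaired test). Zero-variance input with equal means
  returns statistic 0 and p = 1 by convention; a constant non-zero
  difference returns an infinite statistic and p = 0.
* `many_to_one()`: two-sided Dunnett many-to-one comparisons against a single
  control, via the single-step multivariate-t adjustment (`multcomp`); the
  multivariate-t probabilities are evaluated by randomized quasi-Monte-Carlo,
  so a seed argument makes adjusted p values reproducible to that tolerance.
  Two-sided is used throughout for consistency with the two-tailed t tests.
  With one treatment the procedure reduces exactly to the pooled two-sample
  Student's t decision; adjusted p values are never below unadjusted ones.

## The synthetic-data generator

`generate_droplet_experiment()` emulates the parts of a droplet experiment
the pipeline's decisions depend on:

* **Counts.** Negative-binomial draws around per-group gene means
  (`dispersion = 0.1`, variance mu + dispersion mu^2) — the standard UMI
  noise stand-in; the analysis defines no generative model of its own. Gene
  means follow a log-normal abundance profile; per-cell library sizes are
  log-normal (sd 0.35), per-droplet ambient sizes wider (sd 0.8).
* **Two regimes.** 500 real cells around 2,000 UMI and 5,000 empty droplets
  around 50 UMI by default, so the rank curve has the two plateaus that
  inflection calling needs (enforced by the config invariant
  `empty_mean_counts < cell_mean_counts`).
* **Groups.** Each of `n_groups` transcriptional groups carries an exclusive
  planted set of `genes_per_group = 50` up-genes shifted by
  `signature_effect = 2` log2 units. The last group leans toward the first
  half of the samples (`site_bias = 0.25`), emulating a cluster enriched at
  one treatment site.
* **Hashtags and antibodies.** A cell's own hashtag draws around
  `hashtag_signal = 200`, foreign hashtags around `hashtag_background = 5`
  (uniform ambient background — the simplest model under which the threshold
  rule is exercisable), with the config invariant
  `hashtag_signal > 2 x hashtag_background + 10` guaranteeing the rule is
  satisfiable by construction. Antibody counts use their own dispersion
  (0.02): capture of an abundant surface epitope is far less bursty than
  transcription. Antibody totals scale with the square root of the cell's
  RNA size factor — staining tracks cell size only weakly — which keeps the
  two cells of a doublet from differing so much in staining intensity that
  the two-positive rule misreads them. Isotype controls sit at background
  except in a small "sticky" subset (2%) positive on all of them; 16 generic
  antibody channels give realistic TotalSeq-C totals.
* **Doublets and dying cells.** Doublets (5%) are sums of two independently
  drawn cells from distinct samples — "droplets containing two hashtags" —
  and are recorded with both sample labels. A `mito_high_fraction` subset
  has its mitochondrial share inflated to 0.4 (versus 0.03 baseline) across
  13 `mt-`-prefixed genes, mirroring mouse annotation so default
  mitochondrial detection applies.
* **Determinism.** Everything is drawn under `config$seed`; identical
  configs give bit-identical matrices.

`generate_staged_reference()` emits a bulk-style staged table (naive plus
ordered timepoints, 20 samples per stage at depth 1e5) with
stage-exclusive planted programs by default (`cumulative = TRUE` keeps
earlier programs active in later stages); `simulate_stage_query()` draws
query cells expressing any chosen subset of those programs over the same
gene universe, giving "fully differentiated" versus "early-arrested" groups
with known truth. Ambient RNA composition in empty droplets is not pinned
down by any rule the pipeline implements, so it is the mean of the group
profiles by construction and scales freely via `empty_mean_counts`.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: batch effects across lanes, ambient-RNA
contamination *inside* real cells, correlated gene modules beyond the planted
programs, variable hashtag staining quality between samples, cell-type
mixtures beyond the planted groups, or TCR/protein panels beyond
hashtags and isotypes. Recovery rates on this generator are upper bounds for
data with those additional structures.

## Problem sizes and runtime of the checks

The verification suite uses deliberately modest sizes — chosen as the
smallest instances that still exercise every decision boundary: oracle
equivalence on 100 random matrices up to 10x10 against an element-wise
brute-force recomputation (agreement to 1e-10); null calibration of 200
random signatures (20 up, 20 down, 1000 control iterations) on a 500-gene x
200-cell exchangeable matrix; 100 planted-recovery replicates at effect 2
plus 50 replicates at each effect in {0, 0.5, 1, 2} for monotonicity; 100
trajectory replicates (600 genes, naive + 3 stages, 20 samples per stage, 40
query cells per group); the exhaustive 51x51 demultiplexing grid; the
default 5,500-droplet calling fixture; 10,000 null paired-t simulations.
`scripts/acceptance.R` recomputes all of these from scratch for any seed.

## Known limitations

* The inflection finder assumes a two-regime curve; barcode distributions
  with more than two plateaus (e.g. strong cell-size subpopulations) may
  yield a threshold at an interior boundary.
* The demultiplexing rule is deliberately clustering-free; it will not
  recover cells whose hashtag staining failed outright, and labels them
  `UNASSIGNED` rather than guessing.
* Signature scores are relative to the scored population (gene centering);
  scores from different populations are not directly comparable — compare
  groups within one centered matrix, as the pipeline does.
* The rank-sum test uses the normal approximation with tie correction;
  for fewer than ~8 samples per group exact p-values would differ.
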
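#' Configuration for the synthetic droplet experiment generator
#'
#' Collects every tunable of the simulators with defaults chosen to mimic a
#' hashtag-multiplexed 10x-style experiment on epidermal CD8+ T cells: a few
#' hundred real cells sequenced around 2,000 UMI, a large excess of ambient
#' (empty) droplets around 50 UMI, hashtag signal well above background, a
#' small doublet rate and a small dying (high-mitochondrial) subset.
#'
#' @param n_cells number of cell-containing droplets (doublets included).
#' @param n_empty_droplets number of empty (ambient-only) droplets.
#' @param n_genes number of genes in the RNA panel.
#' @param n_hashtags number of hashtag channels / pooled samples (>= 2).
#' @param doublet_fraction fraction of cell-containing droplets that hold two
#'   cells from distinct samples, in `[0, 1)`.
#' @param cell_mean_counts expected total UMI of a single real cell.
#' @param empty_mean_counts expected total UMI of an empty droplet; must be
#'   below `cell_mean_counts` so the rank curve has two regimes.
#' @param hashtag_signal expected counts of a cell's own hashtag.
#' @param hashtag_background expected counts of each foreign hashtag (ambient
#'   antibody). Must satisfy `hashtag_signal > 2 * hashtag_background + 10` so
#'   the demultiplexing rule is satisfiable by construction.
#' @param mito_gene_count number of mitochondrial genes (named with the mouse
#'   "mt-" prefix so default mitochondrial detection applies).
#' @param mito_high_fraction fraction of cells simulated as dying, with an
#'   inflated mitochondrial fraction (`mito_high_level`).
#' @param n_groups number of transcriptional groups (clusters); each group
#'   carries its own planted up-gene signature.
#' @param signature_effect log2 fold-change applied to a group's planted
#'   up-genes in that group's cells.
#' @param dispersion negative-binomial overdispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param seed integer seed; the generators are deterministic given it.
#' @param genes_per_group number of planted up-genes per group signature.
#' @param hashtag_dispersion overdispersion of antibody-tag counts. Antibody
#'   capture of an abundant epitope is less bursty than transcription, so the
#'   default is well below the RNA dispersion.
#' @param n_isotypes number of isotype-control antibody channels.
#' @param n_antibodies number of generic surface-protein antibody channels
#'   (gives real cells a realistic total antibody count).
#' @param adt_mean_counts expected total counts over the generic antibody
#'   channels for a real cell.
#' @param sticky_fraction fraction of cells with non-specific antibody binding
#'   (high counts on every isotype control).
#' @param mito_base_frac expected mitochondrial fraction of a healthy cell.
#' @param mito_high_level expected mitochondrial fraction of a dying cell.
#' @param site_bias association between the last group and the first half of
#'   the samples: a cell of the last group draws its sample from the first
#'   half with probability `0.5 + site_bias` (0 = no association). Emulates a
#'   transcriptional cluster enriched at one treatment site when the first
#'   half of the hashtag samples comes from that site.
#' @param cell_size_sd log-normal sd of per-cell library-size factors.
#' @param empty_size_sd log-normal sd of per-droplet ambient-size factors
#'   (wider than for cells: ambient totals span a broad range).
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 500L,
                       n_empty_droplets = 5000L,
                       n_genes = 2000L,
                       n_hashtags = 4L,
                       doublet_fraction = 0.05,
                       cell_mean_counts = 2000,
                       empty_mean_counts = 50,
                       hashtag_signal = 200,
                       hashtag_background = 5,
                       mito_gene_count = 13L,
                       mito_high_fraction = 0.05,
                       n_groups = 2L,
                       signature_effect = 2,
                       dispersion = 0.1,
                       seed = 1L,
                       genes_per_group = 50L,
                       hashtag_dispersion = 0.02,
                       n_isotypes = 2L,
                       n_antibodies = 16L,
                       adt_mean_counts = 2000,
                       sticky_fraction = 0.02,
                       site_bias = 0.25,
                       mito_base_frac = 0.03,
                       mito_high_level = 0.4,
                       cell_size_sd = 0.35,
                       empty_size_sd = 0.8) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_empty_droplets = as.integer(n_empty_droplets),
    n_genes = as.integer(n_genes), n_hashtags = as.integer(n_hashtags),
    doublet_fraction = doublet_fraction, cell_mean_counts = cell_mean_counts,
    empty_mean_counts = empty_mean_counts, hashtag_signal = hashtag_signal,
    hashtag_background = hashtag_background, mito_gene_count = as.integer(mito_gene_count),
    mito_high_fraction = mito_high_fraction, n_groups = as.integer(n_groups),
    signature_effect = signature_effect, dispersion = dispersion, seed = as.integer(seed),
    genes_per_group = as.integer(genes_per_group), hashtag_dispersion = hashtag_dispersion,
    n_isotypes = as.integer(n_isotypes), n_antibodies = as.integer(n_antibodies),
    adt_mean_counts = adt_mean_counts, sticky_fraction = sticky_fraction,
    site_bias = site_bias,
    mito_base_frac = mito_base_frac, mito_high_level = mito_high_level,
    cell_size_sd = cell_size_sd, empty_size_sd = empty_size_sd)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  if (config$n_cells < 1L)
    stop("n_cells must be a positive integer (no cells to simulate)")
  if (config$n_empty_droplets < 1L)
    stop("n_empty_droplets must be a positive integer")
  if (config$n_genes < 1L) stop("n_genes must be a positive integer")
  if (config$n_hashtags < 2L) stop("n_hashtags must be >= 2")
  if (config$doublet_fraction < 0 || config$doublet_fraction >= 1)
    stop("doublet_fraction must lie in [0, 1)")
  if (config$empty_mean_counts >= config$cell_mean_counts)
    stop("violated bound: empty_mean_counts < cell_mean_counts ",
         "(the rank curve needs two regimes)")
  if (config$hashtag_signal <= 2 * config$hashtag_background + 10)
    stop("violated bound: hashtag_signal > 2 * hashtag_background + 10 ",
         "(the demultiplexing rule must be satisfiable)")
  if (config$dispersion <= 0) stop("dispersion must be positive")
  if (config$mito_high_fraction < 0 || config$mito_high_fraction > 1)
    stop("mito_high_fraction must lie in [0, 1]")
  if (config$n_groups < 1L) stop("n_groups must be a positive integer")
  if (!is.null(config$site_bias) &&
      (config$site_bias < 0 || config$site_bias > 0.5))
    stop("site_bias must lie in [0, 0.5]")
  if (config$n_groups * config$genes_per_group >
      config$n_genes - config$mito_gene_count)
    stop("not enough non-mitochondrial genes to plant ", config$n_groups,
         " group signatures of ", config$genes_per_group, " genes")
  invisible(config)
}

# one NB expression draw for a cell of the given group profile
.draw_cell <- function(profile, mean_counts, size_factor, dispersion) {
  stats::rnbinom(length(profile), mu = profile * mean_counts * size_factor,
                 size = 1 / dispersion)
}

# rescale the mitochondrial block of a relative profile to a target share
.set_mito_share <- function(profile, mito, share) {
  if (!any(mito) || share <= 0) return(profile / sum(profile))
  p <- profile
  p[mito] <- p[mito] / sum(p[mito]) * sum(p[!mito]) * share / (1 - share)
  p / sum(p)
}

#' Simulate a hashtag-multiplexed droplet experiment with known ground truth
#'
#' Real cells draw RNA counts from a negative-binomial model around
#' group-specific gene means (each group's planted up-genes shifted by
#' `signature_effect` log2 units); empty droplets draw from a scaled ambient
#' profile; doublets are sums of two independently sampled cells from distinct
#' samples. Each cell's own hashtag is drawn around `hashtag_signal` and every
#' foreign hashtag around `hashtag_background`; isotype-control and generic
#' antibody channels complete the antibody (ADT) matrix. A `mito_high_fraction`
#' subset of cells is simulated as dying with an inflated mitochondrial
#' fraction. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{rna}{sparse genes x barcodes UMI count matrix (`dgCMatrix`).}
#'     \item{adt}{sparse antibody-tag x barcodes count matrix (hashtags,
#'       isotype controls, generic antibodies).}
#'     \item{truth}{a list: `barcodes`, a data.frame with one row per emitted
#'       barcode (`barcode`, `is_cell`, `sample_of_origin` — a sample label or
#'       `"DOUBLET"`, `sample_a`/`sample_b` for doublets, `group`,
#'       `is_high_mito`, `is_sticky`); `signatures`, one [gene_signature()] of
#'       planted up-genes per group; `samples`, the sample labels; `config`.}
#'   }
#' @export
generate_droplet_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  n_mito <- min(config$mito_gene_count, ng)
  genes <- c(if (n_mito > 0) sprintf("mt-g%02d", seq_len(n_mito)),
             sprintf("gene%05d", seq_len(ng - n_mito)))
  mito <- grepl("^mt-", genes)

  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.5)
  base <- .set_mito_share(base, mito, config$mito_base_frac)

  # plant one exclusive up-gene set per group
  pool <- sample(which(!mito))
  k <- config$genes_per_group
  planted <- lapply(seq_len(config$n_groups), function(g)
    sort(genes[pool[((g - 1L) * k + 1L):(g * k)]]))
  names(planted) <- paste0("group", seq_len(config$n_groups))
  profiles <- vapply(seq_len(config$n_groups), function(g) {
    p <- base
    idx <- match(planted[[g]], genes)
    p[idx] <- p[idx] * 2^config$signature_effect
    p / sum(p)
  }, numeric(ng))

  samples <- paste0("sample", seq_len(config$n_hashtags))
  n_doublets <- as.integer(round(config$doublet_fraction * config$n_cells))
  n_singlets <- config$n_cells - n_doublets
  if (n_singlets < 1L) stop("doublet_fraction leaves no singlets")

  draw_one <- function() {
    g <- sample.int(config$n_groups, 1L)
    high <- stats::runif(1) < config$mito_high_fraction
    prof <- if (high) .set_mito_share(profiles[, g], mito, config$mito_high_level)
            else profiles[, g]
    sf <- stats::rlnorm(1, -config$cell_size_sd^2 / 2, config$cell_size_sd)
    list(counts = .draw_cell(prof, config$cell_mean_counts, sf, config$dispersion),
         group = g, high = high, sf = sf)
  }

  # antibody panel layout
  tags <- paste0("Hashtag", seq_len(config$n_hashtags))
  isos <- if (config$n_isotypes > 0) paste0("Isotype", seq_len(config$n_isotypes))
  adts <- if (config$n_antibodies > 0) paste0("ADT", seq_len(config$n_antibodies))
  channels <- c(tags, isos, adts)
  adt_channel_mu <- if (config$n_antibodies > 0)
    config$adt_mean_counts / config$n_antibodies else numeric(0)

  # antibody staining tracks cell size only weakly: counts scale with the
  # square root of the cell's RNA size factor
  draw_adt <- function(sample_idx, sticky, sf) {
    mu <- c(ifelse(seq_len(config$n_hashtags) == sample_idx,
                   config$hashtag_signal, config$hashtag_background),
            rep(if (sticky) config$hashtag_signal else config$hashtag_background,
                config$n_isotypes),
            rep(adt_channel_mu, config$n_antibodies))
    stats::rnbinom(length(mu), mu = mu * sqrt(sf),
                   size = 1 / config$hashtag_dispersion)
  }

  n_total <- config$n_cells + config$n_empty_droplets
  rna <- matrix(0, nrow = ng, ncol = n_total)
  adt <- matrix(0, nrow = length(channels), ncol = n_total)
  truth <- data.frame(
    barcode = sprintf("BC%06d", seq_len(n_total)),
    is_cell = rep(c(TRUE, FALSE), c(config$n_cells, config$n_empty_droplets)),
    sample_of_origin = NA_character_, sample_a = NA_character_,
    sample_b = NA_character_, group = NA_character_,
    is_high_mito = FALSE, is_sticky = FALSE, stringsAsFactors = FALSE)

  first_half <- seq_len(max(1L, config$n_hashtags %/% 2L))
  draw_sample <- function(group) {
    # the last group leans toward the first half of the samples (site_bias)
    if (group == config$n_groups && config$site_bias > 0) {
      half <- if (stats::runif(1) < 0.5 + config$site_bias) first_half
              else setdiff(seq_len(config$n_hashtags), first_half)
      return(half[sample.int(length(half), 1L)])
    }
    sample.int(config$n_hashtags, 1L)
  }
  for (i in seq_len(n_singlets)) {
    cell <- draw_one()
    s <- draw_sample(cell$group)
    sticky <- stats::runif(1) < config$sticky_fraction
    rna[, i] <- cell$counts
    adt[, i] <- draw_adt(s, sticky, cell$sf)
    truth$sample_of_origin[i] <- samples[s]
    truth$sample_a[i] <- samples[s]
    truth$group[i] <- paste0("group", cell$group)
    truth$is_high_mito[i] <- cell$high
    truth$is_sticky[i] <- sticky
  }
  for (i in seq_len(n_doublets)) {
    j <- n_singlets + i
    ss <- sample.int(config$n_hashtags, 2L)        # distinct samples
    a <- draw_one(); b <- draw_one()
    rna[, j] <- a$counts + b$counts
    adt[, j] <- draw_adt(ss[1], FALSE, a$sf) + draw_adt(ss[2], FALSE, b$sf)
    truth$sample_of_origin[j] <- "DOUBLET"
    truth$sample_a[j] <- samples[ss[1]]
    truth$sample_b[j] <- samples[ss[2]]
  }

  # ambient profiles: mean over group profiles (RNA) and over expected cell
  # channel means (ADT), scaled to the empty-droplet depth
  ambient_rna <- rowMeans(profiles)
  cell_channel_mu <- c(rep((config$hashtag_signal +
                            (config$n_hashtags - 1) * config$hashtag_background) /
                           config$n_hashtags, config$n_hashtags),
                       rep(config$hashtag_background, config$n_isotypes),
                       rep(adt_channel_mu, config$n_antibodies))
  ambient_scale <- config$empty_mean_counts / config$cell_mean_counts
  for (i in seq_len(config$n_empty_droplets)) {
    j <- config$n_cells + i
    sf <- stats::rlnorm(1, -config$empty_size_sd^2 / 2, config$empty_size_sd)
    rna[, j] <- .draw_cell(ambient_rna, config$empty_mean_counts, sf,
                           config$dispersion)
    adt[, j] <- stats::rnbinom(length(channels),
                               mu = cell_channel_mu * ambient_scale * sf,
                               size = 1 / config$hashtag_dispersion)
  }

  # shuffle droplet order so position carries no information
  ord <- sample.int(n_total)
  rna <- rna[, ord, drop = FALSE]
  adt <- adt[, ord, drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  truth$barcode <- sprintf("BC%06d", seq_len(n_total))  # relabel in new order
  rownames(truth) <- NULL
  dimnames(rna) <- list(genes, truth$barcode)
  dimnames(adt) <- list(channels, truth$barcode)

  signatures <- lapply(names(planted), function(nm)
    gene_signature(nm, up_genes = planted[[nm]]))
  names(signatures) <- names(planted)

  list(rna = methods::as(Matrix::Matrix(rna, sparse = TRUE), "CsparseMatrix"),
       adt = methods::as(Matrix::Matrix(adt, sparse = TRUE), "CsparseMatrix"),
       truth = list(barcodes = truth, signatures = signatures,
                    samples = samples, config = config))
}

#' Simulate a staged bulk reference of T cell differentiation
#'
#' Emits an expression (count) table over a naive stage plus `n_timepoints`
#' ordered timepoints, each timepoint carrying `genes_per_stage` planted
#' up-regulated genes shifted by `config$signature_effect` log2 units. Planted
#' sets are stage-exclusive by default; with `cumulative = TRUE` a timepoint's
#' samples also up-regulate every earlier timepoint's planted genes (its own
#' planted set is still only its exclusive block). Stands in for a staged
#' tissue-resident-memory differentiation time course profiled in bulk.
#'
#' @param n_timepoints number of post-naive stages (>= 2... at least 1; the
#'   reference as a whole needs naive plus one stage, >= 2 stages total).
#' @param genes_per_stage planted up-genes per timepoint.
#' @param config a [sim_config()]; `n_genes`, `signature_effect`, `dispersion`
#'   and `seed` are used.
#' @param samples_per_stage bulk samples per stage.
#' @param depth expected total counts per bulk sample.
#' @param cumulative keep earlier stages' programs active in later stages.
#' @return list with `counts` (genes x samples integer matrix), `stages`
#'   (factor, ordered naive first), and `truth` (`planted`: stage -> gene set;
#'   `gene_means`: baseline relative profile; `effect`).
#' @export
generate_staged_reference <- function(n_timepoints, genes_per_stage, config,
                                      samples_per_stage = 20L, depth = 1e5,
                                      cumulative = FALSE) {
  if (n_timepoints < 1L) stop("n_timepoints must be >= 1 (plus the naive stage)")
  if (samples_per_stage < 2L) stop("samples_per_stage must be >= 2")
  ng <- config$n_genes
  if (n_timepoints * genes_per_stage > ng)
    stop("not enough genes for ", n_timepoints, " stages of ", genes_per_stage)
  set.seed(config$seed)
  genes <- sprintf("gene%05d", seq_len(ng))
  base <- stats::rlnorm(ng, 0, 1.5)
  base <- base / sum(base)
  pool <- sample.int(ng)
  stage_names <- sprintf("d%02d", 5L * seq_len(n_timepoints))
  planted <- lapply(seq_len(n_timepoints), function(s)
    sort(genes[pool[((s - 1L) * genes_per_stage + 1L):(s * genes_per_stage)]]))
  names(planted) <- stage_names

  stages <- factor(rep(c("naive", stage_names), each = samples_per_stage),
                   levels = c("naive", stage_names))
  profile_for <- function(stage) {
    p <- base
    if (stage > 0) {
      active <- if (cumulative) seq_len(stage) else stage
      idx <- match(unlist(planted[active]), genes)
      p[idx] <- p[idx] * 2^config$signature_effect
    }
    p / sum(p)
  }
  counts <- vapply(seq_along(stages), function(i) {
    stage <- match(as.character(stages[i]), stage_names, nomatch = 0L)
    sf <- stats::rlnorm(1, -0.02, 0.2)
    .draw_cell(profile_for(stage), depth, sf, config$dispersion)
  }, numeric(ng))
  dimnames(counts) <- list(genes,
                           paste0(as.character(stages), "_s",
                                  stats::ave(seq_along(stages),
                                             stages, FUN = seq_along)))
  list(counts = counts, stages = stages,
       truth = list(planted = planted, gene_means = stats::setNames(base, genes),
                    effect = config$signature_effect, cumulative = cumulative))
}

#' Simulate query cells expressing a chosen subset of staged programs
#'
#' Generates single cells over the same gene universe as a staged reference
#' from [generate_staged_reference()], up-regulating the planted genes of the
#' given stages. Used to build "fully differentiated" (all stages) versus
#' "early-arrested" (first stages only) query groups with known truth.
#'
#' @param reference the list returned by [generate_staged_reference()].
#' @param stages_expressed character vector of stage names whose planted
#'   programs the cells express (may be empty: a null group).
#' @param n_cells number of cells.
#' @param config a [sim_config()] (`signature_effect`, `dispersion`,
#'   `cell_size_sd` are used).
#' @param depth expected total UMI per cell.
#' @param seed seed for this draw (the reference keeps its own).
#' @return genes x cells integer count matrix.
#' @export
simulate_stage_query <- function(reference, stages_expressed, n_cells = 50L,
                                 config = sim_config(), depth = 5000, seed = 1L) {
  planted <- reference$truth$planted
  bad <- setdiff(stages_expressed, names(planted))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  set.seed(seed)
  base <- reference$truth$gene_means
  genes <- names(base)
  p <- base
  if (length(stages_expressed)) {
    idx <- match(unlist(planted[stages_expressed]), genes)
    p[idx] <- p[idx] * 2^config$signature_effect
  }
  p <- p / sum(p)
  counts <- vapply(seq_len(n_cells), function(i) {
    sf <- stats::rlnorm(1, -config$cell_size_sd^2 / 2, config$cell_size_sd)
    .draw_cell(p, depth, sf, config$dispersion)
  }, numeric(length(genes)))
  dimnames(counts) <- list(genes, sprintf("q%04d", seq_len(n_cells)))
  counts
}
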
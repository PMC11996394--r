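# shared fixtures and independent oracles, built in code

# small dense count matrix with identifiers
toy_counts <- function(values, genes = NULL, barcodes = NULL) {
  m <- as.matrix(values)
  if (is.null(genes))
    genes <- if (!is.null(rownames(m))) rownames(m)
             else paste0("g", seq_len(nrow(m)))
  if (is.null(barcodes))
    barcodes <- if (!is.null(colnames(m))) colnames(m)
                else paste0("bc", seq_len(ncol(m)))
  dimnames(m) <- list(genes, barcodes)
  m
}

# mark a matrix as centered without going through center_genes()
as_centered <- function(m) {
  attr(m, "centered") <- TRUE
  m
}

# independent brute-force oracle for the signature score: explicit
# element-by-element loops, no vectorization, no shared code with the package
brute_force_score <- function(expr, up, down, groups) {
  scores <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    up_sum <- 0; up_n <- 0
    for (g in up) if (g %in% rownames(expr)) {
      up_sum <- up_sum + expr[g, j]; up_n <- up_n + 1
    }
    down_sum <- 0; down_n <- 0
    for (g in down) if (g %in% rownames(expr)) {
      down_sum <- down_sum + expr[g, j]; down_n <- down_n + 1
    }
    scores[j] <- up_sum / up_n - (if (down_n > 0) down_sum / down_n else 0)
  }
  out <- list()
  for (lab in unique(groups)) {
    acc <- 0; n <- 0
    for (j in seq_len(ncol(expr))) if (groups[j] == lab) {
      acc <- acc + scores[j]; n <- n + 1
    }
    out[[lab]] <- acc / n
  }
  out
}

# exchangeable-gene null matrix: i.i.d. normal entries, centered
null_centered_matrix <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  center_genes(m)
}

# small droplet experiment restricted to true cells, with centered
# expression and truth group labels — the planted-signature fixture
planted_fixture <- function(seed, n_cells = 100, n_genes = 300,
                            genes_per_group = 20, signature_effect = 2,
                            n_iter = 200) {
  cfg <- sim_config(seed = seed, n_cells = n_cells, n_empty_droplets = 50,
                    n_genes = n_genes, genes_per_group = genes_per_group,
                    signature_effect = signature_effect,
                    doublet_fraction = 0, mito_high_fraction = 0,
                    sticky_fraction = 0)
  sim <- generate_droplet_experiment(cfg)
  tr <- sim$truth$barcodes
  cells <- tr$barcode[tr$is_cell]
  expr <- center_genes(normalize_and_log(sim$rna[, cells, drop = FALSE]))
  groups <- stats::setNames(tr$group[match(cells, tr$barcode)], cells)
  list(sim = sim, expr = expr, groups = groups, n_iter = n_iter)
}
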
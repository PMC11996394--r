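#' Read a MatrixMarket count matrix with barcode and feature companions
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (optionally
#' `.gz`-compressed) in `dir`, the on-disk layout of droplet pipelines.
#' Features and barcodes become row and column names; MatrixMarket's 1-based
#' indices are handled by the reader, so all downstream access is by
#' identifier, never position.
#'
#' @param dir directory holding the three files.
#' @return sparse features x barcodes `dgCMatrix`.
#' @export
read_counts_mtx <- function(dir) {
  locate <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing ", base, "[.gz] in ", dir)
  }
  mtx <- locate("matrix.mtx")
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file ", mtx,
                                         ": ", conditionMessage(e)))
  barcodes <- readLines(locate("barcodes.tsv"))
  feats <- utils::read.delim(locate("features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feats))
    stop("features.tsv length (", length(feats),
         ") does not match matrix rows (", nrow(m), ")")
  if (ncol(m) != length(barcodes))
    stop("barcodes.tsv length (", length(barcodes),
         ") does not match matrix columns (", ncol(m), ")")
  dimnames(m) <- list(feats, barcodes)
  methods::as(m, "CsparseMatrix")
}

#' Write a count matrix as MatrixMarket with companions
#'
#' @param mat features x barcodes matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param gzip compress the three files.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(mat, dir, gzip = FALSE) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must carry feature and barcode names")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(sp, mtx)
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  if (gzip) {
    for (f in file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))) {
      con <- gzfile(paste0(f, ".gz"), "wb")
      writeBin(readBin(f, "raw", file.size(f)), con)
      close(con)
      unlink(f)
    }
  }
  invisible(dir)
}

#' Read gene signatures from a GMT file
#'
#' One tab-separated line per set: name, description, then genes. GMT carries
#' no direction, so every gene is an up-gene. Duplicate genes within a set
#' are removed with a warning.
#'
#' @param path GMT file.
#' @return named list of [gene_signature()] objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 40))
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes))
      warning("duplicate genes in set '", parts[1], "' deduplicated")
    gene_signature(parts[1], up_genes = genes)
  })
  stats::setNames(sigs, vapply(sigs, function(s) s$name, character(1)))
}

#' Write gene signatures as GMT
#'
#' A signature without down-genes is written as a single set under its own
#' name (so up-only signatures round-trip losslessly); one with down-genes is
#' split into `<name>_up` and `<name>_down`, since GMT has no direction field.
#'
#' @param signatures list of [gene_signature()] (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(s) {
    if (!length(s$down_genes))
      return(paste(c(s$name, "up genes", s$up_genes), collapse = "\t"))
    c(paste(c(paste0(s$name, "_up"), "up genes", s$up_genes), collapse = "\t"),
      paste(c(paste0(s$name, "_down"), "down genes", s$down_genes),
            collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed signature from a two-column CSV
#'
#' Columns `gene` and `direction` (`up`/`down`).
#'
#' @param path CSV file.
#' @param name signature name (default: file name without extension).
#' @return a [gene_signature()].
#' @export
read_signature_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(df)))
    stop("signature CSV needs columns 'gene' and 'direction'")
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad)) stop("unknown direction(s): ", paste(bad, collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_signature(name, up_genes = df$gene[df$direction == "up"],
                 down_genes = df$gene[df$direction == "down"])
}

# short content hash of an R object (used to stamp outputs with the
# parameter set that produced them)
.param_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(substr(tools::md5sum(f), 1, 12))
}

#' Write a result table as CSV stamped with seed and parameter hash
#'
#' Prepends a comment line `# seed=<seed> params=<hash>` so every numeric
#' output records the run that produced it; read back with
#' [read_result_csv()].
#'
#' @param df data.frame to write.
#' @param path output CSV.
#' @param seed the run seed.
#' @param params the parameter object hashed into the stamp.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, seed, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s params=%s", seed, .param_hash(params)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_result_csv()]
#' @param path CSV file.
#' @return the data.frame, with attributes `seed` and `params_hash`.
#' @export
read_result_csv <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (grepl("^# seed=", first)) {
    attr(df, "seed") <- sub("^# seed=(\\S+).*", "\\1", first)
    attr(df, "params_hash") <- sub(".*params=(\\S+).*", "\\1", first)
  }
  df
}
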
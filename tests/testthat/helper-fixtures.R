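# Small in-code fixtures shared across test files.

# write a minimal MTX triplet (features x cells on disk, 10x convention)
write_mtx_fixture <- function(dir, n_cells, n_genes, entries,
                              barcodes = sprintf("BC%03d-1", seq_len(n_cells)),
                              genes = sprintf("G%03d", seq_len(n_genes))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    paste(n_genes, n_cells, nrow(entries)),
    if (nrow(entries)) {
      # entries given as (cell, gene, value); stored gene-major like 10x
      apply(entries, 1, function(e) paste(e[2], e[1], e[3]))
    }
  )
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(paste(paste0("ENSG", seq_along(genes)), genes, sep = "\t"),
             file.path(dir, "features.tsv"))
  dir
}

# dense count matrix -> the sparse cell x gene form the package uses
sparse_counts <- function(m, barcodes = NULL, genes = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d-1", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(ncol(m)))
  out <- Matrix::Matrix(m, sparse = TRUE)
  dimnames(out) <- list(barcodes, genes)
  out
}

# independent brute-force two-sided binomial p (minimum-likelihood rule)
oracle_binom_p <- function(x, n, p0) {
  pmf <- exp(lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log1p(-p0))
  if (p0 == 0) pmf <- as.numeric(0:n == 0)
  if (p0 == 1) pmf <- as.numeric(0:n == n)
  min(1, sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)]))
}

# independent brute-force two-sided Fisher p via choose() enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  lo <- max(0, k - n2); hi <- min(k, m)
  supp <- lo:hi
  logp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(m + n2, k)
  pmf <- exp(logp - max(logp))
  pmf <- pmf / sum(pmf)
  min(1, sum(pmf[pmf <= pmf[match(a, supp)] * (1 + 1e-7)]))
}

# tiny cell table for QC tests
qc_cell_row <- function(n_genes = 1000, n_umi = 3000, pct_mito = 5,
                        pct_ribo = 10, pct_top100 = 50, ...) {
  tibble::tibble(barcode = "BC001-1", sample = "s", n_genes = n_genes,
                 n_umi = n_umi, pct_mito = pct_mito, pct_ribo = pct_ribo,
                 pct_top100 = pct_top100, ...)
}

random_key_set <- function(n, seed) {
  set.seed(seed)
  paste0(
    "CASS",
    replicate(n, paste(sample(LETTERS[1:20], 6, TRUE), collapse = "")),
    "F|TRBV", sample(1:30, n, TRUE), "|TRBJ", sample(1:2, n, TRUE), "-",
    sample(1:7, n, TRUE)
  )
}
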
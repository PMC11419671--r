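#' Read a 10x-style Matrix Market count triplet
#'
#' Reads a sparse cell-by-gene count matrix from the standard 10x triplet
#' layout: a Matrix Market `.mtx` file plus a barcode list and a feature
#' list. On disk the MTX entries are 1-based and features are rows; in
#' memory the matrix is returned with cells as rows and genes as columns,
#' oriented by comparing the declared MTX dimensions against the two lists.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param barcodes_path Path to a one-column (or first-column) text file of
#'   cell barcodes, one per row. The 10x `-1` suffix is preserved verbatim:
#'   barcodes are opaque strings so that matching stays exact and
#'   reversible.
#' @param features_path Path to a feature table with one or two tab-separated
#'   columns (gene id, gene symbol). With a single column the id doubles as
#'   the symbol.
#'
#' @return A [Matrix::sparseMatrix()] (`dgCMatrix`) with `rownames` set to
#'   the barcodes and `colnames` to the gene symbols. The feature table is
#'   attached as a tibble in `attr(, "features")` (columns `id`, `symbol`).
#'   Duplicate symbols are allowed; marker lookups resolve a symbol to the
#'   union of matching columns.
#' @export
read_counts_mtx <- function(matrix_path, barcodes_path, features_path) {
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- tryCatch(
    Matrix::readMM(matrix_path),
    error = function(e) stop("malformed MTX file: ", conditionMessage(e), call. = FALSE)
  )
  vals <- m@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    stop("MTX entries must be nonnegative integers", call. = FALSE)
  }
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)[[1]]
  feat_raw <- readr::read_tsv(features_path, col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  features <- tibble::tibble(
    id = feat_raw[[1]],
    symbol = if (ncol(feat_raw) >= 2) feat_raw[[2]] else feat_raw[[1]]
  )

  if (nrow(m) == length(barcodes) && ncol(m) == nrow(features)) {
    # already cells x genes
  } else if (nrow(m) == nrow(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)  # 10x convention: features are rows on disk
  } else {
    stop(sprintf(
      "MTX dimensions (%d x %d) do not match barcode (%d) / feature (%d) lists",
      nrow(m), ncol(m), length(barcodes), nrow(features)), call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("barcodes must be unique within a sample", call. = FALSE)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(barcodes, features$symbol)
  attr(m, "features") <- features
  m
}

#' Write a count matrix as a 10x-style Matrix Market triplet
#'
#' Inverse of [read_counts_mtx()]: writes `matrix.mtx` (features as rows,
#' 1-based, per the on-disk convention), `barcodes.tsv` and `features.tsv`
#' into `dir`.
#'
#' @param counts Cell-by-gene sparse matrix as returned by [read_counts_mtx()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths of the three files written.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(methods::as(Matrix::t(counts), "CsparseMatrix"), paths[1])
  writeLines(rownames(counts), paths[2])
  features <- attr(counts, "features")
  if (is.null(features)) {
    features <- tibble::tibble(id = colnames(counts), symbol = colnames(counts))
  }
  readr::write_tsv(features, paths[3], col_names = FALSE, progress = FALSE)
  invisible(paths)
}

#' Read V(D)J contig annotations into chain records
#'
#' Parses single-cell TCR contig tables in either the 10x
#' `filtered_contig_annotations.csv` dialect or the AIRR rearrangement TSV
#' dialect into one tidy chain record per productive contig. Non-productive
#' rows are dropped (their count is reported with a message), matching the
#' upstream assemblers' default of carrying productive chains forward.
#'
#' @param path Path to the contig table.
#' @param dialect `"tenx_csv"` (columns `barcode`, `chain`, `v_gene`,
#'   `j_gene`, `cdr3`, `umis`, `productive`) or `"airr_tsv"` (columns
#'   `cell_id`, `locus`, `junction_aa`, `v_call`, `j_call`; `productive`
#'   and `duplicate_count`/`umi_count` are honored when present, otherwise
#'   rows are assumed productive with one supporting UMI).
#' @param sample Sample label attached to every record.
#'
#' @return A tibble with columns `barcode`, `sample`, `locus`, `cdr3_aa`,
#'   `v_gene`, `j_gene`, `umis`, `productive` (all retained rows are
#'   productive). V/J calls keep any allele suffix here; stripping happens
#'   when clonotype keys are built, so bulk and single-cell gene calls
#'   remain comparable.
#' @export
read_vdj_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv"),
                             sample = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tenx_csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "umis", "productive")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing mandatory 10x column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    out <- tibble::tibble(
      barcode = df$barcode,
      sample = sample,
      locus = df$chain,
      cdr3_aa = df$cdr3,
      v_gene = df$v_gene,
      j_gene = df$j_gene,
      umis = as.integer(df$umis),
      productive = tolower(df$productive) %in% c("true", "t", "1")
    )
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    required <- c("cell_id", "locus", "junction_aa", "v_call", "j_call")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing mandatory AIRR column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    umis <- if ("duplicate_count" %in% names(df)) {
      as.integer(df$duplicate_count)
    } else if ("umi_count" %in% names(df)) {
      as.integer(df$umi_count)
    } else rep(1L, nrow(df))
    productive <- if ("productive" %in% names(df)) {
      tolower(df$productive) %in% c("true", "t", "1")
    } else rep(TRUE, nrow(df))
    out <- tibble::tibble(
      barcode = df$cell_id,
      sample = sample,
      locus = df$locus,
      cdr3_aa = df$junction_aa,
      v_gene = df$v_call,
      j_gene = df$j_call,
      umis = umis,
      productive = productive
    )
  }
  n_drop <- sum(!out$productive)
  if (n_drop > 0) message("read_vdj_contigs: dropped ", n_drop, " non-productive contig(s)")
  dplyr::filter(out, .data$productive)
}

#' Read a bulk TCR-seq clonotype table
#'
#' Reads the flat clonotype table produced by bulk TCR profilers for
#' reactivity-sorted T cells: one row per beta-chain clonotype with its
#' CDR3 amino-acid sequence, V and J gene calls, and supporting read count.
#'
#' @param path TSV with columns `cdr3b_aa`, `v_gene`, `j_gene`, `read_count`.
#' @return Tibble with those columns plus `key`, the clonotype key built by
#'   [clonotype_key()] (allele suffixes stripped).
#' @export
read_bulk_clonotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("cdr3b_aa", "v_gene", "j_gene", "read_count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing bulk clonotype column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df |>
    dplyr::mutate(
      read_count = as.integer(.data$read_count),
      key = clonotype_key(.data$cdr3b_aa, .data$v_gene, .data$j_gene)
    )
}

#' Write a result table as TSV
#'
#' All tabular pipeline outputs are written as UTF-8 tab-separated files
#' with a header so they round-trip losslessly through [read_table_tsv()].
#'
#' @param records A data frame.
#' @param path Output path.
#' @return Invisibly, `records`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(records)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to the TSV.
#' @param col_types Optional readr column specification; by default column
#'   types are guessed from the full file.
#' @return A tibble.
#' @export
read_table_tsv <- function(path, col_types = NULL) {
  if (is.null(col_types)) {
    readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                    guess_max = Inf)
  } else {
    readr::read_tsv(path, col_types = col_types, progress = FALSE)
  }
}

#' Per-cell QC metrics from a count matrix
#'
#' Computes the per-cell quantities the QC filters operate on: UMI total,
#' detected genes, and the percentage of counts in mitochondrial genes,
#' ribosomal protein genes, and the cell's 100 most expressed genes.
#'
#' @param counts Cell-by-gene sparse matrix (see [read_counts_mtx()]).
#' @param sample Sample label.
#' @param mito_pattern,ribo_pattern Regular expressions on gene symbols for
#'   the mitochondrial and ribosomal gene sets (human defaults).
#' @return A tibble with columns `barcode`, `sample`, `n_umi`, `n_genes`,
#'   `pct_mito`, `pct_ribo`, `pct_top100` (percentages on the 0-100 scale;
#'   zero-count cells get 0 for all percentages).
#' @export
cell_qc_metrics <- function(counts, sample = NA_character_,
                            mito_pattern = "^MT-", ribo_pattern = "^RP[SL]") {
  n_umi <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito <- grepl(mito_pattern, colnames(counts))
  ribo <- grepl(ribo_pattern, colnames(counts))
  pct_of <- function(sel) {
    s <- if (any(sel)) Matrix::rowSums(counts[, sel, drop = FALSE]) else 0
    ifelse(n_umi > 0, 100 * s / n_umi, 0)
  }
  top100 <- apply(counts, 1L, function(v) {
    tot <- sum(v)
    if (tot == 0) return(0)
    100 * sum(utils::head(sort(v, decreasing = TRUE), 100L)) / tot
  })
  tibble::tibble(
    barcode = rownames(counts),
    sample = sample,
    n_umi = as.numeric(n_umi),
    n_genes = as.integer(n_genes),
    pct_mito = as.numeric(pct_of(mito)),
    pct_ribo = as.numeric(pct_of(ribo)),
    pct_top100 = as.numeric(top100)
  )
}

# Columns of a marker symbol in a count matrix; duplicates resolve to the
# union of matching columns, missing symbols to integer(0).
match_symbol_cols <- function(counts, symbols) {
  which(colnames(counts) %in% symbols)
}
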
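#' Build clonotype keys
#'
#' A clonotype is identified by the triple (CDR3beta amino-acid sequence,
#' Vbeta gene, Jbeta gene) - the minimal combination available consistently
#' across bulk TCR-seq (which does not pair alpha and beta chains) and
#' single-cell V(D)J data. Allele suffixes (`*01` etc.) are stripped from
#' the gene calls before the key is formed because bulk and single-cell
#' pipelines report different allele resolution; matching is at gene level.
#'
#' @param cdr3b_aa CDR3beta amino-acid sequence(s).
#' @param vb,jb Vbeta / Jbeta gene call(s), with or without allele suffix.
#' @return Character vector of keys, `"CDR3|V|J"`. Equality of keys is
#'   exact string equality of the triple.
#' @examples
#' clonotype_key("CASSLGQAYEQYF", "TRBV7-9*01", "TRBJ2-7")
#' @export
clonotype_key <- function(cdr3b_aa, vb, jb) {
  bad <- !nzchar(cdr3b_aa) | !nzchar(vb) | !nzchar(jb) |
    is.na(cdr3b_aa) | is.na(vb) | is.na(jb)
  if (any(bad)) stop("clonotype_key: all three fields must be non-empty", call. = FALSE)
  paste(cdr3b_aa, strip_allele(vb), strip_allele(jb), sep = "|")
}

#' Strip the allele suffix from a V/J gene call
#'
#' @param gene Gene call(s), e.g. `"TRBV7-9*01"`.
#' @return Gene-level call(s), e.g. `"TRBV7-9"`.
#' @export
strip_allele <- function(gene) {
  sub("\\*.*$", "", gene)
}

#' Collapse chain records to one clonotype per cell
#'
#' Reduces productive chain records to one row per (barcode, sample): the
#' beta-chain clonotype key plus alpha/beta chain counts. Cells with
#' several productive TRB chains take their key from the TRB with the
#' highest UMI support (ties broken by lexicographically smallest CDR3,
#' then V, then J, so the choice is deterministic). Cells with no
#' productive TRB get `key = NA`. `multi_alpha` marks cells with more than
#' one productive TRA chain; such cells are excluded from specificity-group
#' preparation (see [filter_specificity_clusters()]) but not from matching.
#'
#' @param chains Chain-record tibble as returned by [read_vdj_contigs()].
#' @return Tibble with columns `barcode`, `sample`, `key`, `cdr3b_aa`,
#'   `vb`, `jb`, `n_tra`, `n_trb`, `multi_alpha`.
#' @export
build_cell_clonotypes <- function(chains) {
  chains <- dplyr::filter(chains, .data$productive)
  per_cell <- chains |>
    dplyr::group_by(.data$barcode, .data$sample) |>
    dplyr::summarise(
      n_tra = sum(.data$locus == "TRA"),
      n_trb = sum(.data$locus == "TRB"),
      .groups = "drop"
    )
  trb <- chains |>
    dplyr::filter(.data$locus == "TRB") |>
    dplyr::mutate(vb = strip_allele(.data$v_gene), jb = strip_allele(.data$j_gene)) |>
    dplyr::arrange(.data$barcode, .data$sample, dplyr::desc(.data$umis),
                   .data$cdr3_aa, .data$vb, .data$jb) |>
    dplyr::distinct(.data$barcode, .data$sample, .keep_all = TRUE) |>
    dplyr::transmute(
      .data$barcode, .data$sample,
      cdr3b_aa = .data$cdr3_aa, .data$vb, .data$jb,
      key = clonotype_key(.data$cdr3_aa, .data$vb, .data$jb)
    )
  per_cell |>
    dplyr::left_join(trb, by = c("barcode", "sample")) |>
    dplyr::mutate(multi_alpha = .data$n_tra > 1L) |>
    dplyr::select("barcode", "sample", "key", "cdr3b_aa", "vb", "jb",
                  "n_tra", "n_trb", "multi_alpha")
}

#' Match clonotypes between two repertoires
#'
#' Exact set intersection of clonotype keys: a clonotype is shared when its
#' (CDR3beta, Vbeta, Jbeta) triple is identical in both repertoires. A
#' clonotype present in both counts once regardless of how many cells or
#' reads carry it.
#'
#' @param set_a,set_b Character vectors of clonotype keys (duplicates allowed).
#' @return Sorted character vector of shared unique keys.
#' @export
match_clonotypes <- function(set_a, set_b) {
  sort(intersect(unique(set_a), unique(set_b)))
}

#' Pairwise clonotype-sharing matrix
#'
#' Counts the unique clonotype keys shared by every pair of samples; the
#' diagonal holds each sample's unique-key count.
#'
#' @param samples Named list mapping sample name to a character vector of
#'   clonotype keys (duplicates allowed), or a tibble with columns `sample`
#'   and `key`.
#' @return Symmetric integer matrix with sample names as dimnames.
#' @export
sharing_matrix <- function(samples) {
  if (is.data.frame(samples)) {
    samples <- split(samples$key, samples$sample)
  }
  if (!length(samples)) stop("sharing_matrix: need at least one sample", call. = FALSE)
  sets <- lapply(samples, function(k) unique(k[!is.na(k)]))
  n <- length(sets)
  out <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[i, j] <- out[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  out
}

#' Most abundant clonotypes
#'
#' Ranks clonotypes by the number of cells carrying them, keeping the top
#' `n`. Ties are broken lexicographically on the key so the ranking is
#' deterministic. Frequencies are relative to cells that carry any key.
#'
#' @param cells Cell-clonotype tibble (see [build_cell_clonotypes()]);
#'   rows with `key = NA` are ignored.
#' @param n Number of clonotypes to keep (default 10, the usual abundance
#'   plot depth).
#' @return Tibble `key`, `n_cells`, `frequency`, `rank`, at most `n` rows.
#' @export
top_clonotypes <- function(cells, n = 10) {
  stopifnot(n >= 1)
  counts <- cells |>
    dplyr::filter(!is.na(.data$key)) |>
    dplyr::count(.data$key, name = "n_cells")
  total <- sum(counts$n_cells)
  counts |>
    dplyr::arrange(dplyr::desc(.data$n_cells), .data$key) |>
    utils::head(n) |>
    dplyr::mutate(frequency = .data$n_cells / total,
                  rank = dplyr::row_number())
}

#' Filter specificity clusters to the high-confidence subset
#'
#' Post-filters the cluster table emitted by an external TCR
#' specificity-grouping tool, keeping clusters with a V-gene bias score
#' below `max_bias`, at least `min_tcrs` unique TCRs and at least
#' `min_individuals` contributing individuals.
#'
#' @param rows Tibble with columns `cluster_id`, `n_unique_tcrs`,
#'   `n_individuals`, `vgene_bias_score`.
#' @param max_bias,min_tcrs,min_individuals Filter thresholds.
#' @return The qualifying subset of `rows`.
#' @export
filter_specificity_clusters <- function(rows, max_bias = 0.05, min_tcrs = 3,
                                        min_individuals = 3) {
  required <- c("cluster_id", "n_unique_tcrs", "n_individuals", "vgene_bias_score")
  missing <- setdiff(required, names(rows))
  if (length(missing)) {
    stop("missing specificity-cluster column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dplyr::filter(rows,
                .data$vgene_bias_score < max_bias,
                .data$n_unique_tcrs >= min_tcrs,
                .data$n_individuals >= min_individuals)
}
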
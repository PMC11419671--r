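#' Per-category cluster frequencies
#'
#' For every cell category (e.g. "TIL", "reactive_41BB"), computes the
#' fraction of that category's cells falling in each cluster: the number
#' of cells from the category in the cluster divided by the category's
#' total cell count. Clusters absent from a category appear with frequency
#' zero, so each category's frequencies sum to one. Categories with zero
#' cells are skipped with a warning.
#'
#' @param cells Tibble with columns `cluster` and `category`.
#' @return Tibble `category`, `cluster`, `n_cells`, `total_cells`,
#'   `frequency`.
#' @export
category_frequencies <- function(cells) {
  stopifnot(all(c("cluster", "category") %in% names(cells)))
  cats <- unique(cells$category)
  empty <- cats[is.na(cats)]
  if (any(is.na(cells$category))) {
    warning("cells with missing category skipped")
    cells <- cells[!is.na(cells$category), ]
  }
  clusters <- sort(unique(as.character(cells$cluster)))
  out <- cells |>
    dplyr::mutate(cluster = as.character(.data$cluster)) |>
    dplyr::count(.data$category, .data$cluster, name = "n_cells") |>
    tidyr::complete(category = unique(cells$category), cluster = clusters,
                    fill = list(n_cells = 0L)) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(total_cells = sum(.data$n_cells),
                  frequency = .data$n_cells / .data$total_cells) |>
    dplyr::ungroup()
  out
}

#' Attribute reactive clonotypes to clusters and test enrichment
#'
#' The central statistic of the pipeline. Cells carrying a clonotype key in
#' `reactive_keys` (from a reactivity sort, e.g. 4-1BB+ after tumor
#' co-culture or antigen-dextramer selection) form the "reactive" category;
#' cells carrying a key in `til_keys` (from cultured TIL sequencing) form
#' the background. For each cluster, the reactive-cell count `x` out of `n`
#' total reactive cells is compared with the background frequency `p0` (the
#' fraction of TIL-matching cells in that cluster) by a two-sided exact
#' binomial test ([exact_binomial_test()]); p-values are Bonferroni
#' adjusted over the number of clusters tested. `delta` is the difference
#' between the cluster frequency among reactive-matching cells and among
#' non-matching cells (cells whose key is not reactive), the quantity shown
#' in matching-vs-non-matching cluster plots; deltas sum to zero across
#' clusters.
#'
#' Only cells with an assembled beta-chain key (`key` not `NA`) enter
#' numerators and denominators: the frequencies are defined on
#' clonotype-matched cells. Clusters with `p0 = 0` but reactive cells
#' present are still tested (the null is a point mass, so the p-value
#' collapses toward 0) and flagged `degenerate_background`.
#'
#' @param cells Tibble with columns `barcode`, `cluster`, `key`.
#' @param reactive_keys Character vector of reactive clonotype keys.
#' @param til_keys Character vector of TIL-culture clonotype keys.
#' @return Tibble of class `trl_enrichment` with columns `cluster`, `x`,
#'   `n`, `p0`, `p_two_sided`, `p_bonf`, `direction`
#'   (`"over"`/`"under"`/`"none"`), `delta`, `degenerate_background`.
#' @export
reactive_cluster_enrichment <- function(cells, reactive_keys, til_keys) {
  stopifnot(all(c("cluster", "key") %in% names(cells)))
  keyed <- cells |>
    dplyr::filter(!is.na(.data$key)) |>
    dplyr::mutate(cluster = as.character(.data$cluster))
  reactive <- dplyr::filter(keyed, .data$key %in% reactive_keys)
  til <- dplyr::filter(keyed, .data$key %in% til_keys)
  nonmatching <- dplyr::filter(keyed, !.data$key %in% reactive_keys)
  if (!nrow(reactive)) stop("no cells match the reactive key set", call. = FALSE)
  if (!nrow(til)) stop("no cells match the TIL key set", call. = FALSE)

  clusters <- sort(unique(keyed$cluster))
  count_by <- function(df) {
    v <- table(factor(df$cluster, levels = clusters))
    as.integer(v)
  }
  x <- count_by(reactive)
  n <- nrow(reactive)
  til_n <- count_by(til)
  p0 <- til_n / nrow(til)
  nm_n <- count_by(nonmatching)
  freq_match <- x / n
  freq_nonmatch <- if (nrow(nonmatching)) nm_n / nrow(nonmatching) else rep(0, length(clusters))

  p <- purrr::map2_dbl(x, p0, ~ exact_binomial_test(.x, n, .y))
  out <- tibble::tibble(
    cluster = clusters,
    x = x, n = n, p0 = p0,
    p_two_sided = p,
    p_bonf = bonferroni(p),
    direction = dplyr::case_when(
      x / n > p0 ~ "over",
      x / n < p0 ~ "under",
      TRUE ~ "none"
    ),
    delta = freq_match - freq_nonmatch,
    degenerate_background = p0 == 0 & x > 0
  )
  structure(out, class = c("trl_enrichment", class(out)),
            n_reactive = n, n_til = nrow(til))
}

#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw counts across all cells of each group (typically a biological
#' replicate, or a sample-condition pair), imitating a bulk RNA-seq
#' experiment. The result is a dense gene-by-group integer matrix plus a
#' design table, ready for count-based differential-expression tools; the
#' grand total of counts is conserved.
#'
#' @param counts Cell-by-gene sparse matrix.
#' @param cells Tibble with a `barcode` column covering every row of
#'   `counts`, plus the grouping columns.
#' @param group_by Character vector of `cells` columns defining the groups.
#' @return List with `matrix` (genes x groups) and `design` (tibble of the
#'   grouping columns, one row per group, in column order of `matrix`).
#' @export
pseudobulk_aggregate <- function(counts, cells, group_by = "sample") {
  missing_cols <- setdiff(c("barcode", group_by), names(cells))
  if (length(missing_cols)) {
    stop("cells table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(rownames(counts), cells$barcode)
  if (anyNA(idx)) stop("every cell in the matrix needs a row in `cells`", call. = FALSE)
  meta <- cells[idx, group_by, drop = FALSE]
  if (any(!stats::complete.cases(meta))) {
    stop("every cell must be assigned to exactly one group (no NA)", call. = FALSE)
  }
  grp <- interaction(meta, drop = TRUE, sep = ":", lex.order = TRUE)
  indic <- Matrix::sparse.model.matrix(~ 0 + grp)
  colnames(indic) <- levels(grp)
  agg <- Matrix::t(counts) %*% indic      # genes x groups
  design <- dplyr::distinct(dplyr::mutate(meta, .group = as.character(grp)))
  design <- design[match(levels(grp), design$.group), , drop = FALSE]
  design <- tibble::as_tibble(design[, c(".group", group_by)])
  names(design)[1] <- "group"
  list(matrix = as.matrix(agg), design = design)
}
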
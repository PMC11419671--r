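#' QC threshold profiles
#'
#' A QC profile is a small rule table: one row per retained-cell criterion,
#' giving the metric, the comparison operator and the threshold. A cell is
#' retained iff it satisfies every rule. Two presets are shipped:
#'
#' * `"biopsy"` - the tumor-biopsy profile: detected genes > 200,
#'   UMI counts > 500, ribosomal read percentage < 40, and percentage of
#'   counts in the top 100 expressed genes < 80.
#' * `"um1"` - the stricter PDX-model profile: detected genes between 400
#'   and 6500 (inclusive; cells outside are removed), UMI counts between
#'   500 and 25000, mitochondrial percentage at most 20 and ribosomal
#'   percentage at most 15.
#'
#' Comparison strictness follows the stated removal rules exactly, which is
#' why the two presets differ in whether the bound itself survives.
#'
#' @param name `"biopsy"`, `"um1"`, or `"custom"` (with `rules` supplied).
#' @param rules For `"custom"`: a data frame with columns `metric`
#'   (a column of the cell table), `op` (one of `">"`, `">="`, `"<"`,
#'   `"<="`), and `value`.
#' @return A tibble of rules with class `trl_qc_profile`.
#' @export
qc_profile <- function(name = c("biopsy", "um1", "custom"), rules = NULL) {
  name <- match.arg(name)
  tab <- switch(name,
    biopsy = tibble::tribble(
      ~metric,      ~op,  ~value,
      "n_genes",    ">",  200,
      "n_umi",      ">",  500,
      "pct_ribo",   "<",  40,
      "pct_top100", "<",  80
    ),
    um1 = tibble::tribble(
      ~metric,    ~op,   ~value,
      "n_genes",  ">=",  400,
      "n_genes",  "<=",  6500,
      "n_umi",    ">=",  500,
      "n_umi",    "<=",  25000,
      "pct_mito", "<=",  20,
      "pct_ribo", "<=",  15
    ),
    custom = {
      if (is.null(rules)) stop("custom profile needs a `rules` data frame", call. = FALSE)
      tibble::as_tibble(rules)
    }
  )
  if (!all(tab$op %in% c(">", ">=", "<", "<="))) {
    stop("profile operators must be one of >, >=, <, <=", call. = FALSE)
  }
  structure(tab, class = c("trl_qc_profile", class(tab)), profile_name = name)
}

#' Apply global QC thresholds to a cell table
#'
#' Retains exactly the cells satisfying every rule of the profile, and
#' reports how many cells each rule removed (a cell failing several rules
#' counts toward each). Filtering is idempotent: applying the same profile
#' to an already-filtered table removes nothing.
#'
#' @param cells Cell metadata tibble with the metric columns the profile
#'   references (see [cell_qc_metrics()]).
#' @param profile A [qc_profile()].
#' @return A list with elements `cells` (the retained tibble) and `report`
#'   (tibble `metric`, `op`, `value`, `n_removed`, plus attributes-free
#'   totals in rows `n_in`/`n_out` accessible via `attr(report, "n_in")`
#'   and `attr(report, "n_out")`).
#' @export
apply_global_filters <- function(cells, profile) {
  stopifnot(inherits(profile, "trl_qc_profile"))
  missing <- setdiff(unique(profile$metric), names(cells))
  if (length(missing)) {
    stop("profile references missing metric(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(cells))
  n_removed <- integer(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    v <- cells[[profile$metric[i]]]
    ok <- switch(profile$op[i],
      ">"  = v >  profile$value[i],
      ">=" = v >= profile$value[i],
      "<"  = v <  profile$value[i],
      "<=" = v <= profile$value[i]
    )
    ok[is.na(ok)] <- FALSE
    n_removed[i] <- sum(!ok)
    keep <- keep & ok
  }
  report <- tibble::tibble(
    metric = profile$metric, op = profile$op, value = profile$value,
    n_removed = n_removed
  )
  attr(report, "n_in") <- nrow(cells)
  attr(report, "n_out") <- sum(keep)
  list(cells = cells[keep, , drop = FALSE], report = report)
}

#' Default lineage-conflict rule set
#'
#' Marker combinations that should not co-occur in a single cell; a cell
#' expressing any gene of a rule's set A together with any gene of its set
#' B is marked as a doublet. The token `"TCR_ASSEMBLED"` in set A means
#' "has at least one productive TCR chain". The default rules pair T-cell
#' identity (CD3D/CD4/CD8A/CD8B or an assembled TCR) against melanocytic
#' and erythroid markers, an assembled TCR against myeloid/B/plasma
#' markers, and melanocytic markers against myeloid/B/plasma/NK markers.
#'
#' @return A list of rules, each `list(a = <symbols>, b = <symbols>)`.
#' @export
default_lineage_rules <- function() {
  list(
    list(a = c("CD3D", "CD4", "CD8A", "CD8B", "TCR_ASSEMBLED"),
         b = c("MLANA", "PMEL", "TYR", "HBA1", "HBA2", "HBB")),
    list(a = "TCR_ASSEMBLED",
         b = c("CD14", "CD19", "MS4A1", "JCHAIN")),
    list(a = c("MLANA", "PMEL", "TYR"),
         b = c("CD14", "CD19", "MS4A1", "JCHAIN", "NCR1"))
  )
}

#' Flag cells with conflicting lineage markers
#'
#' Evaluates a lineage rule set on raw counts: "expressed" means count > 0
#' (no higher cutoff is imposed), and `TCR_ASSEMBLED` means the barcode has
#' at least one productive chain in `chains`. Rule symbols missing from the
#' matrix are reported with a message and the rule is evaluated on the
#' remaining symbols; flagging is monotone in expression (adding expressed
#' genes can only switch flags on).
#'
#' @param counts Cell-by-gene sparse matrix.
#' @param chains Chain-record tibble (productive rows; see
#'   [read_vdj_contigs()]), or `NULL` when no V(D)J data exist.
#' @param rules Rule set as produced by [default_lineage_rules()].
#' @return Tibble `barcode`, `lineage_doublet` (logical), one row per cell
#'   of `counts`.
#' @export
flag_lineage_conflicts <- function(counts, chains = NULL,
                                   rules = default_lineage_rules()) {
  barcodes <- rownames(counts)
  has_tcr <- if (is.null(chains)) {
    rep(FALSE, length(barcodes))
  } else {
    barcodes %in% unique(chains$barcode[chains$productive])
  }
  side_expressed <- function(symbols) {
    toks <- setdiff(symbols, "TCR_ASSEMBLED")
    cols <- match_symbol_cols(counts, toks)
    absent <- setdiff(toks, colnames(counts))
    if (length(absent)) {
      message("flag_lineage_conflicts: symbol(s) not in matrix: ",
              paste(absent, collapse = ", "))
    }
    expr <- if (length(cols)) {
      Matrix::rowSums(counts[, cols, drop = FALSE] > 0) > 0
    } else rep(FALSE, length(barcodes))
    if ("TCR_ASSEMBLED" %in% symbols) expr | has_tcr else expr
  }
  flag <- rep(FALSE, length(barcodes))
  for (rule in rules) {
    flag <- flag | (side_expressed(rule$a) & side_expressed(rule$b))
  }
  tibble::tibble(barcode = barcodes, lineage_doublet = unname(flag))
}

#' Per-cluster doublet association statistics
#'
#' For each cluster, tests whether doublet-flagged cells are
#' over-represented with a two-sided Fisher's exact test on the 2x2 table
#' with rows (doublet, singlet) and columns (in-cluster, out-of-cluster),
#' so an odds ratio above 1 means doublets are over-represented in that
#' cluster. p-values are Benjamini-Hochberg adjusted across clusters.
#' Clusters with zero cells (empty factor levels) are excluded with a
#' warning.
#'
#' @param cells Cell table with columns `cluster`, `doublet_flag`, `n_umi`.
#' @return Tibble of class `trl_doublet_stats` with columns `cluster`,
#'   `n_cells`, `n_doublets`, `pct_doublets`, `median_umi`, `odds_ratio`,
#'   `p`, `q`.
#' @export
cluster_doublet_stats <- function(cells) {
  stopifnot(all(c("cluster", "doublet_flag", "n_umi") %in% names(cells)))
  if (any(is.na(cells$cluster)) || any(is.na(cells$doublet_flag))) {
    stop("every cell needs a cluster label and a doublet flag", call. = FALSE)
  }
  if (is.factor(cells$cluster)) {
    empty <- setdiff(levels(cells$cluster), unique(as.character(cells$cluster)))
    if (length(empty)) {
      warning("excluding empty cluster(s): ", paste(empty, collapse = ", "))
    }
  }
  total_doublets <- sum(cells$doublet_flag)
  total_cells <- nrow(cells)
  stats <- cells |>
    dplyr::mutate(cluster = as.character(.data$cluster)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_doublets = sum(.data$doublet_flag),
      median_umi = stats::median(.data$n_umi),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_doublets = 100 * .data$n_doublets / .data$n_cells)
  tests <- purrr::pmap(
    list(stats$n_cells, stats$n_doublets),
    function(nc, nd) {
      tab <- rbind(
        c(nd, total_doublets - nd),
        c(nc - nd, (total_cells - total_doublets) - (nc - nd))
      )
      fisher_exact_2x2(tab)
    }
  )
  stats$odds_ratio <- purrr::map_dbl(tests, "odds_ratio")
  stats$p <- purrr::map_dbl(tests, "p")
  stats$q <- stats::p.adjust(stats$p, method = "BH")
  out <- stats[, c("cluster", "n_cells", "n_doublets", "pct_doublets",
                   "median_umi", "odds_ratio", "p", "q")]
  structure(out, class = c("trl_doublet_stats", class(out)))
}

#' Nominate doublet clusters for removal
#'
#' A cluster is nominated when it meets any of three criteria: (i) the
#' Fisher test shows significant doublet over-representation (`q < q_max`
#' with odds ratio above 1 in the default orientation - see Details),
#' (ii) its doublet percentage is at or above the `pct_percentile`-th
#' percentile of cluster doublet percentages, or (iii) its median UMI count
#' is strictly above the `umi_percentile`-th percentile of cluster median
#' UMIs. Percentiles use linear interpolation (R quantile type 7).
#'
#' @details The literal published removal rule is "odds ratio < 1 and
#' q < 0.05", which with the natural table orientation denotes doublet
#' *depletion*; since the surrounding procedure removes clusters
#' *associated with* doublets, the default criterion here is OR > 1 with
#' q < `q_max` under the (doublet, singlet) x (in, out) orientation of
#' [cluster_doublet_stats()]. Set `fisher_or_direction = "literal"` to
#' restore the printed reading (OR < 1).
#'
#' @param stats Output of [cluster_doublet_stats()].
#' @param q_max BH-adjusted significance threshold for the Fisher criterion.
#' @param pct_percentile,umi_percentile Percentiles (0-100) for criteria
#'   (ii) and (iii).
#' @param fisher_or_direction `"over"` (default) or `"literal"`.
#' @return Tibble `cluster`, logical columns `fisher`, `doublet_pct`,
#'   `umi_pct`, and `reasons` (comma-joined), one row per nominated cluster.
#' @export
nominate_doublet_clusters <- function(stats, q_max = 0.05, pct_percentile = 95,
                                      umi_percentile = 95,
                                      fisher_or_direction = c("over", "literal")) {
  fisher_or_direction <- match.arg(fisher_or_direction)
  if (!nrow(stats)) stop("nominate_doublet_clusters: empty stats", call. = FALSE)
  if (fisher_or_direction == "literal") {
    warning("using the literal published criterion (odds ratio < 1), ",
            "which selects doublet-depleted clusters under this table orientation")
  }
  fisher <- if (fisher_or_direction == "over") {
    stats$odds_ratio > 1 & stats$q < q_max
  } else {
    stats$odds_ratio < 1 & stats$q < q_max
  }
  pct_cut <- stats::quantile(stats$pct_doublets, pct_percentile / 100,
                             type = 7, names = FALSE)
  umi_cut <- stats::quantile(stats$median_umi, umi_percentile / 100,
                             type = 7, names = FALSE)
  doublet_pct <- stats$pct_doublets >= pct_cut
  umi_pct <- stats$median_umi > umi_cut
  out <- tibble::tibble(
    cluster = stats$cluster,
    fisher = fisher, doublet_pct = doublet_pct, umi_pct = umi_pct
  ) |>
    dplyr::filter(.data$fisher | .data$doublet_pct | .data$umi_pct) |>
    dplyr::mutate(reasons = purrr::pmap_chr(
      list(.data$fisher, .data$doublet_pct, .data$umi_pct),
      function(f, d, u) paste(c("fisher", "doublet_pct", "umi_pct")[c(f, d, u)],
                              collapse = ",")
    ))
  out
}

#' Default low-RNA cell-type rescue specification
#'
#' Erythrocytes (hemoglobin genes positive) and plasma cells (JCHAIN
#' positive with IL3RA and LILRA4 required to be zero) have genuinely low
#' RNA content and would be wiped out by the global thresholds; they get
#' their own, lower thresholds via [rescue_low_rna_celltypes()].
#'
#' @return Named list of `list(markers_pos, markers_zero)` per cell type.
#' @export
default_rescue_spec <- function() {
  list(
    erythrocyte = list(markers_pos = c("HBA1", "HBA2", "HBB"),
                       markers_zero = character(0)),
    plasma_cell = list(markers_pos = "JCHAIN",
                       markers_zero = c("IL3RA", "LILRA4"))
  )
}

#' Rescue low-RNA cell types with type-specific thresholds
#'
#' For each configured cell type: (1) candidate cells are selected by the
#' marker criteria (every positive marker set hit with count > 0, every
#' zero-required marker at 0); (2) candidate-candidate Spearman correlation
#' is computed on expression; (3) candidates are hierarchically clustered
#' (distance 1 - rho, complete linkage) and the tree cut into `k` groups;
#' (4) groups with significant doublet over-representation (same Fisher
#' criterion as [cluster_doublet_stats()], BH across groups) or with median
#' UMI above the 95th percentile of group medians are discarded; (5) the
#' first quartile (linear interpolation) of UMI counts and detected genes
#' is computed over cells in the retained groups; (6) the rescued barcodes
#' are the candidates in retained groups with `n_umi` and `n_genes`
#' strictly above their respective quartiles. Cell types with fewer than 4
#' candidates are skipped with a warning (a quartile over fewer cells is
#' not robust).
#'
#' @param counts Cell-by-gene sparse matrix.
#' @param cells Cell table with `barcode`, `n_umi`, `n_genes`,
#'   `doublet_flag`.
#' @param celltype_spec See [default_rescue_spec()].
#' @param k Number of groups to cut the candidate tree into (default 2).
#' @param q_max Fisher BH threshold for discarding doublet-heavy groups.
#' @return List with `thresholds` (tibble `celltype`, `n_candidates`,
#'   `q1_umi`, `q1_genes`, `skipped`) and `barcodes` (character vector of
#'   rescued barcodes across cell types).
#' @export
rescue_low_rna_celltypes <- function(counts, cells,
                                     celltype_spec = default_rescue_spec(),
                                     k = 2, q_max = 0.05) {
  stopifnot(all(c("barcode", "n_umi", "n_genes", "doublet_flag") %in% names(cells)))
  thresholds <- list()
  rescued <- character(0)
  for (ct in names(celltype_spec)) {
    spec <- celltype_spec[[ct]]
    pos_cols <- match_symbol_cols(counts, spec$markers_pos)
    zero_cols <- match_symbol_cols(counts, spec$markers_zero)
    if (!length(pos_cols)) {
      warning("rescue: no positive marker of '", ct, "' found in matrix; skipped")
      thresholds[[ct]] <- tibble::tibble(celltype = ct, n_candidates = 0L,
                                         q1_umi = NA_real_, q1_genes = NA_real_,
                                         skipped = TRUE)
      next
    }
    is_pos <- Matrix::rowSums(counts[, pos_cols, drop = FALSE] > 0) > 0
    is_zero_ok <- if (length(zero_cols)) {
      Matrix::rowSums(counts[, zero_cols, drop = FALSE]) == 0
    } else rep(TRUE, nrow(counts))
    cand <- rownames(counts)[is_pos & is_zero_ok]
    cand <- intersect(cand, cells$barcode)
    if (length(cand) < 4) {
      warning("rescue: fewer than 4 '", ct, "' candidates; rescue skipped")
      thresholds[[ct]] <- tibble::tibble(celltype = ct,
                                         n_candidates = length(cand),
                                         q1_umi = NA_real_, q1_genes = NA_real_,
                                         skipped = TRUE)
      next
    }
    expr <- as.matrix(counts[cand, , drop = FALSE])
    rho <- suppressWarnings(stats::cor(t(expr), method = "spearman"))
    rho[is.na(rho)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "complete")
    grp <- stats::cutree(hc, k = min(k, length(cand)))
    cand_cells <- cells[match(cand, cells$barcode), ]
    cand_cells$group <- grp

    gstats <- cand_cells |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = dplyr::n(), n_dbl = sum(.data$doublet_flag),
                       med_umi = stats::median(.data$n_umi), .groups = "drop")
    tot_dbl <- sum(gstats$n_dbl); tot_n <- sum(gstats$n)
    ft <- purrr::pmap(list(gstats$n, gstats$n_dbl), function(nn, nd) {
      fisher_exact_2x2(rbind(c(nd, tot_dbl - nd),
                             c(nn - nd, (tot_n - tot_dbl) - (nn - nd))))
    })
    gstats$or <- purrr::map_dbl(ft, "odds_ratio")
    gstats$q <- stats::p.adjust(purrr::map_dbl(ft, "p"), method = "BH")
    umi_cut <- stats::quantile(gstats$med_umi, 0.95, type = 7, names = FALSE)
    gstats$discard <- (gstats$or > 1 & gstats$q < q_max) | gstats$med_umi > umi_cut
    # a lone group cannot exceed its own 95th percentile; > keeps it
    keep_groups <- gstats$group[!gstats$discard]
    kept <- cand_cells[cand_cells$group %in% keep_groups, ]
    if (!nrow(kept)) {
      warning("rescue: all '", ct, "' candidate groups discarded")
      thresholds[[ct]] <- tibble::tibble(celltype = ct,
                                         n_candidates = length(cand),
                                         q1_umi = NA_real_, q1_genes = NA_real_,
                                         skipped = TRUE)
      next
    }
    q1_umi <- stats::quantile(kept$n_umi, 0.25, type = 7, names = FALSE)
    q1_genes <- stats::quantile(kept$n_genes, 0.25, type = 7, names = FALSE)
    rescued <- union(rescued,
                     kept$barcode[kept$n_umi > q1_umi & kept$n_genes > q1_genes])
    thresholds[[ct]] <- tibble::tibble(celltype = ct, n_candidates = length(cand),
                                       q1_umi = q1_umi, q1_genes = q1_genes,
                                       skipped = FALSE)
  }
  list(thresholds = dplyr::bind_rows(thresholds), barcodes = rescued)
}
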
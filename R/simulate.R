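#' Configuration for the synthetic single-cell atlas
#'
#' Bundles and validates every knob of [simulate_atlas()]. The generator
#' emulates the statistical structure the pipeline assumes: clustered cell
#' populations with boosted marker genes (negative-binomial counts),
#' clonally expanded TCR repertoires with power-law clone sizes, planted
#' doublets built as barcode collisions (sums of two parent cells, which
#' is how conflicting-lineage expression arises), optional low-RNA cell
#' types, and a planted set of reactive clonotypes whose cells concentrate
#' in configurable clusters.
#'
#' @param n_clusters Number of phenotype clusters.
#' @param cells_per_cluster Singlet cells per cluster.
#' @param n_genes Background genes (lineage and low-RNA marker genes are
#'   appended to these).
#' @param base_expression_rate Mean count per background gene before
#'   library-size scaling.
#' @param marker_boost Multiplier on the mean for a cluster's marker genes.
#' @param markers_per_cluster Cluster-specific marker genes per cluster.
#' @param nb_dispersion Negative-binomial `size` parameter (smaller =
#'   noisier).
#' @param marker_leak_rate Mean count of a marker gene outside its home
#'   cluster or lineage - the residual ambient level. Kept very low so
#'   that genuine singlets rarely trip the lineage-conflict rules.
#' @param library_scale_sd SD of the per-cell log-normal library-size
#'   factor.
#' @param cluster_lineages Character vector (length `n_clusters`) of
#'   lineages drawn from `"T"`, `"melanocytic"`, `"erythroid"`, `"bcell"`,
#'   `"myeloid"`, `"nk"`; lineage marker genes (CD3D, MLANA, HBB, ...) are
#'   expressed in clusters of the matching lineage. Default: all `"T"`
#'   except the last cluster, which is melanocytic so that cross-lineage
#'   doublets carry conflicting markers.
#' @param doublet_rate Baseline fraction of doublets per cluster.
#' @param doublet_cluster_ids Cluster labels with an elevated doublet
#'   fraction (the planted "doublet clusters").
#' @param doublet_cluster_rate Doublet fraction inside those clusters.
#' @param lowrna List of low-RNA cell-type configs, each
#'   `list(markers, depth_scale, n_cells)` (named by cell type); `NULL`
#'   for none.
#' @param n_clonotypes Background (TIL) clonotypes.
#' @param clone_size_alpha Power-law exponent of clone sizes (larger =
#'   less expansion).
#' @param n_reactive_keys Planted reactive clonotypes.
#' @param n_reactive_cells Cells carrying a reactive clonotype; defaults to
#'   a fifth of the T cells.
#' @param reactive_cluster_weights,background_cluster_weights Per-cluster
#'   placement weights (length `n_clusters`, normalized internally).
#'   Defaults put weight 0.5 on the first cluster for reactive cells
#'   against a uniform background.
#' @param multi_alpha_rate Fraction of cells receiving a second productive
#'   TRA chain (exercises the multi-alpha exclusion rule).
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the config.
#' @return A validated config list of class `trl_atlas_config`.
#' @export
atlas_config <- function(n_clusters = 10,
                         cells_per_cluster = 100,
                         n_genes = 300,
                         base_expression_rate = 3,
                         marker_boost = 8,
                         markers_per_cluster = 3,
                         nb_dispersion = 2,
                         marker_leak_rate = 0.001,
                         library_scale_sd = 0.3,
                         cluster_lineages = NULL,
                         doublet_rate = 0.05,
                         doublet_cluster_ids = character(0),
                         doublet_cluster_rate = 0.5,
                         lowrna = NULL,
                         n_clonotypes = 500,
                         clone_size_alpha = 1.5,
                         n_reactive_keys = 20,
                         n_reactive_cells = NULL,
                         reactive_cluster_weights = NULL,
                         background_cluster_weights = NULL,
                         multi_alpha_rate = 0.05,
                         seed = 1L) {
  clusters <- paste0("C", seq_len(n_clusters))
  if (is.null(cluster_lineages)) {
    cluster_lineages <- c(rep("T", max(0, n_clusters - 1)),
                          if (n_clusters > 1) "melanocytic" else "T")
  }
  stopifnot(length(cluster_lineages) == n_clusters)
  is_t <- cluster_lineages == "T"
  if (!any(is_t)) stop("at least one cluster must have lineage 'T'", call. = FALSE)
  # clonotypes live on T cells only, so placement weights are over T clusters
  norm_w <- function(w, what) {
    if (is.null(w)) w <- as.numeric(is_t)
    if (!is.null(names(w))) {
      unknown <- setdiff(names(w), clusters)
      if (length(unknown)) {
        stop("weights refer to unknown cluster(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      full <- stats::setNames(rep(0, n_clusters), clusters)
      full[names(w)] <- w
      w <- full
    }
    if (length(w) != n_clusters || any(w < 0) || sum(w) <= 0) {
      stop(what, " must be ", n_clusters, " nonnegative weights", call. = FALSE)
    }
    if (any(w[!is_t] > 0)) {
      stop(what, " must be zero for non-T clusters (TCRs live on T cells)",
           call. = FALSE)
    }
    as.numeric(w / sum(w))
  }
  if (is.null(reactive_cluster_weights)) {
    # weight 0.5 on the first T cluster, the rest spread over the other T
    # clusters (all of it if there is only one)
    t_idx <- which(is_t)
    reactive_cluster_weights <- rep(0, n_clusters)
    if (length(t_idx) == 1) {
      reactive_cluster_weights[t_idx] <- 1
    } else {
      reactive_cluster_weights[t_idx[1]] <- 0.5
      reactive_cluster_weights[t_idx[-1]] <- 0.5 / (length(t_idx) - 1)
    }
  }
  unknown_dbl <- setdiff(doublet_cluster_ids, clusters)
  if (length(unknown_dbl)) {
    stop("doublet_cluster_ids refer to unknown cluster(s): ",
         paste(unknown_dbl, collapse = ", "), call. = FALSE)
  }
  rates <- c(doublet_rate, doublet_cluster_rate, multi_alpha_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (is.null(n_reactive_cells)) {
    # default: a fifth of the T cells carry a reactive clonotype
    n_reactive_cells <- round(0.2 * sum(is_t) * cells_per_cluster)
  }
  if (n_reactive_cells > sum(is_t) * cells_per_cluster) {
    stop("n_reactive_cells exceeds the number of T cells", call. = FALSE)
  }
  cfg <- list(
    n_clusters = n_clusters, clusters = clusters,
    cells_per_cluster = cells_per_cluster, n_genes = n_genes,
    base_expression_rate = base_expression_rate, marker_boost = marker_boost,
    markers_per_cluster = markers_per_cluster, nb_dispersion = nb_dispersion,
    marker_leak_rate = marker_leak_rate,
    library_scale_sd = library_scale_sd, cluster_lineages = cluster_lineages,
    doublet_rate = doublet_rate, doublet_cluster_ids = doublet_cluster_ids,
    doublet_cluster_rate = doublet_cluster_rate, lowrna = lowrna,
    n_clonotypes = n_clonotypes, clone_size_alpha = clone_size_alpha,
    n_reactive_keys = n_reactive_keys, n_reactive_cells = n_reactive_cells,
    reactive_cluster_weights = norm_w(reactive_cluster_weights,
                                      "reactive_cluster_weights"),
    background_cluster_weights = norm_w(background_cluster_weights,
                                        "background_cluster_weights"),
    multi_alpha_rate = multi_alpha_rate, seed = as.integer(seed)
  )
  structure(cfg, class = "trl_atlas_config")
}

LINEAGE_MARKERS <- list(
  T = c("CD3D", "CD8A"),
  melanocytic = c("MLANA", "PMEL", "TYR"),
  erythroid = c("HBA1", "HBA2", "HBB"),
  bcell = c("CD19", "MS4A1"),
  myeloid = c("CD14"),
  nk = c("NCR1")
)

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_cdr3 <- function(n, prefix = "CASS") {
  lens <- sample(4:9, n, replace = TRUE)
  body <- vapply(lens, function(l) paste(sample(AA_ALPHABET, l, replace = TRUE),
                                         collapse = ""), "")
  paste0(prefix, body, "F")
}

random_keys <- function(n, v_pool, j_pool) {
  out <- tibble::tibble(cdr3b_aa = character(0))
  while (nrow(out) < n) {
    more <- tibble::tibble(
      cdr3b_aa = random_cdr3(n),
      v_gene = sample(v_pool, n, replace = TRUE),
      j_gene = sample(j_pool, n, replace = TRUE)
    )
    out <- dplyr::distinct(dplyr::bind_rows(out, more))
  }
  out <- out[seq_len(n), ]
  out$key <- clonotype_key(out$cdr3b_aa, out$v_gene, out$j_gene)
  out
}

#' Simulate a clustered single-cell atlas with planted truth
#'
#' Generates a cell-by-gene count matrix, a cell metadata table, productive
#' TCR chain records and the planted ground truth, per an [atlas_config()].
#' Counts are negative-binomial with cluster markers boosted; each singlet
#' carries one clonotype (reactive cells placed by the reactive cluster
#' weights, background cells by the background weights); doublets are
#' appended as extra cells whose count vector is the elementwise sum of two
#' parent cells (one from the doublet's home cluster, one from a random
#' other cluster), and carry the upstream doublet flag. Deterministic given
#' the config seed.
#'
#' @param config An [atlas_config()].
#' @return List with elements `counts` (sparse cell x gene matrix),
#'   `cells` (metadata tibble: barcode, sample, cluster, QC metrics,
#'   doublet_flag), `chains` (chain-record tibble), and `truth` (list:
#'   `doublet_cells`, `doublet_clusters`, `enriched_clusters`,
#'   `reactive_barcodes`, `reactive_keys` (tibble), `til_keys` (tibble),
#'   `clone_assignment` (tibble barcode/key)).
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "trl_atlas_config"))
  set.seed(config$seed)
  cfg <- config
  clusters <- cfg$clusters

  # gene universe: background + cluster markers + lineage + low-RNA markers
  bg_genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  marker_panel <- stats::setNames(
    lapply(seq_len(cfg$n_clusters), function(i) {
      sprintf("MK%s_%d", clusters[i], seq_len(cfg$markers_per_cluster))
    }), clusters)
  lineage_genes <- unique(unlist(LINEAGE_MARKERS[unique(cfg$cluster_lineages)]))
  lowrna_genes <- unique(unlist(lapply(cfg$lowrna, function(x)
    c(x$markers, x$zero_markers))))
  genes <- unique(c(bg_genes, unlist(marker_panel), lineage_genes, lowrna_genes))
  n_genes_all <- length(genes)

  # cluster assignment: T-cell clonotype carriers draw their cluster from
  # the reactive/background weights (multinomial, so planted marginal
  # frequencies are exact draws and cluster sizes fluctuate around their
  # expectation); non-T clusters get exactly cells_per_cluster cells and
  # no TCR. The total is fixed at n_clusters * cells_per_cluster.
  is_t <- cfg$cluster_lineages == "T"
  t_clusters <- clusters[is_t]
  n_total <- cfg$n_clusters * cfg$cells_per_cluster
  n_t_cells <- length(t_clusters) * cfg$cells_per_cluster
  reactive_cl <- if (cfg$n_reactive_cells > 0) {
    sample(clusters, cfg$n_reactive_cells, replace = TRUE,
           prob = cfg$reactive_cluster_weights)
  } else character(0)
  background_cl <- sample(clusters, n_t_cells - cfg$n_reactive_cells,
                          replace = TRUE, prob = cfg$background_cluster_weights)
  nont_cl <- rep(clusters[!is_t], each = cfg$cells_per_cluster)
  cell_cluster <- c(reactive_cl, background_cl, nont_cl)
  is_reactive <- c(rep(TRUE, cfg$n_reactive_cells),
                   rep(FALSE, n_total - cfg$n_reactive_cells))
  is_keyed <- c(rep(TRUE, n_t_cells), rep(FALSE, n_total - n_t_cells))
  barcodes <- sprintf("BC%05d-1", seq_len(n_total))

  # mean-expression profile per cluster: marker-class genes sit at the
  # ambient leak level everywhere except their home cluster/lineage
  special_genes <- unique(c(unlist(marker_panel), lineage_genes, lowrna_genes))
  mu_for_cluster <- function(cl) {
    mu <- rep(cfg$base_expression_rate, n_genes_all)
    names(mu) <- genes
    mu[special_genes] <- cfg$marker_leak_rate
    mu[marker_panel[[cl]]] <- cfg$base_expression_rate * cfg$marker_boost
    lin <- cfg$cluster_lineages[match(cl, clusters)]
    mu[intersect(LINEAGE_MARKERS[[lin]], genes)] <-
      cfg$base_expression_rate * cfg$marker_boost
    mu
  }
  mu_by_cluster <- lapply(stats::setNames(clusters, clusters), mu_for_cluster)

  draw_counts <- function(cl_vec, depth_scale = 1) {
    lib <- exp(stats::rnorm(length(cl_vec), 0, cfg$library_scale_sd)) * depth_scale
    m <- matrix(0L, nrow = length(cl_vec), ncol = n_genes_all)
    for (i in seq_along(cl_vec)) {
      m[i, ] <- stats::rnbinom(n_genes_all, size = cfg$nb_dispersion,
                               mu = mu_by_cluster[[cl_vec[i]]] * lib[i])
    }
    m
  }
  counts <- draw_counts(cell_cluster)

  # low-RNA cell types: extra small populations at reduced depth
  lowrna_barcodes <- character(0)
  lowrna_cluster <- character(0)
  if (length(cfg$lowrna)) {
    for (ct in names(cfg$lowrna)) {
      lr <- cfg$lowrna[[ct]]
      n_lr <- lr$n_cells
      mu <- rep(cfg$base_expression_rate, n_genes_all)
      names(mu) <- genes
      mu[special_genes] <- cfg$marker_leak_rate
      mu[intersect(lr$markers, genes)] <- cfg$base_expression_rate * cfg$marker_boost
      lib <- exp(stats::rnorm(n_lr, 0, cfg$library_scale_sd)) * lr$depth_scale
      m <- matrix(0L, nrow = n_lr, ncol = n_genes_all)
      for (i in seq_len(n_lr)) {
        m[i, ] <- stats::rnbinom(n_genes_all, size = cfg$nb_dispersion,
                                 mu = mu * lib[i])
      }
      counts <- rbind(counts, m)
      bc <- sprintf("LR%s%04d-1", toupper(substr(ct, 1, 2)), seq_len(n_lr))
      lowrna_barcodes <- c(lowrna_barcodes, bc)
      lowrna_cluster <- c(lowrna_cluster, rep(ct, n_lr))
    }
  }

  # doublets: barcode collisions appended as extra cells
  singlet_idx_by_cluster <- split(seq_len(n_total), cell_cluster)
  dbl_rows <- list(); dbl_cluster <- character(0); dbl_parents <- list()
  pick1 <- function(x) x[sample.int(length(x), 1L)]
  for (cl in clusters) {
    idx_cl <- singlet_idx_by_cluster[[cl]]
    if (is.null(idx_cl) || !length(idx_cl)) next
    rate <- if (cl %in% cfg$doublet_cluster_ids) cfg$doublet_cluster_rate
            else cfg$doublet_rate
    if (rate <= 0) next
    # n doublets so that the expected in-cluster doublet fraction is `rate`
    n_dbl <- stats::rbinom(1, length(idx_cl),
                           min(1, rate / (1 - min(rate, 0.99))))
    if (n_dbl == 0) next
    nonempty_other <- setdiff(names(singlet_idx_by_cluster), cl)
    for (d in seq_len(n_dbl)) {
      p1 <- pick1(idx_cl)
      p2_cl <- if (length(nonempty_other)) pick1(nonempty_other) else cl
      p2 <- pick1(singlet_idx_by_cluster[[p2_cl]])
      dbl_rows[[length(dbl_rows) + 1L]] <- counts[p1, ] + counts[p2, ]
      dbl_cluster <- c(dbl_cluster, cl)
      dbl_parents[[length(dbl_parents) + 1L]] <- c(p1, p2)
    }
  }
  n_dbl_total <- length(dbl_rows)
  dbl_barcodes <- if (n_dbl_total) sprintf("DB%05d-1", seq_len(n_dbl_total)) else character(0)
  if (n_dbl_total) counts <- rbind(counts, do.call(rbind, dbl_rows))

  all_barcodes <- c(barcodes, lowrna_barcodes, dbl_barcodes)
  all_cluster <- c(cell_cluster, lowrna_cluster, dbl_cluster)
  rownames(counts) <- all_barcodes
  colnames(counts) <- genes
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  attr(counts, "features") <- tibble::tibble(id = genes, symbol = genes)

  # clonotypes
  v_pool <- sprintf("TRBV%d-1", 1:25)
  j_pool <- c(sprintf("TRBJ1-%d", 1:6), sprintf("TRBJ2-%d", 1:7))
  reactive_keys <- random_keys(cfg$n_reactive_keys, v_pool, j_pool)
  bg_keys <- random_keys(cfg$n_clonotypes, v_pool, j_pool)
  while (any(bg_keys$key %in% reactive_keys$key)) {
    bg_keys <- random_keys(cfg$n_clonotypes, v_pool, j_pool)
  }
  clone_prob <- function(n) {
    p <- seq_len(n)^(-cfg$clone_size_alpha)
    p / sum(p)
  }
  react_assign <- sample(seq_len(nrow(reactive_keys)), cfg$n_reactive_cells,
                         replace = TRUE, prob = clone_prob(nrow(reactive_keys)))
  bg_assign <- sample(seq_len(nrow(bg_keys)), n_t_cells - cfg$n_reactive_cells,
                      replace = TRUE, prob = clone_prob(nrow(bg_keys)))
  keyed_barcodes <- barcodes[is_keyed]
  cell_keys <- c(reactive_keys$key[react_assign], bg_keys$key[bg_assign])
  cell_key_tab <- dplyr::bind_rows(reactive_keys[react_assign, ],
                                   bg_keys[bg_assign, ])

  # chain records: one TRB + one (sometimes two) TRA per T-lineage singlet
  ta_v <- sprintf("TRAV%d", 1:20); ta_j <- sprintf("TRAJ%d", 1:30)
  n_sing <- length(keyed_barcodes)
  two_tra <- stats::runif(n_sing) < cfg$multi_alpha_rate
  trb <- tibble::tibble(
    barcode = keyed_barcodes, sample = "synthetic", locus = "TRB",
    cdr3_aa = cell_key_tab$cdr3b_aa, v_gene = cell_key_tab$v_gene,
    j_gene = cell_key_tab$j_gene,
    umis = stats::rpois(n_sing, 3) + 1L, productive = TRUE
  )
  tra1 <- tibble::tibble(
    barcode = keyed_barcodes, sample = "synthetic", locus = "TRA",
    cdr3_aa = random_cdr3(n_sing, prefix = "CAV"),
    v_gene = sample(ta_v, n_sing, replace = TRUE),
    j_gene = sample(ta_j, n_sing, replace = TRUE),
    umis = stats::rpois(n_sing, 2) + 1L, productive = TRUE
  )
  tra2 <- tra1[two_tra, ]
  if (nrow(tra2)) {
    tra2$cdr3_aa <- random_cdr3(nrow(tra2), prefix = "CAV")
  }
  chains <- dplyr::bind_rows(trb, tra1, tra2) |>
    dplyr::arrange(.data$barcode, .data$locus, .data$cdr3_aa)

  cells <- cell_qc_metrics(counts, sample = "synthetic") |>
    dplyr::mutate(
      cluster = all_cluster,
      doublet_flag = .data$barcode %in% dbl_barcodes,
      category = dplyr::case_when(
        .data$barcode %in% barcodes[is_reactive] ~ "reactive",
        .data$barcode %in% keyed_barcodes ~ "TIL",
        TRUE ~ NA_character_
      )
    )

  truth <- list(
    doublet_cells = dbl_barcodes,
    doublet_parents = dbl_parents,
    doublet_clusters = cfg$doublet_cluster_ids,
    enriched_clusters = clusters[cfg$reactive_cluster_weights >
                                   cfg$background_cluster_weights],
    reactive_barcodes = barcodes[is_reactive],
    reactive_keys = reactive_keys,
    til_keys = dplyr::bind_rows(reactive_keys, bg_keys),
    clone_assignment = tibble::tibble(barcode = keyed_barcodes, key = cell_keys)
  )
  list(counts = counts, cells = cells, chains = chains, truth = truth,
       config = cfg)
}

#' Simulate bulk TCR-seq of a reactivity sort
#'
#' Emulates sequencing sorted activated (e.g. 4-1BB+) T cells after tumor
#' co-culture: each planted reactive clonotype is recovered with
#' probability `1 - dropout` and reported with a positive read count; no
#' non-reactive clonotype is ever emitted.
#'
#' @param truth Truth list from [simulate_atlas()].
#' @param dropout Per-clonotype dropout probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param mean_reads Mean read count per recovered clonotype.
#' @return Bulk clonotype tibble: `cdr3b_aa`, `v_gene`, `j_gene`,
#'   `read_count`, `key`.
#' @export
simulate_reactive_sort <- function(truth, dropout = 0, seed = 1L,
                                   mean_reads = 50) {
  stopifnot(dropout >= 0, dropout < 1)
  set.seed(seed)
  keys <- truth$reactive_keys
  kept <- stats::runif(nrow(keys)) >= dropout
  out <- keys[kept, ]
  out$read_count <- stats::rpois(nrow(out), mean_reads) + 1L
  out[, c("cdr3b_aa", "v_gene", "j_gene", "read_count", "key")]
}

#' Simulate per-barcode species read counts for a xenograft sample
#'
#' Draws host-read fractions in the graft band `[0, 0.1)`, the host band
#' `(0.9, 1]`, and an ambiguous middle `[0.3, 0.7]`, converts them to
#' integer host/graft read counts, and records the planted labels.
#' Rounding cannot move a barcode across a band edge because the band ends
#' are inclusive in [classify_barcodes()].
#'
#' @param n_graft,n_host,n_ambiguous Barcode counts per class.
#' @param reads_per_barcode Total reads per barcode.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `barcode`, `host_reads`,
#'   `graft_reads`) and `truth` (tibble `barcode`, `label`).
#' @export
simulate_xenograft_reads <- function(n_graft, n_host, n_ambiguous,
                                     reads_per_barcode = 1000, seed = 1L) {
  stopifnot(n_graft >= 0, n_host >= 0, n_ambiguous >= 0, reads_per_barcode > 0)
  set.seed(seed)
  frac <- c(
    stats::runif(n_graft, 0, 0.1 - 1e-9),
    1 - stats::runif(n_host, 0, 0.1 - 1e-9),
    stats::runif(n_ambiguous, 0.3, 0.7)
  )
  label <- c(rep("graft", n_graft), rep("host", n_host),
             rep("ambiguous", n_ambiguous))
  n <- length(frac)
  host_reads <- as.integer(round(frac * reads_per_barcode))
  barcode <- sprintf("XB%05d-1", seq_len(n))
  list(
    reads = tibble::tibble(barcode = barcode, host_reads = host_reads,
                           graft_reads = as.integer(reads_per_barcode) - host_reads),
    truth = tibble::tibble(barcode = barcode, label = label)
  )
}
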
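test_that("global filters enforce the biopsy and PDX profile thresholds", {
  biopsy <- qc_profile("biopsy")
  um1 <- qc_profile("um1")

  # at or below 200 genes fails the biopsy profile (strict >)
  expect_equal(nrow(apply_global_filters(qc_cell_row(n_genes = 150), biopsy)$cells), 0)
  expect_equal(nrow(apply_global_filters(qc_cell_row(n_genes = 200), biopsy)$cells), 0)
  expect_equal(nrow(apply_global_filters(qc_cell_row(n_genes = 201), biopsy)$cells), 1)

  # over 6500 genes is removed by the PDX profile; exactly 6500 survives
  expect_equal(nrow(apply_global_filters(qc_cell_row(n_genes = 7000), um1)$cells), 0)
  expect_equal(nrow(apply_global_filters(qc_cell_row(n_genes = 6500), um1)$cells), 1)
  expect_equal(nrow(apply_global_filters(qc_cell_row(n_genes = 399), um1)$cells), 0)

  # a healthy cell passes both profiles
  good <- qc_cell_row()
  expect_equal(nrow(apply_global_filters(good, biopsy)$cells), 1)
  expect_equal(nrow(apply_global_filters(good, um1)$cells), 1)

  # per-criterion removal counts: one cell can count toward several
  bad <- qc_cell_row(n_genes = 100, n_umi = 300)
  rep <- apply_global_filters(bad, biopsy)$report
  expect_equal(rep$n_removed[rep$metric == "n_genes"], 1L)
  expect_equal(rep$n_removed[rep$metric == "n_umi"], 1L)

  expect_error(apply_global_filters(dplyr::select(good, -"pct_ribo"), biopsy),
               "pct_ribo")
})

test_that("global filtering is idempotent", {
  set.seed(21)
  cells <- tibble::tibble(
    barcode = sprintf("B%03d", 1:200), sample = "s",
    n_genes = sample(50:8000, 200), n_umi = sample(100:30000, 200),
    pct_mito = runif(200, 0, 30), pct_ribo = runif(200, 0, 60),
    pct_top100 = runif(200, 20, 95)
  )
  for (prof in list(qc_profile("biopsy"), qc_profile("um1"))) {
    once <- apply_global_filters(cells, prof)$cells
    twice <- apply_global_filters(once, prof)
    expect_equal(twice$cells, once)
    expect_equal(sum(twice$report$n_removed), 0L)
  }
})

test_that("lineage-conflict flags fire on the published marker combinations", {
  genes <- c("CD3D", "CD8A", "MLANA", "CD14", "NCR1", "G001")
  counts <- sparse_counts(rbind(
    c(2, 0, 1, 0, 0, 5),   # T marker + melanocytic marker -> doublet
    c(0, 0, 0, 3, 0, 5),   # assembled TCR + myeloid marker -> doublet
    c(5, 1, 0, 0, 0, 5),   # T markers only -> clean
    c(0, 0, 2, 0, 4, 5),   # melanocytic + NK marker -> doublet
    c(0, 0, 0, 0, 0, 5)    # nothing -> clean
  ), genes = genes)
  chains <- tibble::tibble(barcode = "BC002-1", sample = "s", locus = "TRB",
                           cdr3_aa = "CASSF", v_gene = "TRBV1",
                           j_gene = "TRBJ1-1", umis = 2, productive = TRUE)
  flags <- suppressMessages(flag_lineage_conflicts(counts, chains))
  expect_identical(flags$lineage_doublet, c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("lineage flagging is monotone in expression", {
  genes <- c("CD3D", "MLANA", "PMEL", "G001")
  set.seed(3)
  base <- matrix(rpois(40, 0.5), nrow = 10)
  counts <- sparse_counts(base, genes = genes)
  f1 <- suppressMessages(flag_lineage_conflicts(counts, NULL))
  more <- base
  more[, 2] <- more[, 2] + 1   # turn on a conflict gene everywhere
  f2 <- suppressMessages(flag_lineage_conflicts(sparse_counts(more, genes = genes), NULL))
  expect_true(all(f2$lineage_doublet >= f1$lineage_doublet))
})

test_that("cluster doublet statistics match enumeration and orient OR correctly", {
  cells <- tibble::tibble(
    barcode = sprintf("B%03d", 1:40), sample = "s",
    cluster = rep(c("A", "B"), each = 20),
    doublet_flag = c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 1), rep(FALSE, 19)),
    n_umi = rep(1000, 40)
  )
  st <- cluster_doublet_stats(cells)
  expect_gt(st$odds_ratio[st$cluster == "A"], 1)
  expect_lt(st$odds_ratio[st$cluster == "B"], 1)
  # table [[10,1],[10,19]]: p equals the hypergeometric enumeration oracle
  expect_equal(st$p[st$cluster == "A"], oracle_fisher_p(10, 1, 10, 19),
               tolerance = 1e-12)

  # identical doublet fractions across clusters -> no association
  null_cells <- tibble::tibble(
    barcode = sprintf("B%03d", 1:40), sample = "s",
    cluster = rep(c("A", "B"), each = 20),
    doublet_flag = rep(c(TRUE, rep(FALSE, 9)), 4),
    n_umi = 1000
  )
  st0 <- cluster_doublet_stats(null_cells)
  expect_equal(st0$p, rep(1, 2))
})

test_that("doublet-cluster nomination covers all three criteria", {
  make_stats <- function(pcts, umis, q = rep(0.5, length(pcts)),
                         or = rep(1, length(pcts))) {
    structure(tibble::tibble(
      cluster = paste0("C", seq_along(pcts)), n_cells = 100,
      n_doublets = round(pcts), pct_doublets = pcts, median_umi = umis,
      odds_ratio = or, p = q, q = q
    ), class = c("trl_doublet_stats", "tbl_df", "tbl", "data.frame"))
  }
  # maximal doublet pct is always >= the 95th percentile
  st <- make_stats(pcts = c(rep(5, 19), 60), umis = rep(1000, 20))
  nom <- nominate_doublet_clusters(st)
  expect_true("C20" %in% nom$cluster)
  expect_true(grepl("doublet_pct", nom$reasons[nom$cluster == "C20"]))

  # unremarkable cluster is not nominated
  st2 <- make_stats(pcts = c(10, 12, 8, 11, 9), umis = c(900, 1100, 1000, 950, 1050),
                    q = c(0.2, 0.6, 0.7, 0.9, 0.5))
  nom2 <- nominate_doublet_clusters(st2)
  expect_false("C1" %in% nom2$cluster)

  # significant fisher criterion with OR > 1
  st3 <- make_stats(pcts = rep(10, 5), umis = rep(1000, 5),
                    q = c(0.001, 0.5, 0.5, 0.5, 0.5), or = c(4, 1, 1, 1, 1))
  nom3 <- nominate_doublet_clusters(st3)
  expect_true(grepl("fisher", nom3$reasons[nom3$cluster == "C1"]))
  # the literal published direction selects OR < 1 instead
  expect_warning(nom3l <- nominate_doublet_clusters(st3, fisher_or_direction = "literal"),
                 "literal")
  expect_false("C1" %in% nom3l$cluster[grepl("fisher", nom3l$reasons)])
})

test_that("planted doublet clusters are recovered from simulated atlases", {
  hits <- 0; false_noms <- 0; n_runs <- 20
  for (s in seq_len(n_runs)) {
    sim <- simulate_atlas(atlas_config(
      n_clusters = 10, cells_per_cluster = 60, n_genes = 60,
      doublet_cluster_ids = c("C3", "C5"), doublet_cluster_rate = 0.5,
      doublet_rate = 0.05, n_reactive_cells = 0, seed = 1000 + s))
    st <- cluster_doublet_stats(sim$cells)
    nom <- nominate_doublet_clusters(st)
    fisher_noms <- nom$cluster[nom$fisher]
    if (all(c("C3", "C5") %in% nom$cluster)) hits <- hits + 1
    false_noms <- false_noms + length(setdiff(fisher_noms, c("C3", "C5")))
  }
  expect_gte(hits, n_runs - 1)
  expect_equal(false_noms, 0)
})

test_that("low-RNA rescue computes interpolated quartile thresholds", {
  # four clean candidates with UMIs 100..400: Q1 = 175, three cells pass UMI
  genes <- c("JCHAIN", "IL3RA", "LILRA4", "G001", "G002", "G003")
  mat <- rbind(
    c(5, 0, 0, 10, 20, 5),
    c(6, 0, 0, 12, 18, 6),
    c(4, 0, 0, 11, 21, 4),
    c(5, 0, 0, 13, 19, 5),
    c(3, 2, 0, 10, 20, 5)   # JCHAIN+ but IL3RA>0: not a plasma candidate
  )
  counts <- sparse_counts(mat, genes = genes)
  cells <- tibble::tibble(
    barcode = rownames(counts), sample = "s",
    n_umi = c(100, 200, 300, 400, 999), n_genes = c(50, 60, 70, 80, 99),
    doublet_flag = FALSE
  )
  res <- rescue_low_rna_celltypes(
    counts, cells,
    celltype_spec = list(plasma_cell = list(markers_pos = "JCHAIN",
                                            markers_zero = c("IL3RA", "LILRA4"))),
    k = 1)
  expect_equal(res$thresholds$q1_umi, 175)
  expect_equal(res$thresholds$n_candidates, 4L)
  expect_setequal(res$barcodes, rownames(counts)[2:4])

  # fewer than 4 candidates: skipped with a warning
  expect_warning(
    res2 <- rescue_low_rna_celltypes(
      counts[1:3, ], cells[1:3, ],
      celltype_spec = list(plasma_cell = list(markers_pos = "JCHAIN",
                                              markers_zero = c("IL3RA", "LILRA4"))),
      k = 1),
    "fewer than 4")
  expect_true(res2$thresholds$skipped)
  expect_length(res2$barcodes, 0)
})

test_that("rescue discards candidate groups dominated by doublets", {
  set.seed(8)
  genes <- c("HBB", paste0("G", 1:9))
  clean <- matrix(rpois(8 * 10, 2), nrow = 8)
  clean[, 1] <- 5
  dirty <- matrix(rpois(8 * 10, 2), nrow = 8)
  dirty[, 1] <- 5
  dirty[, 6:10] <- dirty[, 6:10] + 30   # distinct expression profile
  counts <- sparse_counts(rbind(clean, dirty), genes = genes)
  cells <- tibble::tibble(
    barcode = rownames(counts), sample = "s",
    n_umi = c(100 + 10 * (0:7), rep(400, 8)),
    n_genes = c(40 + 2 * (0:7), rep(80, 8)),
    doublet_flag = c(rep(FALSE, 8), rep(TRUE, 8))
  )
  res <- rescue_low_rna_celltypes(
    counts, cells,
    celltype_spec = list(ery = list(markers_pos = "HBB",
                                    markers_zero = character(0))),
    k = 2)
  # only the clean group survives; its cells define the thresholds
  expect_true(all(res$barcodes %in% rownames(counts)[1:8]))
  expect_equal(res$thresholds$q1_umi, 117.5)
})
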
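test_that("category frequencies follow the cells-in-cluster over category-total formula", {
  cells <- tibble::tibble(
    cluster = c(rep("A", 4), rep("B", 6), rep("A", 3)),
    category = c(rep("reactive", 10), rep("TIL", 3))
  )
  fr <- category_frequencies(cells)
  expect_equal(fr$frequency[fr$category == "reactive" & fr$cluster == "A"], 0.4)
  expect_equal(fr$frequency[fr$category == "TIL" & fr$cluster == "B"], 0)
  sums <- fr |> dplyr::group_by(category) |> dplyr::summarise(s = sum(frequency))
  expect_equal(sums$s, rep(1, 2))

  one <- category_frequencies(tibble::tibble(cluster = "A", category = "x"))
  expect_equal(one$frequency, 1)

  set.seed(4)
  rand <- tibble::tibble(cluster = sample(LETTERS[1:6], 300, TRUE),
                         category = sample(c("a", "b", "c"), 300, TRUE))
  frr <- category_frequencies(rand)
  expect_equal(as.numeric(tapply(frr$frequency, frr$category, sum)),
               c(1, 1, 1))
})

make_enrichment_cells <- function(clusters, keys) {
  tibble::tibble(barcode = sprintf("B%04d", seq_along(clusters)),
                 cluster = clusters, key = keys)
}

test_that("reactive enrichment computes x, p0, p, direction and delta as specified", {
  # 10 reactive cells, 4 in A; TIL background 40% in A: observed = expected
  reactive_keys <- paste0("R", 1:5)
  til_keys <- c(reactive_keys, paste0("T", 1:20))
  cl <- c(rep("A", 4), rep("B", 6),           # 10 reactive cells
          rep("A", 36), rep("B", 54))         # 90 background TIL cells
  keys <- c(sample(reactive_keys, 10, replace = TRUE),
            sample(paste0("T", 1:20), 90, replace = TRUE))
  enr <- reactive_cluster_enrichment(make_enrichment_cells(cl, keys),
                                     reactive_keys, til_keys)
  a <- enr[enr$cluster == "A", ]
  expect_equal(a$x, 4L)
  expect_equal(a$n, 10L)
  expect_equal(a$p0, 0.4)
  expect_equal(a$p_two_sided, 1)
  expect_identical(a$direction, "none")
  # deltas over clusters sum to zero
  expect_equal(sum(enr$delta), 0, tolerance = 1e-12)
  # Bonferroni m = number of clusters tested
  expect_equal(enr$p_bonf, pmin(1, enr$p_two_sided * nrow(enr)))
})

test_that("degenerate background clusters are flagged, not dropped", {
  reactive_keys <- "R1"
  til_keys <- "T1"
  cells <- make_enrichment_cells(c("A", "A", "B", "B"),
                                 c("R1", "R1", "T1", "T1"))
  enr <- reactive_cluster_enrichment(cells, reactive_keys, til_keys)
  a <- enr[enr$cluster == "A", ]
  expect_true(a$degenerate_background)   # p0 = 0 with x > 0
  expect_equal(a$p0, 0)
  expect_equal(nrow(enr), 2)
})

test_that("planted cluster enrichment is detected with high power", {
  hits <- 0; n_runs <- 20
  for (s in seq_len(n_runs)) {
    sim <- simulate_atlas(atlas_config(
      n_clusters = 10, cells_per_cluster = 100, n_genes = 60,
      n_reactive_cells = 200, doublet_rate = 0, seed = 2000 + s))
    cells <- dplyr::left_join(sim$cells, sim$truth$clone_assignment,
                              by = "barcode")
    enr <- reactive_cluster_enrichment(cells, sim$truth$reactive_keys$key,
                                       sim$truth$til_keys$key)
    planted <- sim$truth$enriched_clusters
    row <- enr[enr$cluster %in% planted, ]
    if (nrow(row) && any(row$p_bonf < 0.05 & row$direction == "over")) hits <- hits + 1
  }
  expect_equal(hits, n_runs)
})

test_that("tidy, glance and autoplot work on enrichment results", {
  cells <- make_enrichment_cells(rep(c("A", "B"), each = 20),
                                 c(rep("R1", 15), rep("T1", 5),
                                   rep("T2", 18), rep("R2", 2)))
  enr <- reactive_cluster_enrichment(cells, c("R1", "R2"),
                                     c("R1", "R2", "T1", "T2"))
  td <- tidy(enr)
  expect_named(td, c("term", "estimate", "null.value", "statistic", "p.value",
                     "adj.p.value", "delta", "direction"))
  gl <- glance(enr)
  expect_equal(gl$n_clusters, 2L)
  expect_equal(gl$n_reactive_cells, 17L)
  p <- autoplot(enr)
  expect_s3_class(p, "ggplot")
})

test_that("pseudobulk aggregation sums counts by group and conserves totals", {
  set.seed(12)
  m <- sparse_counts(matrix(rpois(8 * 5, 3), nrow = 8))
  cells <- tibble::tibble(barcode = rownames(m),
                          sample = rep(c("s1", "s2"), each = 4),
                          condition = rep(c("a", "b"), 4))
  pb <- pseudobulk_aggregate(m, cells, group_by = c("sample", "condition"))
  expect_equal(sum(pb$matrix), sum(m))
  expect_equal(ncol(pb$matrix), 4)
  # explicit sum check for one group
  g <- cells$barcode[cells$sample == "s1" & cells$condition == "a"]
  expect_equal(pb$matrix[, "s1:a"], Matrix::colSums(m[g, , drop = FALSE]))

  # permutation invariance over cell order
  perm <- sample(nrow(m))
  pb2 <- pseudobulk_aggregate(m[perm, ], cells[perm, ],
                              group_by = c("sample", "condition"))
  expect_equal(pb2$matrix, pb$matrix)

  # one cell per group: columns are the input rows rearranged
  solo <- tibble::tibble(barcode = rownames(m), sample = rownames(m))
  pb3 <- pseudobulk_aggregate(m, solo, group_by = "sample")
  expect_equal(unname(pb3$matrix[, rownames(m)[3]]), unname(as.numeric(m[3, ])))

  # ungrouped cell -> error
  bad <- cells; bad$condition[1] <- NA
  expect_error(pseudobulk_aggregate(m, bad, group_by = c("sample", "condition")),
               "exactly one group")
})
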
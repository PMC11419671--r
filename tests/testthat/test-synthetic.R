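test_that("atlas bookkeeping: cell counts, determinism and config validation", {
  cfg <- atlas_config(n_clusters = 3, cells_per_cluster = 100, n_genes = 50,
                      doublet_rate = 0, n_reactive_cells = 50, seed = 5)
  sim <- simulate_atlas(cfg)
  expect_equal(nrow(sim$cells), 300)
  expect_equal(nrow(sim$counts), 300)
  expect_length(sim$truth$doublet_cells, 0)

  # same config, same seed -> identical outputs
  sim2 <- simulate_atlas(cfg)
  expect_identical(as.matrix(sim$counts), as.matrix(sim2$counts))
  expect_equal(sim$cells, sim2$cells)
  expect_equal(sim$chains, sim2$chains)

  # weights for unknown clusters are rejected
  expect_error(atlas_config(n_clusters = 3,
                            reactive_cluster_weights = c(C1 = 1, C9 = 1)),
               "unknown cluster")
  expect_error(atlas_config(doublet_rate = 1.5), "rates")
})

test_that("every singlet T cell carries one clonotype and chains agree with truth", {
  sim <- simulate_atlas(atlas_config(n_clusters = 4, cells_per_cluster = 50,
                                     n_genes = 50, doublet_rate = 0.05, seed = 8))
  truth <- sim$truth
  # planted barcodes all exist in the emitted cell table
  expect_true(all(truth$doublet_cells %in% sim$cells$barcode))
  expect_true(all(truth$clone_assignment$barcode %in% sim$cells$barcode))
  # rebuilding clonotypes from the chain records recovers the assignment
  cc <- build_cell_clonotypes(sim$chains)
  merged <- dplyr::inner_join(cc, truth$clone_assignment, by = "barcode")
  expect_equal(nrow(merged), nrow(truth$clone_assignment))
  expect_identical(merged$key.x, merged$key.y)
  # doublets carry no clonotype
  expect_false(any(truth$doublet_cells %in% sim$chains$barcode))
})

test_that("a planted doublet's counts equal the sum of its parents'", {
  sim <- simulate_atlas(atlas_config(n_clusters = 3, cells_per_cluster = 40,
                                     n_genes = 40, doublet_rate = 0.2, seed = 9))
  n_dbl <- length(sim$truth$doublet_cells)
  expect_gt(n_dbl, 0)
  m <- as.matrix(sim$counts)
  for (i in seq_len(n_dbl)) {
    parents <- sim$truth$doublet_parents[[i]]
    expect_equal(m[sim$truth$doublet_cells[i], ],
                 m[parents[1], ] + m[parents[2], ])
  }
})

test_that("reactive cells land in clusters per the planted weights", {
  # weight 0.8 on one cluster: empirical fraction within 3 binomial SE
  w <- c(0.8, 0.1, 0.1)
  sim <- simulate_atlas(atlas_config(
    n_clusters = 3, cells_per_cluster = 200, n_genes = 40,
    cluster_lineages = rep("T", 3), reactive_cluster_weights = w,
    n_reactive_cells = 300, doublet_rate = 0, seed = 10))
  cells <- dplyr::filter(sim$cells, .data$barcode %in% sim$truth$reactive_barcodes)
  frac <- mean(cells$cluster == "C1")
  se <- sqrt(0.8 * 0.2 / 300)
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("cross-lineage doublets trip the lineage-conflict rules", {
  sim <- simulate_atlas(atlas_config(n_clusters = 4, cells_per_cluster = 60,
                                     n_genes = 60, doublet_rate = 0.15, seed = 12))
  flags <- suppressMessages(
    flag_lineage_conflicts(sim$counts, sim$chains))
  merged <- dplyr::left_join(sim$cells, flags, by = "barcode")
  dbl <- merged$barcode %in% sim$truth$doublet_cells
  # doublets pairing a T parent with the melanocytic cluster conflict;
  # expect a clearly elevated flag rate among doublets vs singlets
  expect_gt(mean(merged$lineage_doublet[dbl]), 0.3)
  expect_lt(mean(merged$lineage_doublet[!dbl]), 0.05)
})

test_that("reactive sort emits exactly the planted keys, honoring dropout", {
  sim <- simulate_atlas(atlas_config(n_clusters = 3, cells_per_cluster = 30,
                                     n_genes = 30, seed = 13,
                                     n_reactive_cells = 30))
  truth <- sim$truth
  bulk0 <- simulate_reactive_sort(truth, dropout = 0, seed = 1)
  expect_setequal(bulk0$key, truth$reactive_keys$key)
  expect_true(all(bulk0$read_count > 0))

  # emitted keys are always a subset of the planted reactive set
  for (s in 1:10) {
    b <- simulate_reactive_sort(truth, dropout = 0.5, seed = s)
    expect_true(all(b$key %in% truth$reactive_keys$key))
  }

  # high dropout: mean recovery approximates the retention probability
  eps <- 0.1
  rec <- vapply(1:200, function(s)
    nrow(simulate_reactive_sort(truth, dropout = 1 - eps, seed = s)), numeric(1))
  n_keys <- nrow(truth$reactive_keys)
  se <- sqrt(eps * (1 - eps) / (200 * n_keys))
  expect_lt(abs(mean(rec) / n_keys - eps), 4 * se)
})

test_that("low-RNA populations are emitted at reduced depth with their markers", {
  sim <- simulate_atlas(atlas_config(
    n_clusters = 3, cells_per_cluster = 60, n_genes = 100, seed = 14,
    lowrna = list(plasma = list(markers = "JCHAIN", depth_scale = 0.25,
                                n_cells = 30))))
  plasma <- dplyr::filter(sim$cells, .data$cluster == "plasma")
  others <- dplyr::filter(sim$cells, .data$cluster != "plasma", !.data$doublet_flag)
  expect_equal(nrow(plasma), 30)
  expect_lt(median(plasma$n_umi), 0.5 * median(others$n_umi))
  expect_true(all(sim$counts[plasma$barcode, "JCHAIN"] |> as.numeric() |> median() > 0))
})
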
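# Per-stage seed substream: stable hash of the stage name folded into the
# run seed, kept below 2^31 so stages re-run reproducibly in isolation.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483647L
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config needs an `outdir`", call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  config$qc_profile <- config$qc_profile %||% "biopsy"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full tumor-reactive lymphocyte pipeline
#'
#' Orchestrates the stages end to end: input simulation (or loading),
#' xenograft host/graft classification, QC filtering (global thresholds,
#' lineage-conflict doublets, doublet-cluster removal), clonotype
#' construction and matching against the reactivity-sorted bulk
#' repertoire, per-cluster enrichment testing, and pseudo-bulk
#' aggregation. All outputs are TSV/MTX files under `outdir`; identical
#' config and seed give byte-identical outputs. A stage failure aborts the
#' run with the failing stage named and leaves a `RUN.partial` marker next
#' to any partial outputs.
#'
#' @param config A config list or the path to a YAML config. Recognized
#'   fields: `outdir`, `seed`, `qc_profile` (`"biopsy"` or `"um1"`),
#'   `fisher_or_direction`, and either a `simulate` block (overrides for
#'   [atlas_config()], plus `xeno: [n_graft, n_host, n_ambiguous]`) or an
#'   `inputs` block with paths `counts_mtx`, `barcodes`, `features`, `vdj`
#'   (+ `vdj_dialect`), `cells` (TSV with `barcode`, `cluster`,
#'   `doublet_flag`), `bulk_reactive`, `bulk_til`, and optionally
#'   `xeno_reads`.
#' @return The run report, invisibly: a list with the seed, per-stage
#'   status and cell/clone counts, and the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  partial_marker <- file.path(cfg$outdir, "RUN.partial")
  file.create(partial_marker)
  report <- list(seed = cfg$seed, stages = list(), paths = character(0))
  current_stage <- "validate"
  run_stage <- function(name, fun) {
    current_stage <<- name
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(cfg$outdir, file)
    write_table(df, path)
    report$paths <<- c(report$paths, path)
    path
  }

  # --- inputs: simulate or load ------------------------------------------
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    run_stage("simulate", function() {
      args <- cfg$simulate
      xeno_spec <- args$xeno; args$xeno <- NULL
      args$seed <- stage_seed(cfg$seed, "simulate")
      ac <- do.call(atlas_config, args)
      sim <<- simulate_atlas(ac)
      sim$bulk_reactive <<- simulate_reactive_sort(
        sim$truth, dropout = 0, seed = stage_seed(cfg$seed, "reactive_sort"))
      sim$bulk_til <<- dplyr::mutate(sim$truth$til_keys, read_count = 1L)
      if (!is.null(xeno_spec)) {
        sim$xeno <<- simulate_xenograft_reads(
          xeno_spec[[1]], xeno_spec[[2]], xeno_spec[[3]],
          seed = stage_seed(cfg$seed, "xeno"))
      }
      report$stages$simulate <<- list(
        status = "complete",
        n_cells = nrow(sim$cells),
        n_doublets = length(sim$truth$doublet_cells)
      )
    })
    counts <- sim$counts
    cells <- sim$cells
    chains <- sim$chains
    bulk_reactive <- sim$bulk_reactive
    bulk_til <- sim$bulk_til
    xeno_reads <- if (!is.null(sim$xeno)) sim$xeno$reads else NULL
  } else {
    run_stage("load_inputs", function() {
      inp <- cfg$inputs
      needed <- c("counts_mtx", "barcodes", "features", "vdj", "cells",
                  "bulk_reactive", "bulk_til")
      for (f in needed) {
        if (is.null(inp[[f]])) stop("config inputs lack `", f, "`")
        if (!file.exists(inp[[f]])) stop("input path does not exist: ", inp[[f]])
      }
      report$stages$load_inputs <<- list(status = "complete")
    })
    inp <- cfg$inputs
    counts <- read_counts_mtx(inp$counts_mtx, inp$barcodes, inp$features)
    chains <- read_vdj_contigs(inp$vdj, dialect = inp$vdj_dialect %||% "tenx_csv",
                               sample = inp$sample %||% "sample1")
    cell_meta <- read_table_tsv(inp$cells)
    cells <- cell_qc_metrics(counts, sample = inp$sample %||% "sample1") |>
      dplyr::left_join(dplyr::select(cell_meta, dplyr::any_of(
        c("barcode", "cluster", "doublet_flag", "category"))), by = "barcode")
    bulk_reactive <- read_bulk_clonotypes(inp$bulk_reactive)
    bulk_til <- read_bulk_clonotypes(inp$bulk_til)
    xeno_reads <- if (!is.null(inp$xeno_reads)) read_table_tsv(inp$xeno_reads) else NULL
  }

  # --- xenosplit ---------------------------------------------------------
  if (!is.null(xeno_reads)) {
    run_stage("xenosplit", function() {
      labels <- classify_barcodes(compute_species_fractions(xeno_reads))
      emit(labels, "xeno_labels.tsv")
      report$stages$xenosplit <<- list(
        status = "complete",
        n_graft = sum(labels$label == "graft"),
        n_host = sum(labels$label == "host"),
        n_ambiguous = sum(labels$label == "ambiguous")
      )
    })
  }

  # --- qc ----------------------------------------------------------------
  retained <- NULL
  run_stage("qc", function() {
    lineage <- flag_lineage_conflicts(counts, chains)
    cells <<- dplyr::left_join(cells, lineage, by = "barcode") |>
      dplyr::mutate(doublet_flag = .data$doublet_flag | .data$lineage_doublet)
    profile <- qc_profile(cfg$qc_profile)
    gf <- apply_global_filters(cells, profile)
    emit(gf$report, "filter_report.tsv")
    dstats <- cluster_doublet_stats(cells)
    emit(dstats, "doublet_cluster_stats.tsv")
    nominated <- nominate_doublet_clusters(
      dstats, fisher_or_direction = cfg$fisher_or_direction %||% "over")
    emit(nominated, "doublet_clusters_nominated.tsv")
    retained <<- gf$cells |>
      dplyr::filter(!.data$doublet_flag,
                    !.data$cluster %in% nominated$cluster)
    emit(retained, "cells_retained.tsv")
    report$stages$qc <<- list(
      status = "complete",
      n_in = nrow(cells),
      n_pass_global = nrow(gf$cells),
      n_nominated_clusters = nrow(nominated),
      n_retained = nrow(retained),
      n_removed = nrow(cells) - nrow(retained)
    )
  })

  # --- clonotype ---------------------------------------------------------
  cell_keys <- NULL
  run_stage("clonotype", function() {
    cc <- build_cell_clonotypes(chains)
    cell_keys <<- retained |>
      dplyr::left_join(dplyr::select(cc, "barcode", "key", "n_tra", "n_trb",
                                     "multi_alpha"), by = "barcode")
    emit(cc, "cell_clonotypes.tsv")
    matched <- match_clonotypes(cell_keys$key, bulk_reactive$key)
    emit(tibble::tibble(key = matched), "matched_reactive_keys.tsv")
    emit(top_clonotypes(cell_keys), "top_clonotypes.tsv")
    report$stages$clonotype <<- list(
      status = "complete",
      n_cells_with_key = sum(!is.na(cell_keys$key)),
      n_reactive_keys_matched = length(matched)
    )
  })

  # --- enrichment --------------------------------------------------------
  run_stage("enrichment", function() {
    enr <- reactive_cluster_enrichment(cell_keys, bulk_reactive$key, bulk_til$key)
    emit(enr, "enrichment.tsv")
    freq_cells <- cell_keys |>
      dplyr::filter(!is.na(.data$key)) |>
      dplyr::mutate(category = dplyr::if_else(.data$key %in% bulk_reactive$key,
                                              "reactive", "TIL"))
    emit(category_frequencies(freq_cells), "category_frequencies.tsv")
    report$stages$enrichment <<- list(
      status = "complete",
      n_clusters_tested = nrow(enr),
      n_significant = sum(enr$p_bonf < 0.05)
    )
  })

  # --- pseudobulk --------------------------------------------------------
  run_stage("pseudobulk", function() {
    grouped <- retained |>
      dplyr::mutate(condition = dplyr::if_else(
        .data$barcode %in% cell_keys$barcode[
          !is.na(cell_keys$key) & cell_keys$key %in% bulk_reactive$key],
        "reactive", "other"))
    pb <- pseudobulk_aggregate(counts[grouped$barcode, , drop = FALSE],
                               grouped, group_by = c("sample", "condition"))
    pb_df <- tibble::as_tibble(pb$matrix, rownames = "gene")
    emit(pb_df, "pseudobulk_counts.tsv")
    emit(pb$design, "pseudobulk_design.tsv")
    report$stages$pseudobulk <<- list(
      status = "complete",
      n_groups = ncol(pb$matrix),
      total_counts = sum(pb$matrix)
    )
  })

  report$config <- cfg[setdiff(names(cfg), "simulate_data")]
  yaml::write_yaml(report, file.path(cfg$outdir, "run_report.yaml"))
  report$paths <- c(report$paths, file.path(cfg$outdir, "run_report.yaml"))
  file.remove(partial_marker)
  invisible(report)
}

#' Create a small demo workspace
#'
#' Writes a compact synthetic dataset (well under 5,000 cells) in the
#' on-disk formats the pipeline reads - a 10x-style MTX triplet, a 10x
#' V(D)J contig CSV, bulk clonotype TSVs for the reactivity sort and the
#' TIL culture, a per-barcode xenograft species-read TSV, a cell metadata
#' TSV - plus a `config.yaml` that exercises every stage from those files.
#'
#' @param dir Workspace directory (created).
#' @param seed Integer seed.
#' @return Path to the written `config.yaml`, invisibly.
#' @export
make_demo <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ac <- atlas_config(
    n_clusters = 8, cells_per_cluster = 120,
    doublet_cluster_ids = "C7", doublet_cluster_rate = 0.5,
    n_reactive_cells = 150, n_reactive_keys = 15, n_clonotypes = 300,
    seed = stage_seed(seed, "demo")
  )
  sim <- simulate_atlas(ac)
  write_counts_mtx(sim$counts, file.path(dir, "counts"))
  vdj <- sim$chains |>
    dplyr::transmute(barcode = .data$barcode, chain = .data$locus,
                     v_gene = .data$v_gene, j_gene = .data$j_gene,
                     cdr3 = .data$cdr3_aa, umis = .data$umis,
                     productive = ifelse(.data$productive, "true", "false"))
  readr::write_csv(vdj, file.path(dir, "filtered_contig_annotations.csv"),
                   progress = FALSE)
  write_table(dplyr::select(sim$cells, "barcode", "cluster", "doublet_flag",
                            "category"),
              file.path(dir, "cells.tsv"))
  bulk <- simulate_reactive_sort(sim$truth, dropout = 0,
                                 seed = stage_seed(seed, "demo_sort"))
  write_table(dplyr::select(bulk, -"key"), file.path(dir, "bulk_reactive.tsv"))
  til <- dplyr::mutate(sim$truth$til_keys, read_count = 1L)
  write_table(dplyr::select(til, "cdr3b_aa", "v_gene", "j_gene", "read_count"),
              file.path(dir, "bulk_til.tsv"))
  xeno <- simulate_xenograft_reads(60, 30, 10, seed = stage_seed(seed, "demo_xeno"))
  write_table(xeno$reads, file.path(dir, "xeno_reads.tsv"))

  config <- list(
    outdir = file.path(dir, "out"),
    seed = as.integer(seed),
    qc_profile = "biopsy",
    inputs = list(
      counts_mtx = file.path(dir, "counts", "matrix.mtx"),
      barcodes = file.path(dir, "counts", "barcodes.tsv"),
      features = file.path(dir, "counts", "features.tsv"),
      vdj = file.path(dir, "filtered_contig_annotations.csv"),
      vdj_dialect = "tenx_csv",
      cells = file.path(dir, "cells.tsv"),
      bulk_reactive = file.path(dir, "bulk_reactive.tsv"),
      bulk_til = file.path(dir, "bulk_til.tsv"),
      xeno_reads = file.path(dir, "xeno_reads.tsv"),
      sample = "demo"
    )
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
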
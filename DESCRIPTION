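Package: trlmap
Title: Mapping Tumor-Reactive T Lymphocytes in Single-Cell RNA/TCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies tumor-reactive T lymphocytes (TRLs) in paired
    single-cell RNA and TCR sequencing data. Provides bespoke quality
    control for tumor biopsies (global metric thresholds, lineage-conflict
    doublet flagging, cluster-level doublet removal by exact tests, and
    rescue of low-RNA cell types), classification of patient-derived
    xenograft barcodes into host and graft by species read fractions,
    exact clonotype matching between reactivity-sorted bulk TCR-seq and
    single-cell atlases on the (CDR3beta, Vbeta, Jbeta) key, per-cluster
    enrichment statistics that attribute reactive clones to phenotype
    clusters via two-sided exact binomial tests against the
    tumor-infiltrating-lymphocyte background, and pseudo-bulk aggregation
    for downstream count-based differential expression. A synthetic-data
    generator with planted ground truth makes every stage testable
    without access to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
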
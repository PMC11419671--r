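#' Per-barcode species read fractions
#'
#' Computes, for each cellular barcode of a patient-derived xenograft
#' sample, the fraction of reads assigned to the host (mouse) genome:
#' `host_fraction = host_reads / (host_reads + graft_reads)`. Barcodes with
#' zero total reads get `NA` and are excluded from classification.
#'
#' @param read_counts Tibble with columns `barcode`, `host_reads`,
#'   `graft_reads` (nonnegative).
#' @return The input with a `host_fraction` column appended.
#' @export
compute_species_fractions <- function(read_counts) {
  stopifnot(all(c("barcode", "host_reads", "graft_reads") %in% names(read_counts)))
  if (any(read_counts$host_reads < 0) || any(read_counts$graft_reads < 0)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  dplyr::mutate(read_counts,
    total = .data$host_reads + .data$graft_reads,
    host_fraction = dplyr::if_else(.data$total > 0,
                                   .data$host_reads / .data$total, NA_real_)
  ) |>
    dplyr::select(-"total")
}

#' Classify xenograft barcodes as graft, host or ambiguous
#'
#' Labels each barcode by where its host-read fraction falls: inside the
#' graft band (default `[0, 0.1]`: at most 10 percent mouse reads) it is
#' graft (human tumor), inside the host band (default `[0.9, 1]`) it is
#' host (mouse), otherwise ambiguous. Band ends are inclusive on both
#' sides, so a fraction of exactly 0.1 is graft and exactly 0.9 is host.
#' The thresholds are bounds on the HOST-read fraction, matching the
#' convention of alignment-based read-splitting tools. Barcodes with an
#' undefined fraction (zero total reads) are dropped with a message.
#'
#' @param fractions Output of [compute_species_fractions()].
#' @param graft_band,host_band Length-2 numeric bands within `[0, 1]`;
#'   they must not overlap.
#' @return The classified rows with a `label` column
#'   (`"graft"`/`"host"`/`"ambiguous"`); the three labels partition all
#'   barcodes with defined fractions.
#' @export
classify_barcodes <- function(fractions, graft_band = c(0, 0.1),
                              host_band = c(0.9, 1)) {
  stopifnot("host_fraction" %in% names(fractions))
  for (b in list(graft_band, host_band)) {
    if (length(b) != 2 || any(b < 0) || any(b > 1) || b[1] > b[2]) {
      stop("bands must be ordered and within [0, 1]", call. = FALSE)
    }
  }
  if (graft_band[2] >= host_band[1] && host_band[2] >= graft_band[1]) {
    stop("graft and host bands must not overlap", call. = FALSE)
  }
  n_undef <- sum(is.na(fractions$host_fraction))
  if (n_undef > 0) {
    message("classify_barcodes: excluding ", n_undef,
            " barcode(s) with zero total reads")
  }
  fractions |>
    dplyr::filter(!is.na(.data$host_fraction)) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$host_fraction >= graft_band[1] & .data$host_fraction <= graft_band[2] ~ "graft",
      .data$host_fraction >= host_band[1] & .data$host_fraction <= host_band[2] ~ "host",
      TRUE ~ "ambiguous"
    ))
}
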
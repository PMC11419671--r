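#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster enrichment result
#'
#' @param x A `trl_enrichment` object from [reactive_cluster_enrichment()].
#' @param ... Unused.
#' @return A plain tibble, one row per cluster, with the estimate columns
#'   renamed to broom conventions: `term` (cluster), `estimate` (observed
#'   reactive frequency), `null.value` (background frequency `p0`),
#'   `p.value`, `adj.p.value`, plus `delta` and `direction`.
#' @method tidy trl_enrichment
#' @export
tidy.trl_enrichment <- function(x, ...) {
  tibble::tibble(
    term = x$cluster,
    estimate = x$x / x$n,
    null.value = x$p0,
    statistic = x$x,
    p.value = x$p_two_sided,
    adj.p.value = x$p_bonf,
    delta = x$delta,
    direction = x$direction
  )
}

#' One-row summary of a cluster enrichment result
#'
#' @param x A `trl_enrichment` object.
#' @param ... Unused.
#' @return Tibble with `n_clusters`, `n_reactive_cells`, `n_til_cells`,
#'   `n_over`, `n_under` (Bonferroni-significant at 0.05 each way), and
#'   `min_adj_p`.
#' @method glance trl_enrichment
#' @export
glance.trl_enrichment <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x),
    n_reactive_cells = attr(x, "n_reactive"),
    n_til_cells = attr(x, "n_til"),
    n_over = sum(x$p_bonf < 0.05 & x$direction == "over"),
    n_under = sum(x$p_bonf < 0.05 & x$direction == "under"),
    min_adj_p = min(x$p_bonf)
  )
}

#' Plot per-cluster enrichment of reactive clonotypes
#'
#' Bar plot of the matching-minus-non-matching frequency difference per
#' cluster, shaded by Bonferroni significance - the standard view of which
#' phenotype clusters the reactive clones concentrate in.
#'
#' @param object A `trl_enrichment` object.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trl_enrichment
#' @export
autoplot.trl_enrichment <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p_bonf < alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$cluster, .data$delta),
    y = .data$delta, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey70"),
                               name = paste0("p_bonf < ", alpha)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "frequency difference (reactive - non-matching)") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster doublet statistics
#'
#' Doublet percentage per cluster with the Fisher-test significance
#' marked; the visual counterpart of [nominate_doublet_clusters()].
#'
#' @param object A `trl_doublet_stats` object from
#'   [cluster_doublet_stats()].
#' @param q_max Significance threshold on the BH-adjusted q-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trl_doublet_stats
#' @export
autoplot.trl_doublet_stats <- function(object, q_max = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$flagged <- df$odds_ratio > 1 & df$q < q_max
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$cluster, .data$pct_doublets),
    y = .data$pct_doublets, fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey70"),
                               name = paste0("OR > 1 & q < ", q_max)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% doublet-flagged cells") +
    ggplot2::theme_minimal()
}

#' Plot category frequencies across clusters
#'
#' Side-by-side cluster composition of each cell category (e.g. TIL
#' background vs reactive cells).
#'
#' @param freqs Output of [category_frequencies()].
#' @return A ggplot object.
#' @export
plot_category_frequencies <- function(freqs) {
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$cluster, y = .data$frequency,
                                      fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of category cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
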
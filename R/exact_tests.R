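# Relative tolerance of the minimum-likelihood two-sided rule: an outcome
# is counted as "at most as likely as observed" when its pmf is <= the
# observed pmf times (1 + REL_TOL). This mirrors the classical exact-test
# convention so p-values are comparable with standard software.
REL_TOL <- 1e-7

#' Two-sided exact binomial test
#'
#' Computes the minimum-likelihood two-sided p-value for observing `x`
#' successes in `n` Bernoulli trials with success probability `p0`: the sum
#' of binomial(n, p0) probabilities over all outcomes whose probability
#' mass does not exceed that of `x` (up to a relative tolerance of 1e-7).
#' This is the classical two-sided exact binomial test used for the
#' per-cluster over/under-representation calls.
#'
#' @param x Observed success count, `0 <= x <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in `[0, 1]`.
#' @return The two-sided p-value. When `x` is the mode of the null
#'   distribution the value is 1. Degenerate nulls (`p0` 0 or 1) give the
#'   point-mass answer: 1 when the observation is the certain outcome,
#'   0 otherwise.
#' @examples
#' exact_binomial_test(5, 10, 0.5)   # 1: the mode
#' exact_binomial_test(9, 10, 0.5)   # 22/1024
#' @export
exact_binomial_test <- function(x, n, p0) {
  if (length(x) != 1L || length(n) != 1L || length(p0) != 1L ||
      is.na(x) || is.na(n) || is.na(p0) ||
      x < 0 || n < 0 || x > n || x != round(x) || n != round(n) ||
      p0 < 0 || p0 > 1) {
    stop("exact_binomial_test: need 0 <= x <= n (integers) and p0 in [0, 1]",
         call. = FALSE)
  }
  pmf <- stats::dbinom(0:n, n, p0)
  d <- pmf[x + 1L]
  min(1, sum(pmf[pmf <= d * (1 + REL_TOL)]))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table, conditioning on
#' both margins. The two-sided p-value follows the minimum-likelihood rule
#' over the hypergeometric distribution (all tables with the same margins
#' whose probability does not exceed the observed table's, up to a relative
#' tolerance of 1e-7). The reported odds ratio is the sample odds ratio
#' `(a*d)/(b*c)` - not the conditional MLE - with `Inf` when `b*c == 0` and
#' `a*d > 0`, and `NaN` for the degenerate all-margin-zero cases.
#'
#' @param table A 2x2 matrix of nonnegative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return A list with elements `odds_ratio` and `p`.
#' @examples
#' fisher_exact_2x2(rbind(c(1, 1), c(1, 1)))  # OR 1, p 1
#' fisher_exact_2x2(rbind(c(0, 5), c(5, 0)))  # p = 2/252
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    stop("fisher_exact_2x2: need a 2x2 matrix", call. = FALSE)
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    stop("fisher_exact_2x2: entries must be nonnegative integers", call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)

  m <- a + b          # row-1 margin ("white balls")
  n2 <- cc + d        # row-2 margin
  k <- a + cc         # column-1 margin (draws)
  if (m + n2 == 0) return(list(odds_ratio = or, p = 1))
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  pmf <- stats::dhyper(support, m, n2, k)
  d_obs <- pmf[match(a, support)]
  p <- min(1, sum(pmf[pmf <= d_obs * (1 + REL_TOL)]))
  list(odds_ratio = or, p = p)
}

#' Bonferroni family-wise multiple-testing adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1 (delegates
#' to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("bonferroni: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}
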
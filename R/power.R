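#' Paired Cohen's d
#'
#' Effect size for a paired design: the mean within-pair difference divided
#' by the sample standard deviation (n-1 denominator) of those differences.
#' Interpretation bands (small/medium/large at 0.2/0.5/0.8 in absolute
#' value) are attached as an attribute.
#'
#' @param flash,placebo Paired measurements (same participants, same
#'   order), or pass precomputed differences via `diffs`.
#' @param diffs Optional vector of within-pair differences (overrides
#'   `flash`/`placebo`).
#' @return Cohen's d with attribute `interpretation`.
#' @export
#' @examples
#' cohens_d_paired(diffs = c(2, 4))  # 3 / sqrt(2)
cohens_d_paired <- function(flash = NULL, placebo = NULL, diffs = NULL) {
  if (is.null(diffs)) {
    if (is.null(flash) || is.null(placebo))
      stop("provide flash and placebo vectors, or diffs")
    if (length(flash) != length(placebo))
      stop("flash and placebo must be paired (equal length)")
    diffs <- flash - placebo
  }
  if (length(diffs) < 2) stop("need at least two pairs")
  s <- sd(diffs)
  if (!is.finite(s) || s == 0)
    stop("zero standard deviation of differences; d undefined")
  d <- mean(diffs) / s
  interp <- if (abs(d) >= 0.8) "large" else if (abs(d) >= 0.5) "medium"
            else if (abs(d) >= 0.2) "small" else "negligible"
  attr(d, "interpretation") <- interp
  d
}

#' Bonferroni-corrected per-test threshold
#'
#' @param family_alpha Family-wise significance level.
#' @param m Number of comparisons (>= 1).
#' @param digits Optional rounding for reporting (e.g. 3 gives 0.007 for
#'   0.05/7); NULL returns the exact quotient.
#' @return Per-test alpha.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 7, digits = 3)  # 0.007
bonferroni_alpha <- function(family_alpha, m, digits = NULL) {
  if (m < 1) stop("m must be >= 1")
  a <- family_alpha / m
  if (!is.null(digits)) a <- round(a, digits)
  a
}

#' Power of a two-sided paired t-test
#'
#' Exact power via the noncentral t distribution:
#' `P(|T'| > t_crit)` with `T'` noncentral t on `n - 1` degrees of
#' freedom, noncentrality `d * sqrt(n)`, and `t_crit` the two-sided
#' critical value at `alpha`. At `d = 0` this returns `alpha` (the size of
#' the test).
#'
#' @param n Number of pairs (>= 2).
#' @param d Standardized effect size (mean difference / SD of differences).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_paired_t(4, 2.77)  # > 0.8
power_paired_t <- function(n, d, alpha = 0.05) {
  if (n < 2) stop("n must be >= 2")
  df <- n - 1
  ncp <- d * sqrt(n)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp)
}

#' Minimal detectable mean difference for a paired t-test
#'
#' The smallest absolute true mean difference for which a two-sided paired
#' t-test at `alpha` reaches the target power, given the SD of the paired
#' differences and the number of pairs. Solved by root-finding on the
#' noncentral-t power function; the result is linear in `sd_diff`.
#'
#' @param sd_diff SD of the within-pair differences (any units).
#' @param n Number of pairs (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Minimal detectable difference, in the units of `sd_diff`.
#' @export
#' @examples
#' mdd_paired_t(3.2, 6)  # ~4.59 min for the wake-duration design
mdd_paired_t <- function(sd_diff, n, alpha = 0.05, power = 0.80) {
  if (n < 2) stop("n must be >= 2")
  if (sd_diff < 0) stop("sd_diff must be >= 0")
  if (power <= alpha || power >= 1)
    stop("target power must lie in (alpha, 1)")
  if (sd_diff == 0) return(0)
  f <- function(d) power_paired_t(n, d, alpha) - power
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e6) stop("infeasible power specification")
  }
  d <- uniroot(f, c(1e-12, upper), tol = 1e-10)$root
  d * sd_diff
}

#' Smallest sample size reaching target power for a paired t-test
#'
#' The smallest integer `n >= 2` with `power_paired_t(n, d, alpha) >=
#' power`, stepping the exact noncentral-t power function.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param n_max Safety cap on the search (default 1e6).
#' @return Required number of pairs.
#' @export
#' @examples
#' n_required_paired_t(2.77)  # 4
n_required_paired_t <- function(d, alpha = 0.05, power = 0.80, n_max = 1e6) {
  if (d <= 0) stop("effect size d must be > 0")
  n <- 2
  while (power_paired_t(n, d, alpha) < power) {
    n <- n + 1
    if (n > n_max) stop("no n <= n_max reaches the target power")
  }
  n
}
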
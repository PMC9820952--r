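#' Mean, SD and 95% confidence interval of a series
#'
#' The CI of the mean uses the t multiplier:
#' `mean +- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param x numeric vector, `n >= 2`.
#' @return List with `mean`, `sd`, `ci` (length-2), `n`.
#' @export
summarize_series <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  m <- mean(x); s <- sd(x)
  half <- qt(0.975, n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci = c(m - half, m + half), n = n)
}

#' Limits of agreement from a mean difference and its SD
#'
#' The Bland-Altman 95% limits: `mean_diff +- 1.96 * sd_diff`.
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff SD of the paired differences (n-1 denominator).
#' @return Numeric length-2: lower and upper limit.
#' @export
agreement_limits <- function(mean_diff, sd_diff) {
  c(mean_diff - 1.96 * sd_diff, mean_diff + 1.96 * sd_diff)
}

#' Bland-Altman agreement analysis of paired measurements
#'
#' Differences `d = x - y`; limits of agreement are
#' `mean(d) +- 1.96 * SD(d)` (SD with the n-1 denominator), the interval
#' expected to contain 95% of the differences.  Also reports the fraction
#' of pairs falling outside the limits and the paired t-test (NA when the
#' differences are constant).
#'
#' @param x,y paired numeric series of equal length `n >= 2`.
#' @return List of class `mm_agreement` with `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `frac_outside`, `t`, `p`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("paired series must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- sd(d)
  lim <- agreement_limits(m, s)
  lower <- lim[1]; upper <- lim[2]
  tt <- if (s > 0) paired_t(x, y) else list(t = NA_real_, p = NA_real_)
  structure(list(mean_diff = m, sd_diff = s, lower = lower, upper = upper,
                 frac_outside = mean(d < lower | d > upper),
                 t = tt$t, p = tt$p, n = n),
            class = "mm_agreement")
}

#' Paired t-test
#'
#' `t = mean(d) / (SD(d)/sqrt(n))` with `d = x - y`; two-sided p-value from
#' the t distribution with `n - 1` degrees of freedom.
#'
#' @param x,y paired numeric series, `n >= 2`, non-constant differences.
#' @return List with `t`, `p`, `df`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired series must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  s <- sd(d)
  if (s == 0) stop("degenerate paired series: zero-variance differences")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), df = n - 1, n = n)
}
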
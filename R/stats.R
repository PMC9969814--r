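# Statistical layer: paired t, Cohen's d with pooled SD, effect-size
# classification, one-way ANOVA and Bland-Altman agreement. The formulas
# are coded directly (they are part of the analysis contract); base-R
# t.test/aov serve as independent cross-checks in the test suite.

#' Paired t test from a vector of paired differences
#'
#' `t = mean(d) * sqrt(n) / sd(d)` with the sample SD (n-1 denominator)
#' and a two-tailed p value on n-1 degrees of freedom. Zero-variance
#' differences make the statistic undefined; it is reported as `NA` with a
#' note rather than as an infinity.
#'
#' @param differences numeric vector of paired differences, length >= 2.
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`, `sd_diff`,
#'   `n`, and `note` (`NA` unless degenerate).
#' @examples
#' paired_t(c(1, 2, 3))  # t = 2 * sqrt(3) / 1
#' @export
paired_t <- function(differences) {
  n <- length(differences)
  if (n < 2) stopf("need at least 2 paired differences")
  mu <- mean(differences)
  sigma <- sd(differences)
  if (sigma == 0) {
    return(list(statistic = NA_real_, df = n - 1L, p_value = NA_real_,
                mean_diff = mu, sd_diff = 0, n = n,
                note = "zero-variance differences: t undefined"))
  }
  t_stat <- mu * sqrt(n) / sigma
  list(statistic = t_stat, df = n - 1L,
       p_value = 2 * pt(-abs(t_stat), df = n - 1),
       mean_diff = mu, sd_diff = sigma, n = n, note = NA_character_)
}

#' Cohen's d with pooled standard deviation
#'
#' `sigma_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))` and
#' `d = |mu1 - mu2| / sigma_pooled`. The absolute value is reported, so
#' the measure is symmetric in group order; direction, if needed, lives in
#' the sign of the mean difference.
#'
#' @param mu1,sd1,n1 mean, SD and size of group 1 (`n1 >= 2`).
#' @param mu2,sd2,n2 mean, SD and size of group 2 (`n2 >= 2`).
#' @return list with `d`, `sigma_pooled` and `effect_class` (see
#'   [classify_effect()]).
#' @examples
#' cohens_d(70, 9.6, 19, 80.6, 12.2, 19)$d    # ~0.97
#' cohens_d(286.9, 20.9, 19, 272, 20.4, 19)$d # ~0.72
#' @export
cohens_d <- function(mu1, sd1, n1, mu2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stopf("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stopf("both SDs are zero: d undefined")
  sigma_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) /
                         (n1 + n2 - 2))
  d <- abs(mu1 - mu2) / sigma_pooled
  list(d = d, sigma_pooled = sigma_pooled, effect_class = classify_effect(d))
}

#' Classify an effect size
#'
#' Conventional Cohen bands: small for `d < 0.2`, medium for
#' `0.2 <= d < 0.5`, large for `0.5 <= d < 0.8`, very large for
#' `d >= 0.8` (values falling exactly on a boundary take the higher
#' class).
#'
#' @param d nonnegative effect size (use [cohens_d()], which reports the
#'   absolute value).
#' @return one of `"small"`, `"medium"`, `"large"`, `"very large"`.
#' @export
classify_effect <- function(d) {
  if (!is_scalar_num(d) || d < 0) {
    stopf("`d` must be a nonnegative number (take the absolute value)")
  }
  if (d < 0.2) "small"
  else if (d < 0.5) "medium"
  else if (d < 0.8) "large"
  else "very large"
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with `k - 1` and `N - k` degrees of
#' freedom and a p value from the F distribution. When every group mean
#' coincides the statistic is 0 (including the fully degenerate all-equal
#' case).
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `statistic` (F), `df` (c(between, within)),
#'   `p_value`, `ms_between`, `ms_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2) stopf("need at least 2 groups")
  if (any(lengths(groups) < 2)) stopf("every group needs n >= 2")
  ns <- lengths(groups)
  N <- sum(ns)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- c(k - 1L, N - k)
  ms_between <- ssb / df[1]
  ms_within <- ssw / df[2]
  f_stat <- if (ssb == 0) 0 else ms_between / ms_within
  list(statistic = f_stat, df = df,
       p_value = pf(f_stat, df[1], df[2], lower.tail = FALSE),
       ms_between = ms_between, ms_within = ms_within)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements `a` and `b`, computes the differences
#' `d_i = a_i - b_i`, their mean (the bias) and the limits of agreement
#' `bias +/- 1.96 * SD(d)`, together with the per-pair means used as the
#' x axis of a Bland-Altman plot.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `bias`, `loa_lower`, `loa_upper`, `sd_diff`,
#'   `differences`, `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  if (length(a) < 2) stopf("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s, differences = d, means = (a + b) / 2)
}
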
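#' Hypergeometric complementary cumulative tail probability
#'
#' Upper tail `P(X > k)` for `X ~ Hypergeometric(N, K, d)`: the probability of
#' observing strictly more than `k` successes in `d` draws without replacement
#' from a population of `N` containing `K` successes. Used per categorical
#' boundary, with `K = d` and `k` the intersection count from
#' [boundary_counts()], as the boundary's association P value.
#'
#' The summation runs over the support `max(0, K + d - N) .. min(K, d)`;
#' out-of-support terms are zero, so `k >= min(K, d)` gives 0 and `k` below
#' the support minimum gives 1. Terms accumulate as exponentials of log-gamma
#' binomials, summed over the upper tail directly, so small tails keep full
#' relative precision and population sizes in the thousands do not overflow.
#'
#' @param N Population size.
#' @param K Total possible successes in the population, `0 <= K <= N`.
#' @param d Number of draws, `0 <= d <= N`.
#' @param k Observed success count, `0 <= k <= d`.
#' @return The tail probability, a single numeric in `[0, 1]`.
#' @examples
#' hccdf_tail(20, 14, 14, 10)  # 0.2252322
#' hccdf_tail(20, 8, 8, 5)     # 0.0154402
#' hccdf_tail(20, 8, 8, 8)     # 0: the full CDF sums to 1
#' @export
hccdf_tail <- function(N, K, d, k) {
  if (length(N) != 1L || length(K) != 1L || length(d) != 1L || length(k) != 1L ||
      anyNA(c(N, K, d, k)) ||
      any(c(N, K, d, k) != floor(c(N, K, d, k))) ||
      k < 0 || k > d || d > N || K < 0 || K > N)
    err_invalid_counts(
      "require integers with 0 <= k <= d <= N and 0 <= K <= N")
  lo <- max(0, K + d - N)
  hi <- min(K, d)
  if (k >= hi) return(0)
  if (k < lo) return(1)
  i <- seq.int(k + 1, hi)
  lp <- lchoose(K, i) + lchoose(N - K, d - i) - lchoose(N, d)
  min(1, sum(exp(lp)))
}

# geometric mean with the exact-zero limit preserved: any zero factor makes
# the product zero, otherwise computed in log space
geometric_mean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' HH-CCDF marker-trait association P value
#'
#' The hierarchical hypergeometric complementary cumulative distribution
#' function: the marker's genotype classes are stratified in ascending order
#' of class phenotype mean, each of the `n - 1` categorical boundaries yields
#' a hypergeometric upper-tail P value ([hccdf_tail()] at that boundary's
#' counts), and the per-boundary tails are combined by geometric mean. The
#' geometric mean is taken in log space; if any boundary attains a perfect
#' split (`k = d`, tail 0) the result is exactly 0.
#'
#' @inheritParams stratify
#' @param details If `TRUE`, return a list with the per-boundary counts and
#'   tail factors alongside the combined P value.
#' @return The combined P value in `[0, 1]`, or (with `details = TRUE`) a list
#'   with elements `p`, `counts`, `tails`.
#' @examples
#' ph <- phenotype_vector(paste0("i", 1:6), c(1, 2, 3, 10, 11, 12))
#' mk <- marker_genotypes(paste0("i", 1:6), c(0, 0, 0, 1, 1, 1))
#' hh_ccdf(ph, mk)  # perfect split: 0
#' @export
hh_ccdf <- function(pheno, geno, details = FALSE) {
  strat <- stratify(pheno, geno)
  cnt <- boundary_counts(strat)
  tails <- mapply(hccdf_tail, cnt$N, cnt$K, cnt$d, cnt$k)
  p <- geometric_mean(tails)
  if (details) list(p = p, counts = cnt, tails = tails, strat = strat) else p
}

#' Hierarchical association coefficient
#'
#' A `[0, 1]` association measure built from per-boundary subset sums. With
#' `y` the sum of all trait values and `f(t) = y * log(t) - t`, each boundary
#' contributes the ratio `(f(obs) - f(btm)) / (f(top) - f(btm))`, where `obs`,
#' `top`, `btm` are the right-subset sums under the observed, top and bottom
#' categorizations; the coefficient is the geometric mean of the `n - 1`
#' ratios. It is 1 when the observed categorization is the top categorization
#' and 0 when it is the bottom categorization. All trait values must be
#' strictly positive (min-max normalize first via [normalize_minmax()] if
#' they are not).
#'
#' @inheritParams stratify
#' @param details If `TRUE`, return the per-boundary ratios too.
#' @return The coefficient, or a list with `value`, `ratios`, `sums`.
#' @export
ha_coefficient <- function(pheno, geno, details = FALSE) {
  ha_strat(stratify(pheno, geno), details)
}

# HA coefficient from an existing stratification (scan-layer fast path)
ha_strat <- function(strat, details = FALSE) {
  if (any(strat$values <= 0))
    err_non_positive(
      "hierarchical association coefficient requires strictly positive trait values")
  ha_from_sums(boundary_sums(strat), details)
}

#' Hierarchical association coefficient from per-boundary sums
#'
#' Evaluates the coefficient from a [boundary_sums()] table: with
#' `f(t) = y * log(t) - t`, each boundary contributes
#' `(f(obs) - f(btm)) / (f(top) - f(btm))` and the coefficient is the
#' geometric mean of the ratios. Exposed separately so the analytic
#' endpoints are directly checkable: `obs = top` everywhere gives 1,
#' `obs = btm` everywhere gives 0. All sums must be strictly positive.
#'
#' @param sums Data frame with columns `y`, `obs`, `top`, `btm` (one row per
#'   boundary).
#' @param details If `TRUE`, also return the per-boundary ratios.
#' @return The coefficient, or a list with `value`, `ratios`, `sums`.
#' @export
ha_from_sums <- function(sums, details = FALSE) {
  stopifnot(all(c("y", "obs", "top", "btm") %in% names(sums)))
  if (any(sums$obs <= 0) || any(sums$top <= 0) || any(sums$btm <= 0))
    err_non_positive("subset sums must be strictly positive")
  if (any(sums$top == sums$btm))
    err_degenerate_spread("top and bottom subset sums coincide at a boundary")
  f <- function(t) sums$y[1] * log(t) - t
  ratios <- (f(sums$obs) - f(sums$btm)) / (f(sums$top) - f(sums$btm))
  # guard tiny negative rounding when obs ~ btm
  ratios <- pmin(1, pmax(0, ratios))
  value <- geometric_mean(ratios)
  if (details) list(value = value, ratios = ratios, sums = sums) else value
}

#' One-way fixed-effects F test of class mean differences
#'
#' The classical one-way ANOVA of trait value on genotype class,
#' `y_ij = mu + alpha_i + e_ij`, fitted via [stats::lm()] with the class label
#' as a factor; the P value is the exact upper tail of the F distribution.
#'
#' @inheritParams stratify
#' @return A list of class `hh_anova`: `ss_between`, `ss_within`,
#'   `df_between`, `df_within`, `F`, `p`, `grand_mean`, `group_effects`.
#' @export
f_test <- function(pheno, geno) {
  f_test_strat(stratify(pheno, geno))
}

# one-way ANOVA from an existing stratification (scan-layer fast path)
f_test_strat <- function(strat) {
  if (strat$n < 2L)
    err_degenerate_marker("single genotype class; F test undefined")
  if (strat$N - strat$n < 1L)
    err_degenerate_marker("no residual degrees of freedom")
  if (stats::var(strat$values) == 0)
    err_degenerate_spread("constant phenotype: F statistic undefined")
  lab <- factor(rep(vapply(strat$groups, `[[`, character(1), "label"),
                    vapply(strat$groups, `[[`, integer(1), "size")))
  fit <- stats::lm(strat$values ~ lab)
  an <- stats::anova(fit)
  gm <- mean(strat$values)
  means <- vapply(strat$groups, `[[`, numeric(1), "mean")
  structure(list(
    ss_between = an$`Sum Sq`[1], ss_within = an$`Sum Sq`[2],
    df_between = an$Df[1], df_within = an$Df[2],
    F = an$`F value`[1], p = an$`Pr(>F)`[1],
    grand_mean = gm,
    group_effects = stats::setNames(means - gm,
                                    vapply(strat$groups, `[[`, character(1),
                                           "label"))
  ), class = "hh_anova")
}

#' @export
print.hh_anova <- function(x, ...) {
  cat(sprintf("One-way F test: F(%d, %d) = %.4f, p = %.6g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Min-max normalization onto [0, 1]
#'
#' Affine rescaling `z_i = (x_i - min(x)) / (max(x) - min(x))`: the minimum
#' maps to 0, the maximum to 1, order is preserved. `NA` entries are left
#' `NA` and ignored when locating the extremes.
#'
#' @param values Numeric vector with at least 2 finite values and positive
#'   spread.
#' @return Numeric vector of the same length in `[0, 1]` (NAs preserved).
#' @examples
#' normalize_minmax(c(-2, 0, 2))  # 0.0 0.5 1.0
#' @export
normalize_minmax <- function(values) {
  obs <- values[is.finite(values)]
  if (length(obs) < 2L)
    err_degenerate_spread("need at least 2 finite values to normalize")
  lo <- min(obs); hi <- max(obs)
  if (hi == lo)
    err_degenerate_spread("constant input: min-max normalization undefined")
  (values - lo) / (hi - lo)
}
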
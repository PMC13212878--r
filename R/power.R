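#' Power of a two-sided paired t-test (noncentral t)
#'
#' Exact power of the two-sided paired t-test: with noncentrality
#' `ncp = (delta / sigma) * sqrt(n)` and `df = n - 1`, power is
#' `P(|T'| > t_{1 - alpha/2, df})` under the noncentral t, counting both
#' rejection tails.
#'
#' @param n paired sample size (>= 2).
#' @param delta true mean paired difference (log2 fold change).
#' @param sigma within-subject SD of the paired differences (log2 units).
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
paired_t_power <- function(n, delta, sigma = 0.45, alpha = 0.05) {
  if (any(n < 2)) stop("paired_t_power: n must be >= 2")
  stopifnot(sigma > 0, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- (delta / sigma) * sqrt(n)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp = ncp) + pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
}

#' Bonferroni-adjusted per-test alpha
#'
#' @param m number of tests (>= 1).
#' @param family_alpha family-wise error rate (default 0.05).
#' @return `family_alpha / m`.
#' @export
bonferroni_alpha <- function(m, family_alpha = 0.05) {
  if (any(m < 1)) stop("bonferroni_alpha: m must be >= 1")
  family_alpha / m
}

#' Effective per-test alpha under Benjamini-Hochberg
#'
#' The BH step-up threshold at rank `k`: a test rejected at rank `k` of `m`
#' faces the per-test threshold `(k / m) * q`. With an expected number of
#' discoveries `k_expected`, this is the realistic post-correction alpha.
#'
#' @param m number of tests.
#' @param k_expected expected number of discoveries (`1 <= k_expected <= m`).
#' @param fdr_q FDR level (default 0.05).
#' @return effective alpha.
#' @export
bh_effective_alpha <- function(m, k_expected, fdr_q = 0.05) {
  if (any(k_expected < 1)) stop("bh_effective_alpha: k_expected must be >= 1")
  if (any(k_expected > m)) stop("bh_effective_alpha: k_expected must be <= m")
  (k_expected / m) * fdr_q
}

#' Linear fold change of a log2 effect size
#'
#' @param delta log2 fold change.
#' @return `2^delta`.
#' @export
fold_change_of_delta <- function(delta) 2^delta

#' Power table over cohorts, effect sizes, and alpha variants
#'
#' One row per (cohort, delta, alpha variant), with variants: nominal alpha,
#' BH-effective alpha (`(k_expected / m) * fdr_q`), and Bonferroni
#' (`family_alpha / m`).
#'
#' @param cohorts named integer vector of paired sample sizes (defaults to
#'   the three study cohorts: head & neck 11, bladder 22, prostate 26).
#' @param deltas grid of log2 effect sizes.
#' @param sigma within-subject SD.
#' @param alpha nominal (and family-wise) significance level.
#' @param m number of simultaneous tests.
#' @param k_expected expected discoveries for the BH-effective threshold.
#' @param fdr_q FDR level for the BH-effective threshold.
#' @return data.frame: `cohort`, `n`, `delta`, `fold_change`, `alpha_variant`,
#'   `alpha_value`, `power`.
#' @export
power_table <- function(cohorts = c(head_neck = 11, bladder = 22, prostate = 26),
                        deltas = c(0.4, 0.7, 1.0), sigma = 0.45, alpha = 0.05,
                        m = 500, k_expected = 30, fdr_q = 0.05) {
  variants <- c(nominal = alpha,
                bh_eff = bh_effective_alpha(m, k_expected, fdr_q),
                bonferroni = bonferroni_alpha(m, alpha))
  grid <- expand.grid(cohort = names(cohorts), delta = deltas,
                      alpha_variant = names(variants),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- cohorts[grid$cohort]
  grid$fold_change <- fold_change_of_delta(grid$delta)
  grid$alpha_value <- variants[grid$alpha_variant]
  grid$power <- paired_t_power(grid$n, grid$delta, sigma, grid$alpha_value)
  grid[, c("cohort", "n", "delta", "fold_change", "alpha_variant",
           "alpha_value", "power")]
}
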
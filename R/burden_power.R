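#' Burden-test design
#'
#' A balanced case-control design for a burden test on a set of `k` SNPs of
#' which `k1` carry a common odds ratio. The MAF factor is the spectrum term
#' of the non-centrality parameter, E_M / sqrt(E\[M(1-M)\]); it can be given
#' as a scalar or derived from a [maf_spectrum()].
#'
#' @param n_per_arm Cases (= controls) per arm, `>= 1`.
#' @param k SNP-set size, `>= 1`.
#' @param k1 Number of associated SNPs, `1 <= k1 <= k`.
#' @param odds_ratio Common odds ratio `gamma > 0` of the associated SNPs.
#' @param maf_factor Positive scalar, or a `maf_spectrum` from which the
#'   factor is computed.
#' @param alpha Significance level in (0, 1).
#' @param sided `"one"` (normal test, default) or `"two"` (chi-square).
#' @return An object of class `burden_design`.
#' @examples
#' d <- burden_design(5000, 100, 10, 3, maf_factor = 0.046)
#' burden_ncp(d)                       # ~6.5
#' power_from_ncp(burden_ncp(d), 5e-8) # ~0.87
#' @export
burden_design <- function(n_per_arm, k, k1, odds_ratio, maf_factor,
                          alpha = 5e-8, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (inherits(maf_factor, "maf_spectrum"))
    maf_factor <- spectrum_moments(maf_factor)$maf_factor
  stopifnot(n_per_arm >= 1, k >= 1, k1 >= 1, k1 <= k,
            odds_ratio > 0, is.numeric(maf_factor), maf_factor > 0,
            alpha > 0, alpha < 1)
  structure(list(n_per_arm = n_per_arm, k = k, k1 = k1,
                 odds_ratio = odds_ratio, maf_factor = maf_factor,
                 alpha = alpha, sided = sided),
            class = "burden_design")
}

#' Burden-test non-centrality parameter
#'
#' The Z-scale non-centrality parameter of a burden test,
#' \deqn{NCP = \sqrt{n}\,\frac{k_1}{\sqrt{k}}\,
#'   \frac{E_M}{\sqrt{E[M(1-M)]}}\,(\gamma - 1),}
#' with `n` cases and `n` controls, a set of `k` SNPs of which `k1` carry a
#' common odds ratio `gamma`, and the MAF factor of the ascertained
#' spectrum. Its four factors isolate the design levers: sample size
#' (quadrupling `n` doubles the NCP), signal sparsity `k1/sqrt(k)`, the MAF
#' spectrum, and the effect size (linear in `gamma - 1`).
#'
#' @param design A [burden_design()].
#' @return Non-negative scalar (0 when `gamma = 1`).
#' @export
burden_ncp <- function(design) {
  stopifnot(inherits(design, "burden_design"))
  with(design,
       sqrt(n_per_arm) * (k1 / sqrt(k)) * maf_factor * (odds_ratio - 1))
}

#' Power at a given non-centrality parameter
#'
#' One-sided: `pnorm(ncp - qnorm(1 - alpha))`. Two-sided: upper tail of a
#' noncentral chi-square with 1 df and noncentrality `ncp^2` beyond the
#' two-sided chi-square critical value.
#'
#' @param ncp Non-negative Z-scale non-centrality parameter.
#' @param alpha Significance level in (0, 1).
#' @param sided `"one"` or `"two"`.
#' @return Rejection probability.
#' @export
power_from_ncp <- function(ncp, alpha, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(is.numeric(ncp), all(ncp >= 0), alpha > 0, alpha < 1)
  if (sided == "one") {
    stats::pnorm(ncp - stats::qnorm(alpha, lower.tail = FALSE))
  } else {
    stats::pchisq(stats::qchisq(alpha, df = 1, lower.tail = FALSE),
                  df = 1, ncp = ncp^2, lower.tail = FALSE)
  }
}

#' Analytic burden power for a design
#'
#' @param design A [burden_design()].
#' @return List with `ncp` and `power`.
#' @export
burden_power <- function(design) {
  ncp <- burden_ncp(design)
  list(ncp = ncp,
       power = power_from_ncp(ncp, design$alpha, design$sided))
}

#' Smallest per-arm sample size reaching a target power
#'
#' Inverts the NCP/power relation: a closed-form normal-approximation seed
#' \eqn{n_0 = ((z_{1-\alpha} + z_{power}) / ((k_1/\sqrt{k})\, f\, (\gamma-1)))^2}
#' is refined to the smallest integer `n` whose power meets the target.
#'
#' @param k,k1,odds_ratio,maf_factor,alpha,sided As in [burden_design()];
#'   `odds_ratio` must differ from 1.
#' @param target_power Desired power in `(alpha, 1)`.
#' @return Integer cases per arm.
#' @export
sample_size_for_power <- function(k, k1, odds_ratio, maf_factor,
                                  target_power = 0.8, alpha = 1e-6,
                                  sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (inherits(maf_factor, "maf_spectrum"))
    maf_factor <- spectrum_moments(maf_factor)$maf_factor
  stopifnot(odds_ratio > 0, target_power > alpha, target_power < 1)
  if (odds_ratio == 1) stop("odds_ratio = 1: target power is unreachable")
  slope <- (k1 / sqrt(k)) * maf_factor * abs(odds_ratio - 1)
  n0 <- ((stats::qnorm(alpha, lower.tail = FALSE) +
            stats::qnorm(target_power)) / slope)^2
  n <- max(1L, as.integer(ceiling(n0)))
  pow <- function(n)
    power_from_ncp(sqrt(n) * slope, alpha, sided)
  while (pow(n) < target_power) n <- n + 1L
  while (n > 1L && pow(n - 1L) >= target_power) n <- n - 1L
  n
}

#' Sample-size curves against signal sparsity
#'
#' For each (sparsity, odds ratio) pair, the per-arm sample size needed to
#' reach the target power, with `k1 = round(k * sparsity)`.
#'
#' @param k SNP-set size.
#' @param odds_ratios Vector of odds ratios (each != 1).
#' @param maf_factor Scalar or `maf_spectrum`.
#' @param target_power,alpha,sided Passed to [sample_size_for_power()].
#' @param sparsity_grid Values of `k1/k` in (0, 1].
#' @return data.frame with columns `sparsity`, `odds_ratio`, `k1`,
#'   `n_per_arm`.
#' @export
sparsity_curve <- function(k = 100, odds_ratios = c(1.5, 2, 3, 5),
                           maf_factor = maf_spectrum(),
                           target_power = 0.8, alpha = 1e-6,
                           sparsity_grid = seq(0.05, 1, by = 0.05),
                           sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (length(sparsity_grid) == 0L) stop("empty sparsity grid")
  stopifnot(all(sparsity_grid > 0), all(sparsity_grid <= 1))
  if (inherits(maf_factor, "maf_spectrum"))
    maf_factor <- spectrum_moments(maf_factor)$maf_factor
  grid <- expand.grid(sparsity = sparsity_grid, odds_ratio = odds_ratios,
                      KEEP.OUT.ATTRS = FALSE)
  grid$k1 <- pmax(1L, as.integer(round(k * grid$sparsity)))
  grid$n_per_arm <- vapply(seq_len(nrow(grid)), function(i)
    sample_size_for_power(k, grid$k1[i], grid$odds_ratio[i], maf_factor,
                          target_power, alpha, sided),
    integer(1))
  grid
}

#' Effect-size algebra of phenotype stratification
#'
#' When only a fraction `alpha_s` of cases is etiologically relevant to the
#' SNP set (mean odds ratio `gamma_t` in the most at-risk stratum, the rest
#' behaving like controls), the full case set shows the diluted MAF
#' `alpha_s * p * gamma_t + (1 - alpha_s) * p` and the diluted effect
#' `gamma - 1 = alpha_s * (gamma_t - 1)`. Restricting the analysis to the
#' `alpha_s * n` relevant cases multiplies the NCP by `1 / sqrt(alpha_s)`.
#'
#' @param relevant_fraction `alpha_s` in (0, 1].
#' @param gamma_t Mean odds ratio in the relevant stratum, `> 1`.
#' @param control_maf Control MAF `p` in (0, 0.5).
#' @return List with `effective_gamma_minus_1`, `full_case_maf`,
#'   `ncp_gain_refined`.
#' @export
stratified_effect <- function(relevant_fraction, gamma_t, control_maf) {
  stopifnot(relevant_fraction > 0, relevant_fraction <= 1, gamma_t > 1,
            control_maf > 0, control_maf < 0.5)
  list(effective_gamma_minus_1 = relevant_fraction * (gamma_t - 1),
       full_case_maf = relevant_fraction * control_maf * gamma_t +
         (1 - relevant_fraction) * control_maf,
       ncp_gain_refined = 1 / sqrt(relevant_fraction))
}

#' Monte-Carlo check of the analytic burden power
#'
#' Simulates per-individual burden scores (sums of per-SNP allele counts)
#' under a logistic disease model and applies the two-sample burden Z-test.
#' Causal SNPs use the exact case/control allele frequencies from
#' [case_control_freqs()]; null SNPs use the population frequency in both
#' arms. Because the analytic NCP uses the rare-variant approximation
#' `p_case - p_ctrl ~ p (gamma - 1)` while the simulation uses exact model
#' frequencies, the comparison also bounds the approximation error.
#'
#' @param design A [burden_design()].
#' @param maf Population MAF shared by the SNPs (scalar), a length-`k`
#'   vector, or a [maf_spectrum()] to draw from.
#' @param prevalence Disease prevalence for the logistic model.
#' @param reps Number of simulated studies, `>= 100`.
#' @param seed Optional integer seed.
#' @return List with `empirical_power` and its binomial `mc_se`.
#' @export
simulate_burden_power <- function(design, maf, prevalence = 0.01,
                                  reps = 2000, seed = NULL) {
  stopifnot(inherits(design, "burden_design"), reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  k <- design$k; k1 <- design$k1; n <- design$n_per_arm
  if (inherits(maf, "maf_spectrum")) {
    p <- sample_mafs(maf, k)
  } else {
    p <- rep_len(maf, k)
  }
  if (all(p == 0)) stop("degenerate design: all MAFs are zero")
  beta <- log(design$odds_ratio)
  null_p <- p[seq_len(k)][-seq_len(k1)]
  freqs <- case_control_freqs_vec(p[seq_len(k1)], rep(beta, k1), prevalence)
  p_case <- c(freqs$p_case, null_p)
  p_ctrl <- c(freqs$p_ctrl, null_p)
  zcrit <- if (design$sided == "one")
    stats::qnorm(design$alpha, lower.tail = FALSE)
  else stats::qnorm(design$alpha / 2, lower.tail = FALSE)
  # Per-individual burden = sum over SNPs of Binomial(2, p_j). SNPs sharing
  # a frequency collapse into one Binomial(2 m, p) draw, so the common
  # shared-MAF case needs O(1) draws per individual instead of O(k).
  draw_burden <- function(freq_vec) {
    W <- matrix(0L, n, reps)
    for (pf in unique(freq_vec)) {
      m <- sum(freq_vec == pf)
      W <- W + matrix(stats::rbinom(n * reps, 2L * m, pf), n, reps)
    }
    W
  }
  col_var <- function(W) (colSums(W^2) - n * colMeans(W)^2) / (n - 1)
  Wc <- draw_burden(p_case); Wt <- draw_burden(p_ctrl)
  se <- sqrt(col_var(Wc) / n + col_var(Wt) / n)
  z <- ifelse(se > 0, (colMeans(Wc) - colMeans(Wt)) / se, 0)
  phat <- if (design$sided == "one") mean(z > zcrit)
          else mean(abs(z) > zcrit)
  list(empirical_power = phat,
       mc_se = sqrt(phat * (1 - phat) / reps))
}
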
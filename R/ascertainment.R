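#' Solve the logistic intercept for a target prevalence
#'
#' For a single-SNP logistic disease model
#' `P(Y = 1 | g) = plogis(a + lor * g)` with Hardy-Weinberg genotype
#' frequencies `Binomial(2, maf)`, finds the intercept `a` such that the
#' population prevalence equals `prevalence`. The prevalence is strictly
#' increasing in `a`, so the root is unique; it is found by Brent's method
#' on a wide bracket.
#'
#' @param maf Population minor allele frequency in (0, 0.5).
#' @param lor Per-allele log odds-ratio.
#' @param prevalence Target prevalence `K` in (0, 1).
#' @return The intercept `a`.
#' @export
solve_intercept <- function(maf, lor, prevalence) {
  stopifnot(maf > 0, maf < 0.5, is.finite(lor),
            prevalence > 0, prevalence < 1)
  hwe <- stats::dbinom(0:2, 2, maf)
  f <- function(a)
    sum(hwe * stats::plogis(a + lor * (0:2))) - prevalence
  stats::uniroot(f, c(-50 - 2 * abs(lor), 50 + 2 * abs(lor)),
                 tol = 1e-14)$root
}

# Vectorized Newton solve over a vector of lORs (one SNP each, shared maf
# allowed to be a vector too). The prevalence equation is smooth, monotone
# and sigmoid-bounded, so damped Newton from a = logit(K) converges fast.
# Cross-checked against solve_intercept() in the test suite.
solve_intercept_vec <- function(maf, lor, prevalence) {
  n <- max(length(maf), length(lor))
  p <- rep_len(maf, n); b <- rep_len(lor, n)
  h0 <- (1 - p)^2; h1 <- 2 * p * (1 - p); h2 <- p^2
  a <- rep(stats::qlogis(prevalence), n)
  for (it in 1:100) {
    e0 <- stats::plogis(a); e1 <- stats::plogis(a + b)
    e2 <- stats::plogis(a + 2 * b)
    fv <- h0 * e0 + h1 * e1 + h2 * e2 - prevalence
    if (max(abs(fv)) < 1e-13) break
    fp <- h0 * e0 * (1 - e0) + h1 * e1 * (1 - e1) + h2 * e2 * (1 - e2)
    a <- a - pmax(pmin(fv / fp, 10), -10)
  }
  a
}

#' Single-SNP logistic disease model
#'
#' Binds a population MAF, a per-allele log odds-ratio and a disease
#' prevalence, solving the logistic intercept so the model's marginal
#' prevalence matches exactly.
#'
#' @inheritParams solve_intercept
#' @return Object of class `disease_model` with fields `maf`, `lor`,
#'   `prevalence`, `intercept`.
#' @examples
#' m <- disease_model(0.002, 1, 0.05)
#' case_control_freqs(m)
#' discovery_prob(m, n_cases = 100, n_controls = 100)
#' @export
disease_model <- function(maf, lor, prevalence) {
  a <- solve_intercept(maf, lor, prevalence)
  structure(list(maf = maf, lor = lor, prevalence = prevalence,
                 intercept = a),
            class = "disease_model")
}

#' Allele frequencies among cases and controls
#'
#' Exact conditional allele frequencies under the logistic model:
#' `p_case = sum_g g HWE(g) P(Y=1|g) / (2 K)` and
#' `p_ctrl = sum_g g HWE(g) P(Y=0|g) / (2 (1-K))`, with the unaffected
#' (not population) conditional for controls. They satisfy the allele
#' conservation identity `K p_case + (1-K) p_ctrl = maf` exactly.
#'
#' @param model A [disease_model()].
#' @return Named list with `p_case`, `p_ctrl`.
#' @export
case_control_freqs <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  res <- case_control_freqs_vec(model$maf, model$lor, model$prevalence)
  list(p_case = res$p_case, p_ctrl = res$p_ctrl)
}

# Vectorized over (maf, lor); used by the simulators.
case_control_freqs_vec <- function(maf, lor, prevalence) {
  n <- max(length(maf), length(lor))
  p <- rep_len(maf, n); b <- rep_len(lor, n)
  a <- solve_intercept_vec(p, b, prevalence)
  h1 <- 2 * p * (1 - p); h2 <- p^2
  e1 <- stats::plogis(a + b); e2 <- stats::plogis(a + 2 * b)
  list(p_case = (h1 * e1 + 2 * h2 * e2) / (2 * prevalence),
       p_ctrl = (h1 * (1 - e1) + 2 * h2 * (1 - e2)) /
         (2 * (1 - prevalence)),
       intercept = a)
}

#' Probability a SNP is discovered in a case-control study
#'
#' Probability that the minor allele is observed at least once among the
#' `2 n_cases` case chromosomes and `2 n_controls` control chromosomes,
#' sampled at their respective conditional allele frequencies:
#' `1 - (1 - p_case)^(2 n_cases) (1 - p_ctrl)^(2 n_controls)`.
#'
#' @param model A [disease_model()].
#' @param n_cases,n_controls Sample sizes, `>= 1`.
#' @return Probability.
#' @export
discovery_prob <- function(model, n_cases, n_controls) {
  stopifnot(inherits(model, "disease_model"),
            n_cases >= 1, n_controls >= 1)
  f <- case_control_freqs(model)
  1 - (1 - f$p_case)^(2 * n_cases) * (1 - f$p_ctrl)^(2 * n_controls)
}

# Integrate h(beta) * dnorm(beta; mu, sigma) over mu +/- 10 sigma,
# collapsing to a point evaluation when sigma = 0.
.effect_integral <- function(h, mu, sigma) {
  if (sigma == 0) return(h(mu))
  .quad(function(b) h(b) * stats::dnorm(b, mu, sigma),
        mu - 10 * sigma, mu + 10 * sigma, rel.tol = 1e-9)
}

# Observation-pattern probabilities for a given effect beta.
.pattern_probs <- function(maf, beta, prevalence, n_cases, n_controls) {
  f <- case_control_freqs_vec(maf, beta, prevalence)
  mc <- 2 * n_cases; mt <- 2 * n_controls
  none_case <- (1 - f$p_case)^mc
  none_ctrl <- (1 - f$p_ctrl)^mt
  list(
    poly = 1 - none_case * none_ctrl,
    case_only = (1 - none_case) * none_ctrl,
    ctrl_singleton = mt * f$p_ctrl * (1 - f$p_ctrl)^(mt - 1) * none_case)
}

#' Conditional probabilities of special observation patterns
#'
#' For a SNP with random effect `beta ~ N(mu, sigma^2)`, the probabilities
#' -- conditional on the SNP being polymorphic in the study -- of (i)
#' appearing only in cases, (ii) appearing exactly once in controls and
#' never in cases, and (iii) any other polymorphic pattern. Allele counts
#' are Binomial over case and control chromosomes at the model's
#' conditional frequencies; the Gaussian effect is integrated out by
#' quadrature. The three probabilities sum to one.
#'
#' @param maf Population MAF in (0, 0.5).
#' @param mu,sigma Effect distribution parameters (`sigma >= 0`).
#' @param prevalence Disease prevalence in (0, 1).
#' @param n_cases,n_controls Sample sizes.
#' @return List with `case_only`, `control_singleton_no_case`, `other`.
#' @export
datatype_probs <- function(maf, mu, sigma, prevalence,
                           n_cases, n_controls) {
  stopifnot(maf > 0, maf < 0.5, sigma >= 0,
            prevalence > 0, prevalence < 1,
            n_cases >= 1, n_controls >= 1)
  poly <- .effect_integral(function(b)
    .pattern_probs(maf, b, prevalence, n_cases, n_controls)$poly,
    mu, sigma)
  if (poly <= 0) stop("discovery probability underflow: SNP essentially ",
                      "unobservable at these settings")
  case_only <- .effect_integral(function(b)
    .pattern_probs(maf, b, prevalence, n_cases, n_controls)$case_only,
    mu, sigma)
  ctrl_one <- .effect_integral(function(b)
    .pattern_probs(maf, b, prevalence, n_cases, n_controls)$ctrl_singleton,
    mu, sigma)
  list(case_only = case_only / poly,
       control_singleton_no_case = ctrl_one / poly,
       other = 1 - (case_only + ctrl_one) / poly)
}

#' Expected true effect of SNPs sampled into a study
#'
#' The mean true log odds-ratio of SNPs conditional on being observed
#' (polymorphic) in the case-control sample,
#' `E[beta | polymorphic] = Int beta P(poly|beta) phi(beta) db /
#'  Int P(poly|beta) phi(beta) db`. For rare SNPs and a rare disease this
#' exceeds `mu`: discovery favours risk-increasing alleles, leaving a
#' preponderance of protective and small effects unobserved.
#'
#' @inheritParams datatype_probs
#' @return Scalar expected log odds-ratio.
#' @export
expected_sampled_lor <- function(maf, mu, sigma, prevalence,
                                 n_cases, n_controls) {
  stopifnot(maf > 0, maf < 0.5, sigma >= 0,
            prevalence > 0, prevalence < 1)
  if (sigma == 0) return(mu)
  pol <- function(b)
    .pattern_probs(maf, b, prevalence, n_cases, n_controls)$poly
  den <- .effect_integral(pol, mu, sigma)
  if (den < 1e-300) stop("discovery probability underflow: SNP essentially ",
                         "unobservable at these settings")
  num <- .effect_integral(function(b) b * pol(b), mu, sigma)
  num / den
}

#' Discovery-probability grid over MAF and effect size
#'
#' Tabulates [discovery_prob()] over a grid of expected population allele
#' counts (`2 n_controls maf`) and log odds-ratios, the coordinates used to
#' contour discovery probability for a study design.
#'
#' @param prevalence Disease prevalence.
#' @param n_cases,n_controls Sample sizes.
#' @param lor_grid Log odds-ratio values.
#' @param count_grid Expected allele counts `2 n_controls * maf`; converted
#'   to MAF internally.
#' @return data.frame with columns `expected_count`, `lor`,
#'   `discovery_prob`.
#' @export
discovery_grid <- function(prevalence = 0.01, n_cases = 100,
                           n_controls = 100,
                           lor_grid = seq(-2, 2, by = 0.25),
                           count_grid = c(0.25, 0.5, 1, 2, 4, 8)) {
  grid <- expand.grid(expected_count = count_grid, lor = lor_grid,
                      KEEP.OUT.ATTRS = FALSE)
  maf <- grid$expected_count / (2 * n_controls)
  stopifnot(all(maf > 0), all(maf < 0.5))
  f <- case_control_freqs_vec(maf, grid$lor, prevalence)
  grid$discovery_prob <-
    1 - (1 - f$p_case)^(2 * n_cases) * (1 - f$p_ctrl)^(2 * n_controls)
  grid
}

#' Observation-pattern grid over MAF
#'
#' Tabulates [datatype_probs()] and [expected_sampled_lor()] over a grid of
#' expected population allele counts for a Gaussian effect distribution.
#'
#' @inheritParams datatype_probs
#' @param count_grid Expected allele counts `2 n_controls * maf`.
#' @return data.frame with columns `expected_count`, `p_case_only`,
#'   `p_control_singleton`, `p_other`, `expected_lor`.
#' @export
datatype_grid <- function(mu = 0, sigma = 1, prevalence = 0.01,
                          n_cases = 100, n_controls = 100,
                          count_grid = c(0.25, 0.5, 1, 2, 4, 8)) {
  maf <- count_grid / (2 * n_controls)
  stopifnot(all(maf > 0), all(maf < 0.5))
  rows <- lapply(seq_along(maf), function(i) {
    dt <- datatype_probs(maf[i], mu, sigma, prevalence,
                         n_cases, n_controls)
    data.frame(expected_count = count_grid[i],
               p_case_only = dt$case_only,
               p_control_singleton = dt$control_singleton_no_case,
               p_other = dt$other,
               expected_lor = expected_sampled_lor(
                 maf[i], mu, sigma, prevalence, n_cases, n_controls))
  })
  do.call(rbind, rows)
}
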
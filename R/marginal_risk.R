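#' Gaussian random-effect disease risk model
#'
#' Risk model for carrying rare alleles whose per-allele log odds-ratios are
#' not known individually but drawn from a Gaussian population with mean
#' `mu` and standard deviation `sigma`. Marginalizing the Gaussian effect
#' out of a logistic model uses the classical logit-probit scaling constant
#' `nu`: the marginal logit for a carrier of `g` alleles is approximately
#' \deqn{\frac{-c + \mu g}{\sqrt{1 + \nu^2 \sigma^2 g}},}
#' where `c = -logit(K)` encodes the disease prevalence `K`.
#'
#' Two named presets are provided for `nu`. `"probit"` is the classical
#' logit-probit scaling 16 sqrt(3) / (15 pi) ~ 0.588 and is the default: it
#' reproduces the canonical worked value (marginal OR ~1.9 for mu = 0,
#' sigma = 1, K = 1%). `"rounded"` = 0.625 is a commonly quoted rounding of
#' the same constant and yields ~2.0 in that example; the two conventions
#' are mutually inconsistent at the second decimal and both are exposed
#' rather than silently merged.
#'
#' @param mu Mean log odds-ratio.
#' @param sigma Standard deviation of log odds-ratios, `>= 0`.
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @param nu `"probit"`, `"rounded"`, or a positive number.
#' @param approx_c If `TRUE`, use the rare-disease approximation
#'   `c = -log(K)` instead of the exact `-logit(K)` (differences < 1% for
#'   `K <= 0.01`).
#' @return Object of class `random_effect_risk` with fields `mu`, `sigma`,
#'   `prevalence`, `nu`, `c`.
#' @examples
#' m <- random_effect_risk(mu = 0, sigma = 1, prevalence = 0.01)
#' exp(carrier_lor(m))   # marginal OR of a novel-allele carrier, ~1.9
#' @export
random_effect_risk <- function(mu = 0, sigma, prevalence,
                               nu = c("probit", "rounded"),
                               approx_c = FALSE) {
  nu <- resolve_nu(nu)
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            prevalence > 0, prevalence < 1)
  cc <- if (approx_c) -log(prevalence) else -stats::qlogis(prevalence)
  structure(list(mu = mu, sigma = sigma, prevalence = prevalence,
                 nu = nu, c = cc),
            class = "random_effect_risk")
}

#' Resolve a logit-probit scaling constant
#'
#' @param nu `"probit"` (16 sqrt(3) / (15 pi), the classical scaling),
#'   `"rounded"` (0.625, a common rounding), or a positive number.
#' @return Numeric scalar.
#' @export
resolve_nu <- function(nu = c("probit", "rounded")) {
  if (is.character(nu)) {
    nu <- match.arg(nu)
    nu <- switch(nu, probit = 16 * sqrt(3) / (15 * pi), rounded = 0.625)
  }
  stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0)
  nu
}

#' Marginal (prediction-scale) logit of disease for a carrier
#'
#' The approximate marginal logit `(-c + mu g) / sqrt(1 + nu^2 sigma^2 g)`
#' for an individual carrying `g` minor alleles with Gaussian-distributed
#' effects. At `g = 0` this is the non-carrier baseline `-c = logit(K)`;
#' at `sigma = 0` the plug-in logistic model `-c + mu g` is recovered.
#'
#' @param model A [random_effect_risk()].
#' @param g Non-negative integer allele count (vectorized).
#' @return Logit values.
#' @export
marginal_logit <- function(model, g) {
  stopifnot(inherits(model, "random_effect_risk"),
            is.numeric(g), all(g >= 0), all(g == round(g)))
  (-model$c + model$mu * g) / sqrt(1 + model$nu^2 * model$sigma^2 * g)
}

#' Marginal log odds-ratio of carrying one allele versus none
#'
#' `marginal_logit(g = 1) - marginal_logit(g = 0)`. With `mu = 0` this is
#' `c (1 - 1 / sqrt(1 + nu^2 sigma^2))`: it grows sharply with the effect
#' heterogeneity `sigma` and scales with `c ~ -log(K)`, so carrying an
#' allele of unknown effect raises predicted risk even when effects are
#' centered at zero, and more so for rarer diseases.
#'
#' @param model A [random_effect_risk()].
#' @return Scalar log odds-ratio.
#' @export
carrier_lor <- function(model) {
  marginal_logit(model, 1L) - marginal_logit(model, 0L)
}

#' Exact marginal logit by quadrature
#'
#' Numerically exact counterpart of [marginal_logit()]: computes
#' `logit( E_beta[ plogis(-c + beta g) ] )` with `beta ~ N(mu, sigma^2)` by
#' adaptive quadrature over `mu +/- 10 sigma`. Serves as the oracle against
#' which the closed-form approximation is judged.
#'
#' @param model A [random_effect_risk()].
#' @param g Non-negative integer allele count (scalar).
#' @param rel_tol Quadrature relative tolerance.
#' @return Logit value.
#' @export
exact_marginal_logit <- function(model, g, rel_tol = 1e-10) {
  stopifnot(inherits(model, "random_effect_risk"),
            length(g) == 1L, g >= 0, g == round(g))
  if (model$sigma == 0 || g == 0)
    return(-model$c + model$mu * g)
  f <- function(b)
    stats::plogis(-model$c + b * g) * stats::dnorm(b, model$mu, model$sigma)
  pr <- .quad(f, model$mu - 10 * model$sigma, model$mu + 10 * model$sigma,
              rel.tol = rel_tol)
  stats::qlogis(pr)
}

#' Inflation of the random-effect lOR relative to a plug-in estimate
#'
#' For estimated (previously observed) SNPs the effect-uncertainty `sigma`
#' in the marginal model can be replaced by the standard error of the
#' estimate. This returns the ratio of the `mu = 0` carrier lOR at
#' `sigma = sigma_new` (novel SNPs) to that at `sigma = se_observed`
#' (estimated SNPs). The prevalence constant `c` cancels, so the ratio is
#' prevalence-free.
#'
#' @param sigma_new Population SD of novel-SNP lORs, `> 0`.
#' @param se_observed Standard error of the estimated lOR, `> 0`.
#' @param nu Scaling constant preset or number (see [resolve_nu()]).
#' @return Ratio of carrier lORs.
#' @export
plugin_inflation_ratio <- function(sigma_new, se_observed,
                                   nu = c("probit", "rounded")) {
  nu <- resolve_nu(nu)
  stopifnot(sigma_new > 0)
  if (se_observed <= 0) stop("se_observed must be positive")
  num <- 1 - 1 / sqrt(1 + nu^2 * sigma_new^2)
  den <- 1 - 1 / sqrt(1 + nu^2 * se_observed^2)
  num / den
}

#' Wald standard error of a null allele-count log odds-ratio
#'
#' Expected standard error of an estimated lOR of zero from the allele-count
#' 2x2 table: `sqrt(1/a + 1/b + 1/c + 1/d)` with expected cells
#' `a = 2 n_cases maf`, `b = 2 n_cases (1 - maf)`, etc. Symmetric in
#' `maf <-> 1 - maf`; quadrupling both sample sizes halves it.
#'
#' @param maf Allele frequency in (0, 1).
#' @param n_cases,n_controls Sample sizes, `>= 1`.
#' @return List with `se` and logical `small_counts` flagging any expected
#'   cell below 1.
#' @export
wald_se_lor <- function(maf, n_cases, n_controls) {
  stopifnot(maf > 0, maf < 1, n_cases >= 1, n_controls >= 1)
  cells <- c(2 * n_cases * maf, 2 * n_cases * (1 - maf),
             2 * n_controls * maf, 2 * n_controls * (1 - maf))
  list(se = sqrt(sum(1 / cells)), small_counts = any(cells < 1))
}
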
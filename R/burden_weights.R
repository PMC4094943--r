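#' Burden-test weighting scheme
#'
#' Weighting schemes that up-weight rare alleles in burden and
#' variance-component tests, together with the anchoring used to translate
#' weights into implied per-SNP effects: because optimal burden weights are
#' proportional to per-SNP log odds-ratios, a weight curve plus a fixed
#' odds ratio at the largest included MAF determines the whole implied
#' effect-size curve.
#'
#' Schemes: `madsen_browning` is `1 / sqrt(maf (1 - maf))` (inverse
#' binomial SD); `attributable_risk` is `1 / maf` (constant per-SNP
#' population attributable fraction); `beta_density` is the Beta density at
#' the MAF -- the variance-component default uses shape parameters (1, 25),
#' concentrating weight on rare alleles. The literal reversed order (25, 1)
#' can be requested explicitly via `beta_a`/`beta_b`. `equal` weights every
#' SNP identically.
#'
#' @param name One of `"madsen_browning"`, `"attributable_risk"`,
#'   `"beta_density"`, `"equal"`.
#' @param beta_a,beta_b Shape parameters for `beta_density` (default 1 and
#'   25).
#' @param anchor_or Odds ratio assigned to the SNP at `anchor_maf`
#'   (default 1.2).
#' @param anchor_maf Largest MAF in the analyzed set (e.g. 0.05 or 0.01).
#' @return Object of class `weight_scheme`.
#' @examples
#' ws <- weight_scheme("madsen_browning", anchor_maf = 0.05)
#' implied_lor_curve(ws, c(0.005, 0.01, 0.05))
#' @export
weight_scheme <- function(name = c("madsen_browning", "attributable_risk",
                                   "beta_density", "equal"),
                          beta_a = 1, beta_b = 25,
                          anchor_or = 1.2, anchor_maf = 0.05) {
  name <- match.arg(name)
  stopifnot(beta_a > 0, beta_b > 0, anchor_or > 0,
            anchor_maf > 0, anchor_maf <= 0.5)
  structure(list(name = name, beta_a = beta_a, beta_b = beta_b,
                 anchor_or = anchor_or, anchor_maf = anchor_maf),
            class = "weight_scheme")
}

#' Weight of a SNP under a scheme
#'
#' @param scheme A [weight_scheme()].
#' @param maf Frequencies strictly inside (0, 1); the endpoint weights are
#'   singular.
#' @return Positive weights, same length as `maf`.
#' @export
weight_value <- function(scheme, maf) {
  stopifnot(inherits(scheme, "weight_scheme"), is.numeric(maf))
  if (any(maf <= 0) || any(maf >= 1))
    stop("weights are singular at maf 0 or 1; supply maf in (0, 1)")
  switch(scheme$name,
         madsen_browning  = 1 / sqrt(maf * (1 - maf)),
         attributable_risk = 1 / maf,
         beta_density = stats::dbeta(maf, scheme$beta_a, scheme$beta_b),
         equal = rep(1, length(maf)))
}

#' Per-SNP odds ratios implied by a weighting scheme
#'
#' Under the optimality relation "weight proportional to per-SNP log
#' odds-ratio", the implied effect at MAF `p` is
#' `lor(p) = log(anchor_or) * w(p) / w(anchor_maf)`, i.e. the curve is
#' anchored multiplicatively on the log-odds scale so the SNP at the
#' largest included MAF has exactly `anchor_or`. The implied curve depends
#' strongly on that upper MAF limit.
#'
#' @param scheme A [weight_scheme()].
#' @param maf_grid Frequencies in `(0, anchor_maf]`.
#' @return data.frame with columns `maf`, `weight`, `implied_or`.
#' @export
implied_lor_curve <- function(scheme, maf_grid) {
  stopifnot(inherits(scheme, "weight_scheme"), length(maf_grid) > 0)
  if (any(maf_grid > scheme$anchor_maf))
    stop("maf_grid values above anchor_maf: the analyzed set is ",
         "truncated at the anchor MAF")
  w <- weight_value(scheme, maf_grid)
  w0 <- weight_value(scheme, scheme$anchor_maf)
  data.frame(maf = maf_grid, weight = w,
             implied_or = exp(log(scheme$anchor_or) * w / w0))
}

#' Relative squared effect sizes implied by variance-component weights
#'
#' Variance-component (kernel) tests with diagonal per-SNP weights `w_j`
#' correspond to a model in which `w_j` is proportional to `E[lOR_j^2]`.
#' This normalizes a weight vector to sum to one, giving the relative
#' squared effects it implies; the result is invariant to rescaling all
#' weights.
#'
#' @param weights Positive numeric vector.
#' @return Numeric vector summing to one.
#' @export
variance_weight_to_lor2 <- function(weights) {
  stopifnot(is.numeric(weights), length(weights) > 0)
  if (any(weights <= 0)) stop("all weights must be positive")
  weights / sum(weights)
}
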
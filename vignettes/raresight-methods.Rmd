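---
title: "Methods: power and interpretation of rare-variant case-control sequencing studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power and interpretation of rare-variant case-control sequencing studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raresight)
```

raresight is a planning and interpretation toolkit for case-control
sequencing studies of rare variants. It has five analytic components: the
ascertained minor-allele-frequency (MAF) spectrum and its moments, an
analytic burden-test power model built on a non-centrality parameter (NCP),
the marginal disease risk carried by alleles whose effects are only known
in distribution, single-SNP discovery (ascertainment) probabilities in
finite samples, and a Monte-Carlo simulator of the winner's curse that
selective discovery induces in pooled rare-variant effect estimates. A
sixth component maps burden-test weighting schemes to the per-SNP effect
sizes they implicitly assume. This vignette explains each model, its
assumptions, the defaults, and the numerical choices.

## The ascertained MAF spectrum

Rare-variant analyses act on the SNPs that were *seen*: a SNP enters the
analysis set only if it is polymorphic in the sequenced sample. We model
the MAF `M` of candidate SNPs either as a Beta(`beta_a`, `beta_b`) density
truncated to `(0, max_maf]`, or as an empirical list of frequencies. The
defaults — Beta(0.14, 0.73), truncation at 1%, ascertainment among
`A = 20000` chromosomes (10,000 diploid subjects) — describe the
low-frequency end of a European-like site-frequency spectrum restricted to
SNPs with MAF below 1%.

Polymorphism ascertainment is implemented as the reweighting
`w(p) = 1 - (1 - p)^A`, the binomial-sampling probability that at least one
of `A` chromosomes carries the minor allele. The model itself does not fix
this form; it is the standard reading of "polymorphic in N subjects". Two
consequences matter and are covered by tests:

* *any* ascertainment removes unseen rare SNPs and raises the mean MAF
  relative to the unconditional spectrum;
* a *larger* sequencing panel is a weaker filter — more of the rare tail
  is observed — so `E[M]` decreases back toward the unconditional mean as
  `A` grows. (It is the conditioning itself, not its severity, that
  shifts the spectrum.)

`spectrum_moments()` integrates the normalized, reweighted density by
adaptive quadrature (relative tolerance `1e-10`; the integrand
`p^(beta_a - 1)` is singular but integrable at zero, which `integrate()`
handles at the endpoint; quadrature non-convergence raises an error rather
than returning a value). It reports `E[M]`, `V[M]`, the genotype-variance
scale `E[M(1-M)] = E[M] - E[M]^2 - V[M]`, and the NCP MAF factor

$$ f = \frac{E[M]}{\sqrt{E[M(1-M)]}}. $$

The denominator is the per-SNP genotype variance scale that a
first-principles variance calculation of the burden score produces. A
plausible alternative reading replaces it with `V[M] + E[M] - E[M]^2`;
both are exposed (`maf_factor`, `maf_factor_alt`) and differ by under 1%
for spectra truncated at 1%, where both are within 2% of the shorthand
`sqrt(E[M])`. Under the defaults the factor evaluates to ≈ 0.047, in
agreement at two significant digits with the reference value 0.046 derived
from sequencing panel data.

## Burden-test power

For a balanced design with `n` cases and `n` controls and a set of `k`
independent SNPs of which `k1` share a common odds ratio γ, the Z-scale
non-centrality parameter of the burden test factorizes as

$$ NCP = \sqrt{n} \cdot \frac{k_1}{\sqrt{k}} \cdot f \cdot (\gamma - 1). $$

The four factors isolate the design levers: sample size (quadrupling `n`
doubles the NCP), signal sparsity `k1/k`, the MAF spectrum, and the effect
size. Power is `pnorm(NCP - qnorm(1 - alpha))` for the one-sided test
(default, since a burden alternative is directional) or the noncentral
chi-square tail for the two-sided variant. `n` is cases per arm: with the
printed factor 0.046, `n = 5000`, `k = 100`, `k1 = 10`, γ = 3, the NCP is
≈ 6.5 and one-sided power at `5e-8` is ≈ 0.87. `sample_size_for_power()`
inverts the relation exactly (closed-form seed plus integer bracketing),
and `sparsity_curve()` tabulates `n` against `k1/k`; `n` scales as the
inverse square of sparsity.

Two approximations are baked into the NCP and bound its validity domain:

* the frequency difference uses `p_case - p_ctrl ≈ p(γ - 1)`, accurate to
  about `1.3 p` in relative terms — excellent below MAF 1%;
* the variance is evaluated at the population MAF, ignoring the inflation
  of the case-arm variance under the alternative, a relative NCP error of
  roughly `(k1/k)(γ - 1)/4`.

`simulate_burden_power()` is the package's own check: it draws
per-individual burden scores from exact logistic-model case/control
frequencies (no rare-variant approximation) and applies the two-sample
Z-test. The agreement suite runs six designs with `k1/k ≤ 0.1`, MAF
≤ 0.005 and γ ≤ 1.4 at α = 0.05 and 10⁻³, 600 simulated studies each —
sizes chosen so Monte-Carlo error (~0.02) dominates the documented
approximation bias (~0.01). Within that domain analytic and empirical
power agree within three Monte-Carlo standard errors; outside it (dense
causal sets with γ ≥ 2) the analytic NCP is optimistic by several percent,
which is the approximation error quantified above, not a bug in either
calculation.

The stratification algebra (`stratified_effect()`) expresses the value of
phenotype refinement: if only a fraction α_s of cases is etiologically
relevant (odds ratio γ_T in that stratum), the full case set shows the
diluted effect `γ - 1 = α_s (γ_T - 1)` and diluted case MAF
`α_s p γ_T + (1 - α_s) p`; restricting the analysis to the relevant α_s n
cases multiplies the NCP by `1/sqrt(α_s)`.

## Marginal risk of novel alleles

When a newly sequenced individual carries a variant never seen before, its
effect β is unknown; modelling β as Gaussian `N(mu, sigma^2)` and
marginalizing it out of the logistic model gives the prediction-scale
logit for a carrier of `g` alleles:

$$ \mathrm{logit}\,P(Y{=}1 \mid g) \approx
   \frac{-c + \mu g}{\sqrt{1 + \nu^2 \sigma^2 g}}, \qquad
   c = -\mathrm{logit}(K), $$

with prevalence `K` and the logit-probit scaling constant ν. Even with
effects centred at zero, carrying an unknown allele raises predicted risk
(for `K < 0.5`), because effect uncertainty pulls the prediction from the
baseline toward 50:50 — for `mu = 0` the carrier log odds-ratio is
`c (1 - 1/sqrt(1 + ν² σ²))`, growing with σ and with the rarity of the
disease. At `mu = 0`, `sigma = 1`, `K = 1%` the marginal carrier OR is
≈ 1.9.

Numerical conventions, chosen once and exposed rather than hidden:

* ν defaults to the classical logit-probit scaling `16√3/(15π) ≈ 0.588`
  (preset `"probit"`), which reproduces the 1.9 example; the commonly
  quoted rounding 0.625 (preset `"rounded"`) gives ≈ 2.0. The two are
  mutually inconsistent at the second decimal; both are available and
  neither is silently corrected.
* `c` is the exact `-logit(K)`; the rare-disease shorthand `-log(K)` is a
  flag (`approx_c`), differing by under 1% for `K ≤ 1%`.
* the carrier lOR is computed as the exact difference of the two logit
  evaluations, not from a series expansion.

`exact_marginal_logit()` is the built-in oracle: it evaluates
`logit(E_β[expit(-c + βg)])` by adaptive quadrature over ±10σ. Comparing
the two quantifies the approximation honestly: the closed form scales with
`c ≈ -log K`, while the exact marginal carrier lOR saturates near `σ²/2`
for rare diseases (the log-normal mean of the allele's risk ratio). The
measured signed relative error of the approximate carrier lOR is +92% to
+136% at `K = 0.001`, +34% to +60% at `K = 0.01`, and within ±10% at
`K = 0.1` (σ ≤ 1). The approximation is therefore a qualitative guide at
low prevalence — it always errs upward there — and quantitatively reliable
only for common-ish diseases; the tests assert exactly this structure.
(At `K = 1%`, `σ = 1` the exact marginal OR is ≈ 1.6 against the
approximate 1.9.)

The same formula prices the difference between *novel* and *estimated*
SNPs: for an estimated SNP, σ² is replaced by the squared standard error
of its estimate (`wald_se_lor()` gives the null allele-count Wald SE;
MAF 0.3 with 3000 cases and controls gives ≈ 0.04). The ratio of carrier
lORs (`plugin_inflation_ratio()`) is prevalence-free; a novel-SNP
population SD of 0.5 against an estimation SE of 0.06 yields a ≈ 65-fold
gap, underlining that novel-variant risk is dominated by effect
*uncertainty*, not effect *estimates*.

## Discovery in finite case-control samples

`disease_model()` anchors a single-SNP logistic model: given population
MAF `p`, per-allele log odds-ratio β and prevalence `K`, the intercept
solves the Hardy-Weinberg prevalence constraint (Brent's method, tolerance
`1e-14`; the equation is strictly monotone, so the root is unique). The
simulators use a damped-Newton vectorized version of the same solve,
cross-checked against the scalar solver in the tests. Case and control
allele frequencies follow by genotype enumeration, with controls
conditioned on being unaffected (not a population sample — visible at
prevalences of 1–5%); they satisfy
`K p_case + (1 - K) p_ctrl = p` exactly, which the suite checks to
machine precision.

A SNP is *discovered* when its minor allele appears at least once among
the `2 n` case chromosomes or `2 n` control chromosomes, each binomial at
its conditional frequency: allele-level sampling, which at these MAFs is
indistinguishable from genotype-level sampling. Discovery probability
rises steeply with β when `2 n p` is of order one: risk-increasing alleles
are over-represented among discovered SNPs because their case-frequency
gain outweighs their control-frequency loss. `datatype_probs()` gives the
probabilities, conditional on discovery, of the diagnostic observation
patterns (case-only; exactly one control copy and no case copies; other),
integrating β out over its Gaussian by quadrature, and
`expected_sampled_lor()` gives the mean true effect of discovered SNPs —
the enrichment that drives everything in the next section. "Exactly one
control copy" is interpreted as one minor-allele copy, the natural reading
for allele counts.

## The winner's curse for pooled rare variants

The simulator (`run_winners_curse()`) draws, per replicate, `k` per-SNP
effects from `N(mu, sigma^2)`, computes each SNP's case/control
frequencies under its own logistic model, draws observation counts, and
splits SNPs into discovered and novel pools. It reports four summaries:

* discovery fraction;
* the in-study pooled "super-SNP" estimate: all discovered-SNP alleles
  pooled into one 2×2 allele table, Haldane-Anscombe `h = 0.5` added to
  every cell unconditionally (so replicate means always exist), log odds
  ratio taken;
* the replication log odds-ratio of the discovered pool and of the novel
  pool, computed analytically from the population case/control
  frequencies — the value an arbitrarily large replication sample would
  estimate. A finite-replication mode (`finite_replication = n`) exists
  for verification and approaches the analytic values.

The default configuration — 50 cases, 50 controls, prevalence 5%, 125
SNPs at MAF 0.002, standard-normal effects, 2000 replicates — is the
reference scenario; "sample size of 100" is read as 50 per arm, which
reproduces the reference discovery fraction of ≈ 36% (100 per arm gives
≈ 60%). Under it the simulation gives: discovery ≈ 0.37, in-study pooled
estimate ≈ 0.40, replication lOR ≈ 0.71 for discovered and ≈ 0.15 for
novel SNPs. The qualitative phenomenon is exactly the one the reference
analysis highlights: discovered rare SNPs carry a strongly inflated
pooled effect in replication while novel SNPs do not, and every summary
vanishes under the null (`sigma = 0`), confirming the effect is pure
sampling selection, not confounding. Quantitatively our estimator
reproduces the reference values for discovery fraction, in-study estimate
and the discovered pool within their tolerance, but yields ≈ 0.15 for the
novel pool against the reference ≈ 0.05. We examined many candidate
estimator definitions (per-SNP mean effects, frequency-weighted means,
grand pooling, finite-sample count pooling, population-sample controls);
none reproduces 0.05 while preserving the other three values, so we
retain the principled pooled-frequency definition and report the
discrepancy rather than tuning toward it. Two structural facts explain
why the novel pool stays positive: pooling averages frequencies before
taking odds, and the heavy right tail of surviving effects keeps the
pooled case frequency elevated even after discovery has skimmed the most
harmful alleles.

Sampling is independent across SNPs conditional on case status
(single-SNP intercepts); co-carriage correlations of a joint
multi-SNP liability are ignored. At 125 SNPs of MAF 0.002 with
standard-normal effects an individual carries ≈ 0.5 causal alleles on
average, so this independence is an approximation — a joint model would
shrink all pooled log odds-ratios by roughly 8% (the other-SNP burden acts
as extra logistic noise) — documented here as a known limitation.

Study-size behaviour: quadrupling the sample raises discovery (≈ 0.37 to
≈ 0.80) and makes the discovered pool representative — its replication
lOR moves toward the all-SNP marginal pooled value — while the
ever-smaller novel pool becomes more extreme, not less. Rare novel SNPs
are unrepresentative of previously seen SNPs at *any* study size.

Reproducibility: the master seed is expanded into per-replicate sub-seeds
(counter-based), so any replicate can be regenerated in isolation and
identical configurations give bit-identical summaries.

## Implied effect sizes of weighting schemes

Burden weights are optimal when proportional to per-SNP log odds-ratios,
so a weight curve plus one anchoring assumption — the SNP at the largest
included MAF has OR `anchor_or` (default 1.2) — determines the entire
per-SNP effect curve a scheme implicitly assumes:
`lor(p) = log(anchor_or) · w(p)/w(anchor_maf)`. Schemes provided:
inverse binomial SD `1/sqrt(p(1-p))` (Madsen-Browning), `1/p`
(constant per-SNP attributable risk; the source reference for this weight
is not available, so the constant-attributable-fraction form is adopted
and documented), the Beta-density weight of variance-component (SKAT-type)
tests, and equal weights. The Beta default is shape (1, 25) — mass on
rare alleles, the convention of the variance-component literature; the
literal reversed order (25, 1) sometimes quoted is available by passing
the parameters explicitly, since the two orders contradict each other and
neither is silently corrected. For diagonal variance-component tests the
weights admit the interpretation `w_j ∝ E[lOR_j²]`
(`variance_weight_to_lor2()`).

Two properties are enforced exactly: the curve passes through
`anchor_or` at `anchor_maf` for every scheme, and the implied effect at a
fixed rare MAF depends strongly on the truncation MAF of the analyzed set
(anchoring at 5% versus 1% changes the implied OR at MAF 0.5%
substantially) — a warning that weighting schemes are not transportable
across set definitions.

## Problem sizes and runtime

All defaults are analytic except the simulators. The test suite uses 2000
replicates for the reference winner's-curse scenario (Monte-Carlo SE
≈ 0.003 on the discovery fraction, ≈ 0.006 on the pooled estimate), 600
simulated studies per burden-power design, and 10⁵-draw Monte-Carlo
oracles for discovery and observation-pattern probabilities; the whole
suite runs in well under a minute on one CPU. The acceptance script
recomputes every headline number (spectrum factor by quadrature, NCP,
marginal OR, and the four winner's-curse summaries at 2000 replicates) in
a few seconds.
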
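# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: intercepts come from a dense grid refined by
# bisection, frequencies from direct genotype enumeration.

# Bisection solve of the prevalence equation on a coarse bracket.
oracle_intercept <- function(maf, lor, prevalence, iters = 200) {
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  prev <- function(a) sum(hwe / (1 + exp(-(a + lor * 0:2)))) - prevalence
  lo <- -60; hi <- 60
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (prev(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Genotype-enumeration case/control allele frequencies.
oracle_ccfreq <- function(maf, lor, prevalence) {
  a <- oracle_intercept(maf, lor, prevalence)
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  risk <- 1 / (1 + exp(-(a + lor * 0:2)))
  list(p_case = sum((0:2) * hwe * risk) / (2 * prevalence),
       p_ctrl = sum((0:2) * hwe * (1 - risk)) / (2 * (1 - prevalence)))
}

expect_within_3se <- function(estimate, truth, se, label = NULL) {
  expect_lt(abs(estimate - truth), 3 * se + 1e-12, label = label)
}
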
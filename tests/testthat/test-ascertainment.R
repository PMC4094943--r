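test_that("the intercept solve hits the prevalence constraint", {
  # null effect: intercept is exactly logit(K)
  expect_equal(solve_intercept(0.1, 0, 0.05), qlogis(0.05),
               tolerance = 1e-10)
  # monotone: stronger risk alleles push the intercept down
  a <- vapply(c(-1, 0, 1, 2), function(b) solve_intercept(0.01, b, 0.05),
              numeric(1))
  expect_true(all(diff(a) < 0))
  # independent bisection oracle
  expect_equal(solve_intercept(0.002, 1, 0.05),
               oracle_intercept(0.002, 1, 0.05), tolerance = 1e-6)
  # the solved model reproduces the prevalence by direct enumeration
  m <- disease_model(0.002, 1, 0.05)
  hwe <- dbinom(0:2, 2, 0.002)
  expect_equal(sum(hwe * plogis(m$intercept + 1 * (0:2))), 0.05,
               tolerance = 1e-10)
})

test_that("the vectorized Newton solver matches the scalar Brent solver", {
  set.seed(41)
  p <- runif(30, 5e-4, 0.2)
  b <- runif(30, -3, 3)
  K <- runif(30, 0.005, 0.3)
  for (i in seq_along(p)) {
    a_vec <- raresight:::solve_intercept_vec(p[i], b[i], K[i])
    expect_equal(a_vec, solve_intercept(p[i], b[i], K[i]),
                 tolerance = 1e-8)
  }
})

test_that("case/control frequencies conserve alleles exactly", {
  # null effect gives the population frequency in both arms
  f0 <- case_control_freqs(disease_model(0.01, 0, 0.05))
  expect_equal(f0$p_case, 0.01, tolerance = 1e-10)
  expect_equal(f0$p_ctrl, 0.01, tolerance = 1e-10)
  # K p_case + (1 - K) p_ctrl = p to machine precision on a random grid
  set.seed(42)
  for (i in 1:25) {
    p <- runif(1, 1e-4, 0.3); b <- runif(1, -3, 3); K <- runif(1, 0.01, 0.3)
    f <- case_control_freqs(disease_model(p, b, K))
    expect_equal(K * f$p_case + (1 - K) * f$p_ctrl, p, tolerance = 1e-12)
  }
})

test_that("case/control frequencies match the enumeration oracle", {
  f <- case_control_freqs(disease_model(0.002, 1, 0.05))
  o <- oracle_ccfreq(0.002, 1, 0.05)
  expect_equal(f$p_case, o$p_case, tolerance = 1e-8)
  expect_equal(f$p_ctrl, o$p_ctrl, tolerance = 1e-8)
  expect_equal(f$p_case, 5.4e-3, tolerance = 0.02)
  expect_equal(f$p_ctrl, 1.8e-3, tolerance = 0.02)
})

test_that("discovery probability has its closed form and Monte-Carlo behaviour", {
  # null SNP: 1 - (1 - p)^(2 n_cases + 2 n_controls)
  m0 <- disease_model(0.002, 0, 0.05)
  expect_equal(discovery_prob(m0, 50, 50), 1 - 0.998^200,
               tolerance = 1e-10)
  # strictly increasing in the effect and in the MAF
  d <- vapply(c(-1, 0, 0.5, 1, 2), function(b)
    discovery_prob(disease_model(0.002, b, 0.05), 100, 100), numeric(1))
  expect_true(all(diff(d) > 0))
  d2 <- vapply(c(5e-4, 1e-3, 2e-3, 5e-3), function(p)
    discovery_prob(disease_model(p, 1, 0.05), 100, 100), numeric(1))
  expect_true(all(diff(d2) > 0))
  # Monte-Carlo allele-sampling oracle
  m <- disease_model(0.002, 1, 0.05)
  f <- case_control_freqs(m)
  set.seed(43)
  reps <- 1e5
  seen <- (rbinom(reps, 200, f$p_case) + rbinom(reps, 200, f$p_ctrl)) >= 1
  se <- sd(seen) / sqrt(reps)
  expect_within_3se(mean(seen), discovery_prob(m, 100, 100), se)
})

test_that("observation-pattern probabilities normalize and order correctly", {
  dt <- datatype_probs(0.005, 0, 1, 0.01, 100, 100)
  expect_equal(dt$case_only + dt$control_singleton_no_case + dt$other, 1,
               tolerance = 1e-8)
  # fixed null effect, equal arms, rare disease: more ways to be case-only
  dt0 <- datatype_probs(0.005, 0, 0, 0.01, 100, 100)
  expect_gt(dt0$case_only, dt0$control_singleton_no_case)
  # closed-form binomial oracle at sigma = 0
  f <- case_control_freqs(disease_model(0.005, 0, 0.01))
  poly <- 1 - (1 - f$p_case)^200 * (1 - f$p_ctrl)^200
  case_only <- (1 - (1 - f$p_case)^200) * (1 - f$p_ctrl)^200
  ctrl_one <- 200 * f$p_ctrl * (1 - f$p_ctrl)^199 * (1 - f$p_case)^200
  expect_equal(dt0$case_only, case_only / poly, tolerance = 1e-8)
  expect_equal(dt0$control_singleton_no_case, ctrl_one / poly,
               tolerance = 1e-8)
})

test_that("observation-pattern probabilities match Monte-Carlo under random effects", {
  # expected population count p * 2n = 1, standard-normal effects
  p <- 1 / 200; K <- 0.01; n <- 100
  dt <- datatype_probs(p, 0, 1, K, n, n)
  set.seed(44)
  reps <- 2e5
  beta <- rnorm(reps)
  f <- raresight:::case_control_freqs_vec(p, beta, K)
  cc <- rbinom(reps, 2 * n, f$p_case)
  tc <- rbinom(reps, 2 * n, f$p_ctrl)
  poly <- (cc + tc) >= 1
  co <- mean(cc >= 1 & tc == 0) / mean(poly)
  cs <- mean(tc == 1 & cc == 0) / mean(poly)
  expect_within_3se(co, dt$case_only, sqrt(co * (1 - co) / sum(poly)))
  expect_within_3se(cs, dt$control_singleton_no_case,
                    sqrt(cs * (1 - cs) / sum(poly)))
})

test_that("sampled SNPs are enriched for risk effects", {
  expect_identical(expected_sampled_lor(0.002, 0.3, 0, 0.05, 100, 100), 0.3)
  # enrichment above the population mean for rare SNPs
  e_rare <- expected_sampled_lor(0.002, 0, 1, 0.05, 50, 50)
  expect_gt(e_rare, 0)
  # enrichment fades as the SNP becomes common enough to always be seen
  e_common <- expected_sampled_lor(0.05, 0, 1, 0.05, 50, 50)
  expect_lt(e_common, e_rare)
  e_grid <- vapply(c(0.001, 0.002, 0.005, 0.02, 0.1), function(p)
    expected_sampled_lor(p, 0, 1, 0.05, 50, 50), numeric(1))
  expect_true(all(diff(e_grid) < 0))
})

test_that("grid generators tabulate the analytic quantities", {
  g <- discovery_grid(prevalence = 0.01, n_cases = 100, n_controls = 100,
                      lor_grid = c(0, 1), count_grid = c(0.5, 1, 2))
  expect_identical(names(g), c("expected_count", "lor", "discovery_prob"))
  expect_equal(nrow(g), 6L)
  m <- disease_model(1 / 200, 1, 0.01)
  expect_equal(g$discovery_prob[g$lor == 1 & g$expected_count == 1],
               discovery_prob(m, 100, 100), tolerance = 1e-10)
  dg <- datatype_grid(sigma = 0.5, count_grid = c(0.5, 1))
  expect_equal(dg$p_case_only + dg$p_control_singleton + dg$p_other,
               c(1, 1), tolerance = 1e-8)
})
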
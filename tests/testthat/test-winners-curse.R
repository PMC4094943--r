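# Hand-built replicate record for estimator unit tests.
make_record <- function(case_count, control_count, p_case, p_ctrl,
                        n_cases = 50, n_controls = 50,
                        true_lor = rep(0, length(case_count))) {
  structure(list(true_lor = true_lor,
                 maf = rep(0.002, length(case_count)),
                 p_case = p_case, p_ctrl = p_ctrl,
                 case_count = case_count, control_count = control_count,
                 discovered = (case_count + control_count) >= 1L,
                 n_cases = n_cases, n_controls = n_controls),
            class = "replicate_record")
}

test_that("the pooled super-SNP estimator matches direct arithmetic", {
  # two discovered SNPs, 3 case alleles vs 1 control allele, h = 0.5
  rec <- make_record(case_count = c(2L, 1L, 0L),
                     control_count = c(0L, 1L, 0L),
                     p_case = rep(0.003, 3), p_ctrl = rep(0.002, 3))
  expect_equal(pooled_lor_estimate(rec, 0.5),
               log((3.5 / 197.5) / (1.5 / 199.5)), tolerance = 1e-12)
  # symmetric counts in equal arms give zero
  rec0 <- make_record(c(2L, 1L), c(1L, 2L), rep(0.002, 2), rep(0.002, 2))
  expect_equal(pooled_lor_estimate(rec0, 0.5), 0, tolerance = 1e-12)
  # invariant to SNP order
  perm <- make_record(case_count = c(0L, 1L, 2L),
                      control_count = c(0L, 1L, 0L),
                      p_case = rep(0.003, 3), p_ctrl = rep(0.002, 3))
  expect_equal(pooled_lor_estimate(perm, 0.5), pooled_lor_estimate(rec, 0.5))
  # no discovery: undefined marker
  none <- make_record(c(0L, 0L), c(0L, 0L), rep(0.002, 2), rep(0.002, 2))
  expect_true(is.na(pooled_lor_estimate(none)))
})

test_that("replication lORs reduce correctly for simple pools", {
  # every SNP null: both pools sit at zero
  recnull <- make_record(c(1L, 0L), c(0L, 0L),
                         p_case = c(0.002, 0.002),
                         p_ctrl = c(0.002, 0.002))
  rl <- replication_lors(recnull)
  expect_equal(rl$lor_discovered, 0, tolerance = 1e-12)
  expect_equal(rl$lor_novel, 0, tolerance = 1e-12)
  # singleton pools equal the SNP's own population per-allele lOR
  f <- case_control_freqs(disease_model(0.002, 1, 0.05))
  rec1 <- make_record(c(1L, 0L), c(0L, 0L),
                      p_case = c(f$p_case, f$p_case),
                      p_ctrl = c(f$p_ctrl, f$p_ctrl))
  rl1 <- replication_lors(rec1)
  single <- log(f$p_case * (1 - f$p_ctrl) / (f$p_ctrl * (1 - f$p_case)))
  expect_equal(rl1$lor_discovered, single, tolerance = 1e-12)
  expect_equal(rl1$lor_novel, single, tolerance = 1e-12)
  # empty pool: undefined marker
  alld <- make_record(c(1L, 1L), c(0L, 1L), rep(0.003, 2), rep(0.002, 2))
  expect_true(is.na(replication_lors(alld)$lor_novel))
})

test_that("replicates are reproducible and respect the null model", {
  cfg <- curse_config(replicates = 150, seed = 17, sigma = 0)
  s1 <- run_winners_curse(cfg)
  s2 <- run_winners_curse(cfg)
  expect_identical(s1[-length(s1)], s2[-length(s2)])
  # sigma = 0, mu = 0: every SNP has p_case = p_ctrl = maf and all lOR
  # summaries vanish within Monte-Carlo error
  set.seed(17)
  rec <- simulate_replicate(cfg)
  expect_equal(rec$p_case, rep(0.002, 125), tolerance = 1e-10)
  expect_equal(rec$p_ctrl, rep(0.002, 125), tolerance = 1e-10)
  expect_lt(abs(s1$mean_pooled_estimate), 3 * s1$pooled_estimate_se)
  expect_equal(s1$mean_replication_lor_discovered, 0, tolerance = 1e-10)
  expect_equal(s1$mean_replication_lor_novel, 0, tolerance = 1e-10)
})

test_that("discovery fraction matches the analytic ascertainment integral", {
  cfg <- curse_config(replicates = 500, seed = 29)
  s <- run_winners_curse(cfg)
  analytic <- raresight:::.effect_integral(function(b) {
    f <- raresight:::case_control_freqs_vec(0.002, b, 0.05)
    1 - (1 - f$p_case)^100 * (1 - f$p_ctrl)^100
  }, mu = 0, sigma = 1)
  expect_within_3se(s$mean_discovery_fraction, analytic,
                    s$discovery_fraction_se)
})

test_that("discovered SNPs carry larger replication effects than novel ones", {
  s <- run_winners_curse(curse_config(replicates = 400, seed = 31))
  expect_gt(s$mean_replication_lor_discovered,
            s$mean_replication_lor_novel)
  expect_gt(s$mean_replication_lor_novel, 0)   # rare-SNP pools stay inflated
  # mean true effect of discovered SNPs matches the analytic enrichment
  set.seed(57)
  cfg <- curse_config(replicates = 400)
  tl <- replicate(400, {
    rec <- simulate_replicate(cfg)
    if (any(rec$discovered)) mean(rec$true_lor[rec$discovered]) else NA_real_
  })
  e_an <- expected_sampled_lor(0.002, 0, 1, 0.05, 50, 50)
  expect_within_3se(mean(tl, na.rm = TRUE), e_an,
                    sd(tl, na.rm = TRUE) / sqrt(sum(!is.na(tl))))
})

test_that("larger studies push the curse to rarer alleles", {
  s1 <- run_winners_curse(curse_config(replicates = 400, seed = 37))
  s4 <- run_winners_curse(curse_config(n_cases = 200, n_controls = 200,
                                       replicates = 400, seed = 37))
  expect_gt(s4$mean_discovery_fraction, s1$mean_discovery_fraction)
  # all-SNP pooled replication lOR: the marginal rare-variant effect that
  # the full (unstratified) pool estimates, independent of study size
  set.seed(37)
  b <- rnorm(2e5)
  f <- raresight:::case_control_freqs_vec(0.002, b, 0.05)
  marg <- log(mean(f$p_case) * (1 - mean(f$p_ctrl)) /
                (mean(f$p_ctrl) * (1 - mean(f$p_case))))
  # with near-exhaustive discovery the discovered pool becomes
  # representative of all rare SNPs ...
  expect_lt(abs(s4$mean_replication_lor_discovered - marg),
            abs(s1$mean_replication_lor_discovered - marg))
  # ... while the novel pool stays unrepresentative at any study size
  expect_gt(s1$mean_replication_lor_discovered,
            s1$mean_replication_lor_novel)
  expect_gt(s4$mean_replication_lor_discovered,
            s4$mean_replication_lor_novel)
})

test_that("a large finite replication study approaches the analytic replication lORs", {
  base <- run_winners_curse(curse_config(replicates = 300, seed = 41))
  fin <- run_winners_curse(curse_config(replicates = 300, seed = 41,
                                        finite_replication = 20000))
  expect_equal(fin$mean_replication_lor_discovered,
               base$mean_replication_lor_discovered, tolerance = 0.05)
  expect_equal(fin$mean_replication_lor_novel,
               base$mean_replication_lor_novel, tolerance = 0.05)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(curse_config(maf = 0.7))
  expect_error(curse_config(replicates = 0))
  expect_error(curse_config(sigma = -1))
  # MAF spectrum accepted as the frequency source
  cfg <- curse_config(maf = maf_spectrum(), replicates = 5, seed = 2)
  set.seed(2)
  rec <- simulate_replicate(cfg)
  expect_true(all(rec$maf > 0 & rec$maf <= 0.01))
})
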
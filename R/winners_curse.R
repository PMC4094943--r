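#' Configuration of the rare-variant winner's-curse simulator
#'
#' Settings for a Monte-Carlo study of selective SNP discovery in a
#' case-control sequencing sample and its downstream effect on pooled
#' ("super-SNP") effect estimates. The defaults encode the reference
#' scenario: 50 cases and 50 controls, prevalence 5%, 125 SNPs at
#' population MAF 0.002, per-SNP log odds-ratios i.i.d. N(0, 1).
#'
#' @param n_cases,n_controls Sample sizes, `>= 1`.
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @param k_snps Number of SNPs, `>= 1`.
#' @param maf Population MAF shared by the SNPs (scalar in (0, 0.5)) or a
#'   [maf_spectrum()] to draw per-SNP MAFs from.
#' @param mu,sigma Gaussian effect distribution of the per-SNP log
#'   odds-ratios (`sigma >= 0`).
#' @param replicates Number of simulated studies `R >= 1`.
#' @param seed Integer seed; each replicate receives a reproducible
#'   sub-seed so any replicate can be regenerated in isolation.
#' @param continuity Haldane-Anscombe continuity constant `h >= 0` added to
#'   every cell of the pooled allele table (default 0.5).
#' @param finite_replication `NULL` for the analytic infinite-replication
#'   log odds-ratios (default), or a per-arm sample size to instead draw a
#'   finite replication study and use Haldane-corrected count estimates.
#' @return Object of class `curse_config`.
#' @export
curse_config <- function(n_cases = 50, n_controls = 50, prevalence = 0.05,
                         k_snps = 125, maf = 0.002, mu = 0, sigma = 1,
                         replicates = 2000, seed = 1, continuity = 0.5,
                         finite_replication = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            prevalence > 0, prevalence < 1,
            k_snps >= 1, sigma >= 0, replicates >= 1, continuity >= 0)
  if (!inherits(maf, "maf_spectrum"))
    stopifnot(is.numeric(maf), length(maf) == 1L, maf > 0, maf < 0.5)
  if (!is.null(finite_replication))
    stopifnot(finite_replication >= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 prevalence = prevalence, k_snps = k_snps, maf = maf,
                 mu = mu, sigma = sigma, replicates = replicates,
                 seed = as.integer(seed), continuity = continuity,
                 finite_replication = finite_replication),
            class = "curse_config")
}

#' Simulate one sequencing case-control replicate
#'
#' Draws `k_snps` log odds-ratios from the effect distribution, computes
#' each SNP's exact case and control allele frequencies under its logistic
#' disease model, and draws minor-allele counts
#' `Binomial(2 n_cases, p_case)` and `Binomial(2 n_controls, p_ctrl)`
#' independently per SNP. A SNP is *discovered* when its total count is at
#' least one. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param config A [curse_config()].
#' @return List of class `replicate_record` with per-SNP vectors
#'   `true_lor`, `maf`, `p_case`, `p_ctrl`, `case_count`, `control_count`,
#'   `discovered`, plus the design fields needed by the estimators.
#' @export
simulate_replicate <- function(config) {
  stopifnot(inherits(config, "curse_config"))
  k <- config$k_snps
  beta <- stats::rnorm(k, config$mu, config$sigma)
  p <- if (inherits(config$maf, "maf_spectrum"))
    sample_mafs(config$maf, k) else rep(config$maf, k)
  f <- case_control_freqs_vec(p, beta, config$prevalence)
  case_count <- stats::rbinom(k, 2L * config$n_cases, f$p_case)
  control_count <- stats::rbinom(k, 2L * config$n_controls, f$p_ctrl)
  structure(list(true_lor = beta, maf = p,
                 p_case = f$p_case, p_ctrl = f$p_ctrl,
                 case_count = case_count, control_count = control_count,
                 discovered = (case_count + control_count) >= 1L,
                 n_cases = config$n_cases, n_controls = config$n_controls),
            class = "replicate_record")
}

#' Pooled super-SNP log odds-ratio estimate from a replicate
#'
#' Pools the minor-allele counts of the discovered SNPs into a single 2x2
#' allele table (allele vs non-allele chromosomes, cases vs controls) and
#' returns its Haldane-corrected log odds-ratio:
#' `log(((A_case + h) / (2 n_cases d - A_case + h)) /
#'      ((A_ctrl + h) / (2 n_ctrl d - A_ctrl + h)))`
#' over the `d` discovered SNPs. The continuity constant is added to all
#' four cells unconditionally so that replicate means are always defined.
#'
#' @param record A `replicate_record` from [simulate_replicate()].
#' @param continuity Haldane-Anscombe constant `h >= 0`.
#' @return Scalar estimate, or `NA` when no SNP was discovered.
#' @export
pooled_lor_estimate <- function(record, continuity = 0.5) {
  stopifnot(inherits(record, "replicate_record"), continuity >= 0)
  d <- sum(record$discovered)
  if (d == 0L) return(NA_real_)
  h <- continuity
  a_case <- sum(record$case_count[record$discovered])
  a_ctrl <- sum(record$control_count[record$discovered])
  log(((a_case + h) / (2 * record$n_cases * d - a_case + h)) /
      ((a_ctrl + h) / (2 * record$n_controls * d - a_ctrl + h)))
}

#' Infinite-replication log odds-ratios of discovered and novel SNP pools
#'
#' For each pool S (the SNPs discovered in the original study; the novel,
#' i.e. undiscovered, SNPs), computes the per-allele log odds-ratio a
#' replication sample of unbounded size would estimate for the pooled
#' super-SNP: with `f_case` and `f_ctrl` the means of the per-SNP
#' population case/control allele frequencies over S,
#' `log(f_case (1 - f_ctrl) / (f_ctrl (1 - f_case)))`.
#'
#' @param record A `replicate_record`.
#' @return List with `lor_discovered`, `lor_novel` (`NA` when the
#'   corresponding pool is empty).
#' @export
replication_lors <- function(record) {
  stopifnot(inherits(record, "replicate_record"))
  pool_lor <- function(sel) {
    if (!any(sel)) return(NA_real_)
    fc <- mean(record$p_case[sel]); ft <- mean(record$p_ctrl[sel])
    log(fc * (1 - ft) / (ft * (1 - fc)))
  }
  list(lor_discovered = pool_lor(record$discovered),
       lor_novel = pool_lor(!record$discovered))
}

# Finite replication study: redraw counts at the population frequencies and
# apply the pooled Haldane estimator to each pool. Verification mode for
# replication_lors().
finite_replication_lors <- function(record, n_per_arm, continuity = 0.5) {
  k <- length(record$true_lor)
  cc <- stats::rbinom(k, 2L * n_per_arm, record$p_case)
  tc <- stats::rbinom(k, 2L * n_per_arm, record$p_ctrl)
  h <- continuity
  pool <- function(sel) {
    d <- sum(sel)
    if (d == 0L) return(NA_real_)
    a <- sum(cc[sel]); b <- sum(tc[sel])
    log(((a + h) / (2 * n_per_arm * d - a + h)) /
        ((b + h) / (2 * n_per_arm * d - b + h)))
  }
  list(lor_discovered = pool(record$discovered),
       lor_novel = pool(!record$discovered))
}

#' Run the winner's-curse simulation
#'
#' Runs `replicates` seeded replicates of [simulate_replicate()] and
#' aggregates four summaries: the fraction of SNPs discovered, the pooled
#' in-study super-SNP estimate over discovered SNPs, and the
#' (infinite-sample) replication log odds-ratios of the discovered and
#' novel pools. Replicates with an empty discovered (or novel) pool are
#' excluded from the affected mean and counted in `n_degenerate`.
#'
#' @param config A [curse_config()].
#' @return Object of class `curse_summary` with fields
#'   `mean_discovery_fraction`, `mean_pooled_estimate`,
#'   `mean_replication_lor_discovered`, `mean_replication_lor_novel`, their
#'   Monte-Carlo standard errors (`*_se`), `n_replicates_used`,
#'   `n_degenerate`.
#' @examples
#' \donttest{
#' summary <- run_winners_curse(curse_config(replicates = 200, seed = 7))
#' summary$mean_discovery_fraction   # about 0.36
#' }
#' @export
run_winners_curse <- function(config) {
  stopifnot(inherits(config, "curse_config"))
  R <- config$replicates
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, R)
  disc <- pooled <- rd <- rn <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    set.seed(sub_seeds[r])
    rec <- simulate_replicate(config)
    disc[r] <- mean(rec$discovered)
    pooled[r] <- pooled_lor_estimate(rec, config$continuity)
    rl <- if (is.null(config$finite_replication))
      replication_lors(rec)
    else
      finite_replication_lors(rec, config$finite_replication,
                              config$continuity)
    rd[r] <- rl$lor_discovered
    rn[r] <- rl$lor_novel
  }
  if (all(is.na(pooled)) && all(is.na(rn)))
    stop("all replicates degenerate: no SNPs discovered and none novel")
  mse <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  structure(list(
    mean_discovery_fraction = mean(disc),
    discovery_fraction_se = mse(disc),
    mean_pooled_estimate = mean(pooled, na.rm = TRUE),
    pooled_estimate_se = mse(pooled),
    mean_replication_lor_discovered = mean(rd, na.rm = TRUE),
    replication_lor_discovered_se = mse(rd),
    mean_replication_lor_novel = mean(rn, na.rm = TRUE),
    replication_lor_novel_se = mse(rn),
    n_replicates_used = R,
    n_degenerate = sum(is.na(pooled)) + sum(is.na(rn)),
    config = config),
    class = "curse_summary")
}

#' @export
print.curse_summary <- function(x, ...) {
  cat("Winner's-curse simulation (", x$n_replicates_used,
      " replicates, ", x$n_degenerate, " degenerate pools)\n", sep = "")
  line <- function(lbl, m, s)
    cat(sprintf("  %-34s %8.4f (mc se %.4f)\n", lbl, m, s))
  line("discovery fraction", x$mean_discovery_fraction,
       x$discovery_fraction_se)
  line("pooled in-study lOR (discovered)", x$mean_pooled_estimate,
       x$pooled_estimate_se)
  line("replication lOR, discovered pool",
       x$mean_replication_lor_discovered, x$replication_lor_discovered_se)
  line("replication lOR, novel pool",
       x$mean_replication_lor_novel, x$replication_lor_novel_se)
  invisible(x)
}
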
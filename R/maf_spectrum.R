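#' Minor allele frequency spectrum with polymorphism ascertainment
#'
#' Describes the MAF distribution of the SNPs entering a rare-variant
#' analysis. Two kinds are supported: a truncated Beta density (the
#' parametric surrogate for the low-frequency end of a population
#' site-frequency spectrum) and an empirical list of frequencies. In both
#' cases the distribution can be conditioned on the SNP being *polymorphic*
#' in a sequencing sample of `A` chromosomes, i.e. reweighted by the
#' probability \eqn{w(p) = 1 - (1 - p)^A} that at least one copy of the
#' minor allele is seen among `A` independently drawn chromosomes.
#'
#' The defaults -- Beta(0.14, 0.73) truncated at MAF 0.01 and ascertained in
#' 20,000 chromosomes (10,000 sequenced subjects) -- describe a European-like
#' rare-variant spectrum restricted to SNPs with MAF below 1%.
#'
#' @param kind `"parametric_beta"` or `"empirical"`.
#' @param beta_a,beta_b Shape parameters of the Beta density (used by the
#'   parametric kind). Both must be positive.
#' @param max_maf Truncation point; only frequencies in `(0, max_maf]` are
#'   retained. Must lie in `(0, 0.5]`.
#' @param ascertainment_chromosomes Integer `A >= 0`, the number of sequenced
#'   chromosomes defining the polymorphism condition. `0` disables
#'   ascertainment. For `N` diploid subjects use `A = 2 N`.
#' @param maf_values Numeric vector of frequencies in `(0, max_maf]`
#'   (empirical kind only).
#' @return An object of class `maf_spectrum`.
#' @seealso [spectrum_moments()], [ascertained_density()], [sample_mafs()]
#' @examples
#' sp <- maf_spectrum()                       # the default rare-variant spectrum
#' spectrum_moments(sp)$maf_factor            # ~0.047
#' @export
maf_spectrum <- function(kind = c("parametric_beta", "empirical"),
                         beta_a = 0.14, beta_b = 0.73, max_maf = 0.01,
                         ascertainment_chromosomes = 20000L,
                         maf_values = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(beta_a), length(beta_a) == 1L, beta_a > 0,
            is.numeric(beta_b), length(beta_b) == 1L, beta_b > 0,
            is.numeric(max_maf), length(max_maf) == 1L,
            max_maf > 0, max_maf <= 0.5,
            length(ascertainment_chromosomes) == 1L,
            ascertainment_chromosomes >= 0,
            ascertainment_chromosomes == round(ascertainment_chromosomes))
  if (kind == "empirical") {
    if (is.null(maf_values) || length(maf_values) == 0L)
      stop("empirical spectrum requires a non-empty 'maf_values'")
    if (any(!is.finite(maf_values)) || any(maf_values <= 0) ||
        any(maf_values > max_maf))
      stop("all 'maf_values' must lie in (0, max_maf]")
  } else if (!is.null(maf_values)) {
    stop("'maf_values' is only meaningful for the empirical kind")
  }
  structure(
    list(kind = kind, beta_a = beta_a, beta_b = beta_b, max_maf = max_maf,
         ascertainment_chromosomes = as.integer(ascertainment_chromosomes),
         maf_values = maf_values),
    class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  if (x$kind == "parametric_beta") {
    cat(sprintf("MAF spectrum: Beta(%g, %g) truncated at %g\n",
                x$beta_a, x$beta_b, x$max_maf))
  } else {
    cat(sprintf("MAF spectrum: empirical, %d frequencies, max %g\n",
                length(x$maf_values), x$max_maf))
  }
  cat(sprintf("  polymorphism ascertainment: %s\n",
              if (x$ascertainment_chromosomes > 0)
                sprintf("%d chromosomes", x$ascertainment_chromosomes)
              else "disabled"))
  invisible(x)
}

# Polymorphism weight: P(>= 1 minor allele among A chromosomes).
.poly_weight <- function(p, A) {
  if (A == 0) rep(1, length(p)) else 1 - (1 - p)^A
}

# Adaptive quadrature with an explicit failure instead of a silent value.
# The integrand p^(beta_a - 1) is singular but integrable at 0; integrate()
# handles the endpoint singularity.
.quad <- function(f, lower, upper, rel.tol = 1e-10) {
  res <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol,
                     subdivisions = 1000L, stop.on.error = FALSE),
    error = function(e) stop("quadrature failure: ", conditionMessage(e)))
  if (!res$message %in% c("OK", "roundoff error was detected"))
    stop("quadrature failure: ", res$message)
  res$value
}

# Unnormalized ascertained density of a parametric spectrum.
.spectrum_kernel <- function(spectrum) {
  a <- spectrum$beta_a; b <- spectrum$beta_b
  A <- spectrum$ascertainment_chromosomes
  function(p) stats::dbeta(p, a, b) * .poly_weight(p, A)
}

.spectrum_norm <- function(spectrum) {
  .quad(.spectrum_kernel(spectrum), 0, spectrum$max_maf)
}

#' Ascertained MAF density
#'
#' Normalized density of the spectrum's MAF distribution after truncation at
#' `max_maf` and reweighting by the polymorphism probability
#' \eqn{1 - (1-p)^A}. Zero outside `(0, max_maf]`.
#'
#' @param spectrum A [maf_spectrum()] of parametric kind.
#' @param p Numeric vector of frequencies.
#' @return Density values, same length as `p`.
#' @export
ascertained_density <- function(spectrum, p) {
  stopifnot(inherits(spectrum, "maf_spectrum"), is.numeric(p),
            all(is.finite(p)))
  if (spectrum$kind != "parametric_beta")
    stop("ascertained_density is defined for the parametric kind; ",
         "empirical spectra are weighted point masses")
  Z <- .spectrum_norm(spectrum)
  kern <- .spectrum_kernel(spectrum)
  out <- numeric(length(p))
  inside <- p > 0 & p <= spectrum$max_maf
  out[inside] <- kern(p[inside]) / Z
  out
}

#' Moments of the ascertained MAF distribution
#'
#' Computes the mean `e_m`, variance `v_m`, the genotype-variance scale
#' `e_m1m` = E\[M(1-M)\] = E_M - E_M^2 - V_M, and the NCP MAF factor
#' `maf_factor` = E_M / sqrt(E\[M(1-M)\]) that multiplies the burden-test
#' non-centrality parameter. `maf_factor_alt` uses the alternative
#' denominator V_M + E_M - E_M^2; the two differ by well under 1% for
#' spectra truncated at MAF 0.01. For small `max_maf` both are close to
#' sqrt(E_M).
#'
#' @param spectrum A [maf_spectrum()].
#' @return A list of class `spectrum_moments` with elements `e_m`, `v_m`,
#'   `e_m1m`, `maf_factor`, `maf_factor_alt`.
#' @examples
#' spectrum_moments(maf_spectrum())$maf_factor
#' # a single SNP at MAF 0.2 gives sqrt(0.2/0.8) = 0.5
#' sp <- maf_spectrum("empirical", max_maf = 0.5, ascertainment_chromosomes = 0,
#'                    maf_values = 0.2)
#' spectrum_moments(sp)$maf_factor
#' @export
spectrum_moments <- function(spectrum) {
  stopifnot(inherits(spectrum, "maf_spectrum"))
  if (spectrum$kind == "parametric_beta") {
    kern <- .spectrum_kernel(spectrum)
    Z <- .spectrum_norm(spectrum)
    e_m  <- .quad(function(p) p   * kern(p), 0, spectrum$max_maf) / Z
    e_m2 <- .quad(function(p) p^2 * kern(p), 0, spectrum$max_maf) / Z
  } else {
    p <- spectrum$maf_values
    w <- .poly_weight(p, spectrum$ascertainment_chromosomes)
    if (sum(w) <= 0) stop("all empirical weights are zero")
    e_m  <- sum(w * p)   / sum(w)
    e_m2 <- sum(w * p^2) / sum(w)
  }
  v_m   <- e_m2 - e_m^2
  e_m1m <- e_m - e_m2                    # = e_m - e_m^2 - v_m
  if (e_m1m <= 0) stop("degenerate spectrum: E[M(1-M)] <= 0")
  structure(
    list(e_m = e_m, v_m = v_m, e_m1m = e_m1m,
         maf_factor = e_m / sqrt(e_m1m),
         maf_factor_alt = e_m / sqrt(v_m + e_m - e_m^2)),
    class = "spectrum_moments")
}

#' @export
print.spectrum_moments <- function(x, ...) {
  cat(sprintf("E[M] = %.4g, V[M] = %.4g, E[M(1-M)] = %.4g\n",
              x$e_m, x$v_m, x$e_m1m))
  cat(sprintf("MAF factor E[M]/sqrt(E[M(1-M)]) = %.4g (alt %.4g)\n",
              x$maf_factor, x$maf_factor_alt))
  invisible(x)
}

#' Draw MAFs from an ascertained spectrum
#'
#' I.i.d. draws from the truncated, ascertainment-reweighted distribution.
#' Parametric spectra use inverse-CDF sampling from the truncated Beta
#' followed by rejection on the polymorphism weight; empirical spectra
#' resample `maf_values` with the polymorphism weights.
#'
#' @param spectrum A [maf_spectrum()].
#' @param k Number of draws (`>= 0`).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `k` frequencies in `(0, max_maf]`.
#' @export
sample_mafs <- function(spectrum, k, seed = NULL) {
  stopifnot(inherits(spectrum, "maf_spectrum"),
            is.numeric(k), length(k) == 1L, k >= 0, k == round(k))
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(k)
  if (k == 0L) return(numeric(0))
  if (spectrum$kind == "empirical") {
    w <- .poly_weight(spectrum$maf_values, spectrum$ascertainment_chromosomes)
    return(sample(spectrum$maf_values, k, replace = TRUE, prob = w))
  }
  a <- spectrum$beta_a; b <- spectrum$beta_b
  Fmax <- stats::pbeta(spectrum$max_maf, a, b)
  A <- spectrum$ascertainment_chromosomes
  out <- numeric(0)
  while (length(out) < k) {
    m <- max(2L * (k - length(out)), 1000L)
    cand <- stats::qbeta(stats::runif(m) * Fmax, a, b)
    keep <- stats::runif(m) < .poly_weight(cand, A)
    out <- c(out, cand[keep])
  }
  out[seq_len(k)]
}

#' Read an empirical MAF list from a plain-text file
#'
#' One frequency per line, `.` decimal point; lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path File path.
#' @param max_maf,ascertainment_chromosomes Passed to [maf_spectrum()].
#' @return An empirical [maf_spectrum()].
#' @export
read_maf_file <- function(path, max_maf = 0.01,
                          ascertainment_chromosomes = 0L) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no MAF values in ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stop("non-numeric MAF line in ", path)
  maf_spectrum("empirical", max_maf = max_maf,
               ascertainment_chromosomes = ascertainment_chromosomes,
               maf_values = vals)
}
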
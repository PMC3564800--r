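# Instrumental-variable (Wald) ratio layer.
#
# The causal effect of the exposure on the outcome is estimated as the
# pooled allele-score association with the outcome divided by the pooled
# allele-score association with the exposure.  Both coefficients are on the
# percent scale, so the ratio reads as percent change in the outcome per
# percent change in the exposure (a ln-ln elasticity).  Its variance comes
# from a first-order Taylor expansion (delta method) with, by default, zero
# covariance between numerator and denominator.

.beta_se <- function(x) {
  x <- as.list(as.data.frame(x))
  if (is.null(x$beta) || is.null(x$se)) stop("need 'beta' and 'se'")
  list(beta = x$beta[[1]], se = x$se[[1]])
}

#' IV (Wald) ratio with Taylor-expansion variance
#'
#' @param num Pooled gene-outcome association (a `meta_estimate`, an
#'   `assoc_estimate`, or any list/data.frame with `beta` and `se`).
#' @param den Pooled gene-exposure association, same form; `den$beta` must be
#'   nonzero.
#' @param cov_num_den Optional covariance between the two coefficients
#'   (default 0; the numerator and denominator are typically estimated from
#'   overlapping samples but the standard ratio variance ignores the
#'   covariance, which can be supplied here when known).
#' @param numerator_ref,denominator_ref Labels recorded in the result.
#' @return One-row `data.frame` of class `iv_result` with `ratio, se,
#'   ci_low, ci_high, p, weak_denominator, numerator_ref, denominator_ref`.
#'   A denominator with |beta|/se < 2 sets `weak_denominator = TRUE` and
#'   raises a warning; the estimator is not switched.
#' @export
#' @examples
#' iv_ratio(list(beta = -0.06, se = 0.0204), list(beta = 0.14, se = 0.0102))
iv_ratio <- function(num, den, cov_num_den = 0,
                     numerator_ref = "outcome", denominator_ref = "exposure") {
  nu <- .beta_se(num); de <- .beta_se(den)
  if (de$beta == 0) stop("undefined IV ratio: denominator association is zero")
  ratio <- nu$beta / de$beta
  v <- nu$se^2 / de$beta^2 +
    nu$beta^2 * de$se^2 / de$beta^4 -
    2 * nu$beta * cov_num_den / de$beta^3
  if (v <= 0) stop("non-positive ratio variance; check cov_num_den")
  se <- sqrt(v)
  weak <- abs(de$beta) / de$se < 2
  if (weak) warning("weak denominator: |beta|/se < 2 for the gene-exposure association")
  z <- stats::qnorm(0.975)
  out <- data.frame(
    ratio = ratio, se = se,
    ci_low = ratio - z * se, ci_high = ratio + z * se,
    p = 2 * stats::pnorm(-abs(ratio / se)),
    weak_denominator = weak,
    numerator_ref = numerator_ref, denominator_ref = denominator_ref,
    stringsAsFactors = FALSE
  )
  class(out) <- c("iv_result", "data.frame")
  out
}

#' Instrument strength F-statistic
#'
#' Approximates the first-stage F-statistic from the fraction of phenotype
#' variance explained by the allele score: F = R^2 (n - 2) / (1 - R^2).
#' Values above 10 conventionally indicate a non-weak instrument.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size (> 2).
#' @return The F-statistic.
#' @export
#' @examples
#' instrument_f(0.0097, 32391)
instrument_f <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= 2)) stop("n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Combine per-SNP summary statistics into an allele-score estimate
#'
#' Approximation for forming a score-level association when only per-SNP
#' summary statistics are available: each SNP's coefficient and standard
#' error are rescaled to the per-score-unit scale by dividing by its
#' predefined weight (unit weights for unweighted scores), then pooled by
#' inverse-variance fixed-effects meta-analysis.
#'
#' @param per_snp `data.frame` with columns `beta` and either `se` or
#'   `ci_low`/`ci_high` (converted via [ci_to_se()]), one row per SNP.
#' @param weights Per-SNP positive weights (default all 1).
#' @return One-row `data.frame` with `beta, se, ci_low, ci_high, p, k`.
#' @export
#' @examples
#' # published per-SNP associations of the two metabolism-score SNPs with
#' # BMI (kg/m^2), from a large anthropometric GWAS consortium
#' ss <- read.delim(system.file("extdata", "vitd_snp_bmi_summary.tsv",
#'                              package = "scoremr"))
#' summary_score(ss[ss$gene %in% c("GC", "CYP24A1"), ])
summary_score <- function(per_snp, weights = rep(1, nrow(per_snp))) {
  per_snp <- as.data.frame(per_snp)
  if (nrow(per_snp) < 1) stop("need at least one SNP")
  if (length(weights) != nrow(per_snp) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("weights must be positive, one per SNP")
  }
  se <- if ("se" %in% names(per_snp)) per_snp$se else
    ci_to_se(per_snp$ci_low, per_snp$ci_high)
  if (any(se <= 0)) stop("per-SNP standard errors must be positive")
  b <- per_snp$beta / weights
  s <- se / weights
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  z <- stats::qnorm(0.975)
  data.frame(beta = beta, se = se_pool,
             ci_low = beta - z * se_pool, ci_high = beta + z * se_pool,
             p = 2 * stats::pnorm(-abs(beta / se_pool)),
             k = nrow(per_snp))
}

#' Rescale an IV ratio to percent change per 10% exposure increase
#'
#' Linear (x10) rescaling of the elasticity and its confidence limits, the
#' convention used for reading ln-ln ratios as "per 10% increase".
#'
#' @param iv An [iv_ratio()] result.
#' @return The `iv_result` with `ratio`, `se`, `ci_low`, `ci_high`
#'   multiplied by 10 (p-value unchanged).
#' @export
percent_change_per_10pct <- function(iv) {
  stopifnot(inherits(iv, "iv_result"))
  iv$ratio <- 10 * iv$ratio
  iv$se <- 10 * iv$se
  iv$ci_low <- 10 * iv$ci_low
  iv$ci_high <- 10 * iv$ci_high
  iv
}

# slope and standard error of y ~ x without lm overhead (complete data)
.fast_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- sum((x - mx) * (y - my)) / sxx
  rss <- sum((y - my - b * (x - mx))^2)
  list(beta = b, se = sqrt(rss / (n - 2) / sxx))
}

#' Power of IV regression by simulation
#'
#' Per replicate: an instrument score S ~ N(0,1) is drawn for `n` subjects;
#' the (standardized ln-scale) exposure is built so the score explains
#' `instrument_r2` of its variance; the outcome mean is shifted by `effect`
#' ln-units per decile of the exposure (decile rank minus its mean), with
#' N(0, resid_sd^2) residual noise.  The gene-outcome and gene-exposure
#' slopes are then combined with [iv_ratio()] and power is the fraction of
#' replicates with p below `alpha`.
#'
#' @param effect Outcome shift in ln-units per exposure decile (e.g. 0.02).
#' @param n Subjects per replicate.
#' @param instrument_r2 Variance of the exposure explained by the score,
#'   in (0, 1).
#' @param resid_sd Residual SD of the ln outcome (default 0.45, typical of
#'   ln 25(OH)D).
#' @param alpha Significance level (default 0.05).
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return A list of class `power_result`: `effect, n, instrument_r2, alpha,
#'   reps, power, mc_se` with Monte Carlo standard error
#'   sqrt(power (1 - power) / reps).
#' @export
iv_power <- function(effect, n, instrument_r2, resid_sd = 0.45,
                     alpha = 0.05, reps = 1000, seed = 1) {
  if (reps < 100) stop("reps must be at least 100")
  if (instrument_r2 <= 0 || instrument_r2 >= 1) {
    stop("instrument_r2 must lie strictly in (0, 1)")
  }
  if (resid_sd <= 0) stop("resid_sd must be positive")
  hits <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      S <- stats::rnorm(n)
      X <- sqrt(instrument_r2) * S + sqrt(1 - instrument_r2) * stats::rnorm(n)
      dec <- ceiling(10 * rank(X, ties.method = "first") / n)
      Y <- effect * (dec - mean(dec)) + stats::rnorm(n, 0, resid_sd)
      den <- .fast_slope(S, X)
      num <- .fast_slope(S, Y)
      iv <- suppressWarnings(iv_ratio(num, den))
      iv$p < alpha
    }, NA)
  })
  power <- mean(hits)
  structure(list(effect = effect, n = n, instrument_r2 = instrument_r2,
                 alpha = alpha, reps = reps, power = power,
                 mc_se = sqrt(power * (1 - power) / reps)),
            class = "power_result")
}
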
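#' Run code with a temporary RNG seed
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library functions do not disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Convert a 95% confidence interval to a standard error
#'
#' Inverts the normal-theory interval `beta +/- 1.959964 * se`; used when
#' published tables print confidence limits rather than standard errors.
#'
#' @param ci_low,ci_high Interval bounds.
#' @return Standard error (same units as the bounds).
#' @export
#' @examples
#' ci_to_se(-0.71, -0.13)
ci_to_se <- function(ci_low, ci_high) {
  if (any(ci_high <= ci_low)) stop("ci_high must exceed ci_low")
  (ci_high - ci_low) / (2 * stats::qnorm(0.975))
}

#' Format an estimate preserving signed zero
#'
#' Report tables print ratios to two decimals and keep the sign of values
#' that round to zero (e.g. "-0.00"), so that the direction of a null-ish
#' estimate remains visible.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Character vector.
#' @export
format_estimate <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f"), x)
}

# derive a child seed for sub-stream i from a master seed; kept < 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 104729 * as.double(i)) %% 2147483629)
}
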
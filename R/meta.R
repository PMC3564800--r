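# Inverse-variance pooling of per-cohort coefficients.
#
# Fixed-effects weights are 1/se^2.  Between-study variance tau^2 uses the
# DerSimonian-Laird moment estimator; the pooled model is selected by
# Cochran's Q: random effects when p_Q < alpha_het (default 0.05, strict
# inequality), fixed effects otherwise.  All confidence intervals are 95%
# normal-theory and all coefficients stay on the percent scale.

.check_estimates <- function(estimates) {
  est <- as.data.frame(estimates)
  if (!all(c("beta", "se") %in% names(est))) {
    stop("estimates need 'beta' and 'se' columns")
  }
  if (nrow(est) < 2) stop("insufficient studies: meta-analysis needs k >= 2")
  if (any(!is.finite(est$beta)) || any(!is.finite(est$se)) || any(est$se <= 0)) {
    stop("estimates must have finite beta and positive se")
  }
  est
}

.meta_estimate <- function(beta, se, k, Q, p_Q, i2, tau2, model) {
  z <- stats::qnorm(0.975)
  out <- data.frame(
    beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    k = k, Q = Q, p_Q = p_Q, i2 = i2, tau2 = tau2, model = model,
    stringsAsFactors = FALSE
  )
  class(out) <- c("meta_estimate", "data.frame")
  out
}

#' Cochran's Q heterogeneity diagnostics
#'
#' @param estimates `data.frame` (or list coercible to one) with columns
#'   `beta` and `se`, one row per study.
#' @return List with `Q`, `p_Q` (chi-square on k-1 df) and `i2` (percent,
#'   clamped to \[0, 100\]).
#' @export
heterogeneity <- function(estimates) {
  est <- .check_estimates(estimates)
  w <- 1 / est$se^2
  b_fix <- sum(w * est$beta) / sum(w)
  Q <- sum(w * (est$beta - b_fix)^2)
  k <- nrow(est)
  list(Q = Q,
       p_Q = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
       i2 = if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' @inheritParams heterogeneity
#' @return A one-row `meta_estimate` data frame with the pooled coefficient,
#'   its standard error, 95% CI, p-value and heterogeneity diagnostics.
#' @export
#' @examples
#' fixed_effects(data.frame(beta = c(1, 3), se = c(1, 1)))
fixed_effects <- function(estimates) {
  est <- .check_estimates(estimates)
  w <- 1 / est$se^2
  het <- heterogeneity(est)
  .meta_estimate(beta = sum(w * est$beta) / sum(w), se = sqrt(1 / sum(w)),
                 k = nrow(est), Q = het$Q, p_Q = het$p_Q, i2 = het$i2,
                 tau2 = 0, model = "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w))) with fixed-effects
#' weights w = 1/se^2; studies are then re-weighted by 1/(se^2 + tau^2).  When
#' Q <= k-1 the estimator returns tau^2 = 0 and coincides with
#' [fixed_effects()].
#'
#' @inheritParams heterogeneity
#' @return A one-row `meta_estimate` data frame (`model = "random"`).
#' @export
dersimonian_laird <- function(estimates) {
  est <- .check_estimates(estimates)
  w <- 1 / est$se^2
  k <- nrow(est)
  het <- heterogeneity(est)
  tau2 <- max(0, (het$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (est$se^2 + tau2)
  .meta_estimate(beta = sum(w_star * est$beta) / sum(w_star),
                 se = sqrt(1 / sum(w_star)),
                 k = k, Q = het$Q, p_Q = het$p_Q, i2 = het$i2,
                 tau2 = tau2, model = "random")
}

#' Pool with heterogeneity-based model selection
#'
#' Runs the heterogeneity test and returns the random-effects pooled estimate
#' when `p_Q < alpha_het` (strict), the fixed-effects estimate otherwise; the
#' `model` column records the choice.
#'
#' @inheritParams heterogeneity
#' @param alpha_het Heterogeneity significance threshold (default 0.05).
#' @return A one-row `meta_estimate` data frame.
#' @export
pool <- function(estimates, alpha_het = 0.05) {
  het <- heterogeneity(estimates)
  if (het$p_Q < alpha_het) dersimonian_laird(estimates) else fixed_effects(estimates)
}

#' Univariate meta-regression on a study-level factor
#'
#' Weighted least squares of the per-study coefficients on a study-level
#' covariate, with weights 1/(se^2 + residual tau^2) and residual tau^2 by
#' the method of moments (metafor's `rma(..., method = "DL")`).  Inference is
#' by normal approximation.  Categorical covariates are expanded to
#' indicators against an explicitly supplied reference level.
#'
#' @inheritParams heterogeneity
#' @param covariate Per-study values (numeric, or character/factor for a
#'   categorical factor).
#' @param reference Reference level, required for categorical covariates.
#' @return `data.frame` with one row per contrast: `term, slope, se, ci_low,
#'   ci_high, z, p`, with residual `tau2` attached as an attribute.
#' @export
meta_regression <- function(estimates, covariate, reference = NULL) {
  est <- .check_estimates(estimates)
  if (length(covariate) != nrow(est)) {
    stop("covariate must have one value per study")
  }
  if (is.character(covariate) || is.factor(covariate)) {
    covariate <- factor(covariate)
    if (nlevels(covariate) < 2) stop("no contrast: covariate is constant across studies")
    if (is.null(reference)) {
      stop("categorical meta-regression requires an explicit reference level")
    }
    covariate <- stats::relevel(covariate, ref = reference)
    ncontrast <- nlevels(covariate) - 1
  } else {
    if (stats::sd(covariate) == 0) stop("no contrast: covariate is constant across studies")
    ncontrast <- 1
  }
  if (nrow(est) < ncontrast + 2) stop("too few studies for this many contrasts")
  fit <- metafor::rma(yi = est$beta, sei = est$se, mods = ~covariate,
                      method = "DL", test = "z")
  keep <- rownames(fit$beta) != "intrcpt"
  out <- data.frame(
    term = sub("^covariate", "", rownames(fit$beta)[keep]),
    slope = as.vector(fit$beta)[keep],
    se = fit$se[keep],
    ci_low = fit$ci.lb[keep],
    ci_high = fit$ci.ub[keep],
    z = fit$zval[keep],
    p = fit$pval[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "tau2") <- fit$tau2
  out
}

#' Multivariate (bivariate) fixed-effects meta-analysis
#'
#' Generalised-least-squares pooling of per-study coefficient pairs using the
#' within-study covariance matrices: pooled vector
#' (sum C_i^-1)^-1 sum(C_i^-1 b_i) with covariance (sum C_i^-1)^-1, plus a
#' 2-df Wald test of the joint null.
#'
#' @param bivariate List of [joint_score_association()] results (or lists
#'   with elements `beta` (length 2) and `cov` (2x2)).
#' @return List with `beta` (pooled pair), `vcov` (2x2), `components`
#'   (per-component `meta_estimate` rows), `joint_p`, `k`.
#' @export
multivariate_pool <- function(bivariate) {
  if (length(bivariate) < 2) stop("insufficient studies: need k >= 2")
  usable <- vapply(bivariate, function(s) {
    C <- s$cov
    ok <- is.matrix(C) && all(dim(C) == 2) && all(is.finite(C)) &&
      isTRUE(all.equal(C, t(C), tolerance = 1e-8))
    if (ok) {
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      ok <- all(ev > 0)
    }
    ok
  }, NA)
  if (any(!usable)) {
    warning(sum(!usable), " stud(ies) dropped: singular or invalid covariance")
  }
  bivariate <- bivariate[usable]
  if (length(bivariate) < 1) stop("all within-study covariance matrices singular")

  Sinv <- matrix(0, 2, 2)
  Sb <- c(0, 0)
  for (s in bivariate) {
    Ci <- solve(s$cov)
    Sinv <- Sinv + Ci
    Sb <- Sb + Ci %*% s$beta
  }
  V <- solve(Sinv)
  b <- as.vector(V %*% Sb)
  names(b) <- names(bivariate[[1]]$beta)
  se <- sqrt(diag(V))
  k <- length(bivariate)
  comps <- do.call(rbind, lapply(1:2, function(j) {
    .meta_estimate(beta = b[j], se = se[j], k = k,
                   Q = NA_real_, p_Q = NA_real_, i2 = NA_real_,
                   tau2 = 0, model = "fixed_mv")
  }))
  comps$term <- names(b)
  wald <- as.vector(t(b) %*% solve(V) %*% b)
  list(beta = b, vcov = V, components = comps,
       joint_p = stats::pchisq(wald, df = 2, lower.tail = FALSE), k = k)
}
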
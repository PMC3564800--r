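# Per-cohort covariate-adjusted associations on the percent scale.
#
# Outcomes are natural-log transformed before regression; multiplying the
# resulting coefficients by 100 lets them be read as percent difference in
# the outcome per unit of the exposure.  Models with 25(OH)D as the outcome
# are additionally adjusted for month of blood draw as a categorical
# variable, which absorbs seasonal variation of any smooth shape.

# build the covariate part of the model frame; month and sex become factors
.covariate_frame <- function(table, covariates) {
  if (length(covariates) == 0) return(NULL)
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop("covariate column(s) not found: ",
                         paste(miss, collapse = ", "))
  cf <- table[, covariates, drop = FALSE]
  for (v in intersect(c("month", "sex"), covariates)) cf[[v]] <- factor(cf[[v]])
  drop <- vapply(cf, function(x) is.factor(x) && nlevels(droplevels(factor(x))) < 2,
                 NA)
  if (any(drop)) {
    warning("dropping degenerate covariate(s) with a single level: ",
            paste(names(cf)[drop], collapse = ", "))
    cf <- cf[, !drop, drop = FALSE]
    if (ncol(cf) == 0) cf <- NULL
  }
  cf
}

#' Covariate-adjusted percent-scale association in one cohort
#'
#' Fits OLS of `ln(outcome)` on the exposure plus covariates and returns the
#' exposure coefficient and standard error multiplied by 100 (percent
#' difference in the outcome per unit exposure).
#'
#' @param table Cohort table.
#' @param outcome Name of a strictly positive column (e.g. `"vitd"` or
#'   `"bmi"`); it is ln-transformed internally.
#' @param exposure Either the name of a column (e.g. `"bmi"` for the
#'   observational model) or a numeric vector of per-subject values (e.g. an
#'   allele score), in which case `exposure_label` names it.
#' @param covariates Character vector of covariate columns; `"month"` and
#'   `"sex"` are expanded to indicator variables.  Covariates with a single
#'   observed level (e.g. month in a cohort sampled once) are dropped with a
#'   warning.
#' @param exposure_label Label used when `exposure` is a vector.
#' @param cohort Cohort label (defaults to the table's `"cohort"` attribute).
#' @return One-row `data.frame` of class `assoc_estimate` with columns
#'   `cohort, outcome, exposure, beta, se, n, covariates`.
#' @export
#' @examples
#' panel <- make_snp_panel(seed = 1)
#' tab <- simulate_cohort(cohort_spec("demo", 500), panel, true_model(), seed = 2)
#' adjusted_percent_association(tab, "vitd", "bmi",
#'                              covariates = c("age", "sex", "month"))
adjusted_percent_association <- function(table, outcome, exposure,
                                         covariates = character(),
                                         exposure_label = NULL,
                                         cohort = attr(table, "cohort")) {
  y_raw <- table[[outcome]]
  if (is.null(y_raw)) stop("outcome column '", outcome, "' not found")
  if (any(y_raw <= 0, na.rm = TRUE)) {
    stop("outcome '", outcome, "' must be strictly positive before ln-transform")
  }
  if (is.character(exposure) && length(exposure) == 1) {
    exposure_label <- exposure
    x <- table[[exposure]]
    if (is.null(x)) stop("exposure column '", exposure, "' not found")
  } else {
    x <- as.numeric(exposure)
    if (length(x) != nrow(table)) {
      stop("exposure vector length does not match the table")
    }
    if (is.null(exposure_label)) exposure_label <- "exposure"
  }

  mf <- data.frame(.y = log(y_raw), .x = x)
  cf <- .covariate_frame(table, covariates)
  if (!is.null(cf)) mf <- cbind(mf, cf)
  fit <- stats::lm(.y ~ ., data = mf, na.action = stats::na.omit)

  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(alias)[alias], collapse = ", "))
  }
  n_used <- stats::nobs(fit)
  if (n_used <= length(stats::coef(fit))) {
    stop("fewer observations than model parameters")
  }
  sm <- summary(fit)$coefficients
  out <- data.frame(
    cohort = if (is.null(cohort)) NA_character_ else cohort,
    outcome = outcome,
    exposure = exposure_label,
    beta = 100 * sm[".x", "Estimate"],
    se = 100 * sm[".x", "Std. Error"],
    n = n_used,
    covariates = paste(covariates, collapse = "+"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_estimate", "data.frame")
  out
}

#' Joint bivariate association of the two vitamin D scores with an outcome
#'
#' Fits `ln(outcome) ~ synthesis + metabolism + covariates` in one cohort and
#' returns both percent-scale coefficients with their within-study 2x2
#' covariance matrix, the input required by [multivariate_pool()].
#'
#' @inheritParams adjusted_percent_association
#' @param synthesis,metabolism Per-subject score vectors.
#' @return A list of class `bivariate_estimate` with elements `beta`
#'   (length-2 named vector), `cov` (2x2 matrix), `n`, `cohort`.
#' @export
joint_score_association <- function(table, outcome, synthesis, metabolism,
                                    covariates = character(),
                                    cohort = attr(table, "cohort")) {
  y_raw <- table[[outcome]]
  if (any(y_raw <= 0, na.rm = TRUE)) {
    stop("outcome '", outcome, "' must be strictly positive before ln-transform")
  }
  mf <- data.frame(.y = log(y_raw), .syn = synthesis, .met = metabolism)
  cf <- .covariate_frame(table, covariates)
  if (!is.null(cf)) mf <- cbind(mf, cf)
  fit <- stats::lm(.y ~ ., data = mf, na.action = stats::na.omit)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient bivariate design")
  idx <- c(".syn", ".met")
  structure(list(
    beta = stats::setNames(100 * stats::coef(fit)[idx],
                           c("synthesis", "metabolism")),
    cov = 100^2 * stats::vcov(fit)[idx, idx],
    n = stats::nobs(fit),
    cohort = if (is.null(cohort)) NA_character_ else cohort
  ), class = "bivariate_estimate")
}

#' Variance in a phenotype explained by an allele score
#'
#' Marginal (unadjusted) squared Pearson correlation between the score and
#' the ln-scale phenotype, the quantity entering the instrument F-statistic.
#'
#' @param score Per-subject score values.
#' @param ln_phenotype Per-subject ln-phenotype values.
#' @return R-squared as a fraction in \[0, 1\].
#' @export
variance_explained <- function(score, ln_phenotype) {
  ok <- stats::complete.cases(score, ln_phenotype)
  if (sum(ok) <= 2) stop("need more than 2 complete observations")
  if (stats::sd(score[ok]) == 0) stop("undefined R-squared: score has zero variance")
  stats::cor(score[ok], ln_phenotype[ok])^2
}
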
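# Synthetic individual-level cohort generator.
#
# Genotypes are drawn per SNP as Binomial(2, eaf) (Hardy-Weinberg, linkage
# equilibrium across SNPs).  Phenotypes live on the natural-log scale:
#
#   ln BMI     = a_b + shift_b + G_b + c_b U + delta * x_v + e_b
#   ln 25(OH)D = a_v + shift_v + G_v + M + c_v U + gamma * x_b + e_v
#
# where G are the per-allele genetic sums (panel weight / 100 per effect
# allele), U ~ N(0,1) is a shared confounder, M is a cosine seasonal term on
# month of blood draw, x_b / x_v are the phenotypes' deviations from their
# means, and e are cohort-specific residuals.  When both causal effects are
# nonzero the two-equation system is solved in reduced form, which requires
# |gamma * delta| < 1.  Age, sex and the principal-component columns are
# generated as covariates that do not enter the phenotype equations.

#' Simulate one cohort
#'
#' @param spec A [cohort_spec()].
#' @param panel An [make_snp_panel()] panel (or any `snp_panel`).
#' @param truth A [true_model()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `iid, age, sex, month, pc1..pck, bmi,
#'   vitd, ln_bmi, ln_vitd` and one genotype column per panel SNP (0-2 count
#'   of the effect allele; columns listed in `spec$missing_snps` are all
#'   `NA`).  The cohort name is attached as attribute `"cohort"`.
#' @export
#' @examples
#' panel <- make_snp_panel(seed = 1)
#' tab <- simulate_cohort(cohort_spec("demo", 200), panel, true_model(), seed = 7)
#' head(tab[, 1:8])
simulate_cohort <- function(spec, panel, truth, seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "true_model"),
            nrow(panel) > 0)
  if (!all(spec$missing_snps %in% panel$rsid)) {
    stop("missing_snps of cohort '", spec$name,
         "' contains rsids absent from the panel")
  }
  gd <- truth$gamma_bmi_to_vitd * truth$delta_vitd_to_bmi
  if (abs(gd) >= 1) {
    stop("non-invertible reduced form: |gamma * delta| = ", abs(gd), " >= 1")
  }
  n <- spec$n
  with_seed(seed, {
    g <- vapply(seq_len(nrow(panel)),
                function(j) stats::rbinom(n, 2L, panel$eaf[j]),
                integer(n))
    colnames(g) <- panel$rsid

    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    sex <- ifelse(stats::runif(n) < spec$prop_female, "F", "M")
    month <- sample.int(12L, n, replace = TRUE)
    pcs <- if (spec$n_pc > 0) {
      matrix(stats::rnorm(n * spec$n_pc), n, spec$n_pc,
             dimnames = list(NULL, paste0("pc", seq_len(spec$n_pc))))
    } else NULL

    U <- stats::rnorm(n)
    e_b <- stats::rnorm(n, 0, spec$resid_sd_lnbmi)
    e_v <- stats::rnorm(n, 0, spec$resid_sd_lnvitd)

    is_bmi <- panel$axis == "bmi"
    G_b <- as.vector(g[, is_bmi, drop = FALSE] %*% (panel$weight[is_bmi] / 100))
    G_v <- as.vector(g[, !is_bmi, drop = FALSE] %*% (panel$weight[!is_bmi] / 100))
    # centre the genetic sums so intercepts remain the phenotype means
    G_b <- G_b - sum(2 * panel$eaf[is_bmi] * panel$weight[is_bmi] / 100)
    G_v <- G_v - sum(2 * panel$eaf[!is_bmi] * panel$weight[!is_bmi] / 100)

    M <- spec$month_amplitude * cos(2 * pi * (month - spec$peak_month) / 12)

    A_b <- G_b + truth$confounder_effect_bmi * U + e_b
    A_v <- G_v + M + truth$confounder_effect_vitd * U + e_v
    x_b <- (A_b + truth$delta_vitd_to_bmi * A_v) / (1 - gd)
    x_v <- (A_v + truth$gamma_bmi_to_vitd * A_b) / (1 - gd)

    ln_bmi <- truth$intercept_lnbmi + spec$mean_shift_lnbmi + x_b
    ln_vitd <- truth$intercept_lnvitd + spec$mean_shift_lnvitd + x_v

    g[, colnames(g) %in% spec$missing_snps] <- NA_integer_

    out <- data.frame(
      iid = paste0(spec$name, "_", seq_len(n)),
      age = age, sex = sex, month = month,
      stringsAsFactors = FALSE
    )
    if (!is.null(pcs)) out <- cbind(out, as.data.frame(pcs))
    out <- cbind(out,
                 data.frame(bmi = exp(ln_bmi), vitd = exp(ln_vitd),
                            ln_bmi = ln_bmi, ln_vitd = ln_vitd),
                 as.data.frame(g))
    attr(out, "cohort") <- spec$name
    out
  })
}

#' Simulate a multi-cohort collaboration
#'
#' Cohorts are generated independently, each from a child seed derived
#' deterministically from the master seed, so the full collaboration is
#' reproducible and individual cohorts can be regenerated in isolation.
#'
#' @param specs List of [cohort_spec()] objects with unique names (>= 2).
#' @param panel Instrument panel.
#' @param truth A [true_model()].
#' @param seed Master integer seed.
#' @return Named list of cohort tables (see [simulate_cohort()]).
#' @export
simulate_collaboration <- function(specs, panel, truth, seed) {
  if (length(specs) < 2) stop("a collaboration needs at least 2 cohorts")
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) {
    stop("duplicate cohort names: ", paste(nm[duplicated(nm)], collapse = ", "))
  }
  out <- lapply(seq_along(specs), function(i) {
    simulate_cohort(specs[[i]], panel, truth, derive_seed(seed, i))
  })
  names(out) <- nm
  out
}

#' Write / read a cohort table as TSV
#'
#' UTF-8, tab-separated, header row; missing genotype cells empty.
#'
#' @param table Cohort `data.frame`.
#' @param path File path.
#' @param cohort Cohort name used when the attribute is absent (read only).
#' @export
write_cohort_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path, cohort = sub("\\.tsv$", "", basename(path))) {
  tab <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  stopifnot(all(c("ln_bmi", "ln_vitd", "bmi", "vitd", "month") %in% names(tab)))
  attr(tab, "cohort") <- cohort
  tab
}
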
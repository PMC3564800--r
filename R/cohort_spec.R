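#' Describe one cohort of a collaboration
#'
#' A cohort spec carries the design parameters the generator needs: size, sex
#' mix, age distribution, continent, assay label, which panel SNPs the cohort
#' lacks entirely, ln-scale residual SDs for the two phenotypes, the seasonal
#' amplitude of ln 25(OH)D, and optional shifts of the cohort's geometric
#' means away from the collaboration-wide intercepts.
#'
#' @param name Cohort label (unique within a collaboration).
#' @param n Number of subjects (>= 30).
#' @param prop_female Fraction of women in \[0, 1\].
#' @param age_mean,age_sd Age distribution in years.
#' @param continent `"europe"` or `"north_america"`.
#' @param assay 25(OH)D assay label (carried as a study-level covariate for
#'   meta-regression only; no assay error model is simulated).
#' @param missing_snps Character vector of panel rsids this cohort lacks;
#'   the corresponding genotype columns are emitted entirely missing.
#' @param resid_sd_lnbmi,resid_sd_lnvitd Residual SDs on the ln scale.
#' @param month_amplitude Amplitude of the cosine seasonal term on
#'   ln 25(OH)D (0.15 means roughly +/-15% peak-to-mean variation).
#' @param peak_month Month (1-12) at which 25(OH)D peaks; default 7 (summer).
#' @param mean_shift_lnbmi,mean_shift_lnvitd Cohort-specific shifts of the
#'   ln-phenotype means, used to emulate heterogeneous cohort means.
#' @param n_pc Number of principal-component noise covariates to emit.
#' @return A list of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec("demo", n = 1000, prop_female = 0.55)
cohort_spec <- function(name, n,
                        prop_female = 0.5,
                        age_mean = 50, age_sd = 10,
                        continent = c("europe", "north_america"),
                        assay = "RIA",
                        missing_snps = character(),
                        resid_sd_lnbmi = 0.16,
                        resid_sd_lnvitd = 0.42,
                        month_amplitude = 0.15,
                        peak_month = 7L,
                        mean_shift_lnbmi = 0,
                        mean_shift_lnvitd = 0,
                        n_pc = 2L) {
  continent <- match.arg(continent)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(n) || length(n) != 1 || n < 30) {
    stop("cohort size n must be at least 30")
  }
  stopifnot(prop_female >= 0, prop_female <= 1,
            age_sd > 0, resid_sd_lnbmi > 0, resid_sd_lnvitd > 0,
            month_amplitude >= 0, peak_month >= 1, peak_month <= 12,
            n_pc >= 0)
  structure(list(
    name = name, n = as.integer(n), prop_female = prop_female,
    age_mean = age_mean, age_sd = age_sd, continent = continent,
    assay = assay, missing_snps = as.character(missing_snps),
    resid_sd_lnbmi = resid_sd_lnbmi, resid_sd_lnvitd = resid_sd_lnvitd,
    month_amplitude = month_amplitude, peak_month = as.integer(peak_month),
    mean_shift_lnbmi = mean_shift_lnbmi,
    mean_shift_lnvitd = mean_shift_lnvitd,
    n_pc = as.integer(n_pc)
  ), class = "cohort_spec")
}

#' Define the causal truth of the simulated system
#'
#' The two ln-scale phenotypes are linked by a (possibly bi-directional)
#' linear structural model with a shared standard-normal confounder U:
#' ln BMI receives `confounder_effect_bmi * U` and
#' `delta_vitd_to_bmi * (ln 25(OH)D deviation)`; ln 25(OH)D receives
#' `confounder_effect_vitd * U`, a seasonal term, and
#' `gamma_bmi_to_vitd * (ln BMI deviation)`.  When both causal effects are
#' nonzero the system is solved in reduced form, which requires
#' `|gamma * delta| < 1`.
#'
#' Defaults encode the adiposity-to-vitamin-D scenario: an elasticity of
#' -0.42 (percent 25(OH)D per percent BMI) with no reverse effect, and mild
#' shared confounding whose loadings are chosen so that the observational
#' ln-ln association is attenuated relative to the causal elasticity (an
#' observational slope of roughly -1.15% per kg/m^2 against a causal
#' -1.58% per kg/m^2 at the reference BMI), the pattern the instrumental
#' analysis is designed to see through.
#'
#' @param gamma_bmi_to_vitd Causal effect of ln BMI on ln 25(OH)D
#'   (dimensionless elasticity).
#' @param delta_vitd_to_bmi Causal effect of ln 25(OH)D on ln BMI.
#' @param confounder_effect_bmi,confounder_effect_vitd ln-scale loadings of
#'   the shared standard-normal confounder.
#' @param intercept_lnbmi,intercept_lnvitd Baseline ln-phenotype means
#'   (defaults ln 26.5 kg/m^2 and ln 55 nmol/l).
#' @return A list of class `true_model`.
#' @export
true_model <- function(gamma_bmi_to_vitd = -0.42,
                       delta_vitd_to_bmi = 0,
                       confounder_effect_bmi = 0.06,
                       confounder_effect_vitd = 0.06,
                       intercept_lnbmi = log(26.5),
                       intercept_lnvitd = log(55)) {
  vals <- c(gamma_bmi_to_vitd, delta_vitd_to_bmi, confounder_effect_bmi,
            confounder_effect_vitd, intercept_lnbmi, intercept_lnvitd)
  if (any(!is.finite(vals))) stop("true_model parameters must be finite")
  structure(list(
    gamma_bmi_to_vitd = gamma_bmi_to_vitd,
    delta_vitd_to_bmi = delta_vitd_to_bmi,
    confounder_effect_bmi = confounder_effect_bmi,
    confounder_effect_vitd = confounder_effect_vitd,
    intercept_lnbmi = intercept_lnbmi,
    intercept_lnvitd = intercept_lnvitd
  ), class = "true_model")
}

#' Write / read a truth record
#'
#' The causal parameters used by a simulation are written as a YAML snippet
#' so that recovery tests can compare estimates against the generating truth.
#'
#' @param truth A [true_model()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  do.call(true_model, yaml::read_yaml(path))
}

#' Default 21-cohort collaboration template
#'
#' Cohort sizes, sex mix, ages, continents, geometric-mean shifts and
#' whole-SNP missingness patterns emulate a large trans-Atlantic vitamin D
#' collaboration of 21 adult cohorts totalling 42,024 subjects, including
#' three male-only and two female-only studies, five cohorts missing one to
#' three BMI SNPs, one cohort missing a synthesis-score SNP and one missing
#' one SNP from each vitamin D score.
#'
#' @return A list of 21 [cohort_spec()] objects.
#' @export
#' @examples
#' sum(vapply(default_cohort_specs(), function(s) s$n, 1))
default_cohort_specs <- function() {
  # name, n, prop_female, age_mean, age_sd, continent, assay, bmi_gm, vitd_gm
  tab <- list(
    list("study01", 7414, 0.50, 45.2,  0.4, "europe",        "ELISA", 26.9, 52.1),
    list("study02", 4453, 0.51, 31.1,  0.4, "europe",        "ELISA", 24.3, 63.2),
    list("study03", 5656, 0.53, 46.6, 13.1, "north_america", "RIA",   26.8, 69.7),
    list("study04", 3298, 0.30, 62.6, 10.6, "europe",        "RIA",   27.2, 37.3),
    list("study05", 1210, 0.52, 65.0,  2.6, "europe",        "RIA",   26.9, 41.7),
    list("study06", 2608, 0.50, 43.8, 12.2, "europe",        "ELISA", 26.1, 52.5),
    list("study07", 1984, 0.54, 37.6,  5.0, "europe",        "RIA",   25.5, 56.3),
    list("study08", 2297, 0.69, 64.3, 16.6, "north_america", "RIA",   26.8, 64.1),
    list("study09", 1930, 0.91, 51.2, 13.2, "europe",        "RIA",   25.3, 68.0),
    list("study10", 1558, 0.47, 74.8,  2.9, "north_america", "RIA",   26.3, 67.7),
    list("study11", 1245, 0.00, 63.8,  8.6, "north_america", "RIA",   25.5, 56.8),
    list("study12", 1094, 0.55, 68.3, 15.5, "europe",        "RIA",   26.8, 43.4),
    list("study13", 1194, 0.00, 71.0,  0.6, "europe",        "MS",    26.1, 65.8),
    list("study14",  999, 0.50, 70.2,  0.2, "europe",        "MS",    26.7, 54.3),
    list("study15",  921, 0.00, 18.9,  0.6, "europe",        "RIA",   22.1, 61.8),
    list("study16",  870, 1.00, 59.6,  5.8, "north_america", "RIA",   25.0, 74.4),
    list("study17",  821, 0.52, 50.7, 11.1, "europe",        "RIA",   25.0, 44.7),
    list("study18",  758, 0.57, 53.5,  7.7, "europe",        "MS",    25.5, 53.2),
    list("study19",  664, 0.49, 51.2,  5.1, "europe",        "RIA",   26.8, 34.3),
    list("study20",  720, 1.00, 56.5,  6.9, "north_america", "RIA",   27.1, 53.5),
    list("study21",  330, 0.57, 49.0, 13.9, "north_america", "RIA",   26.8, 53.8)
  )
  missing <- list(
    study03 = "rs7647305",                                  # 1 BMI SNP
    study05 = c("rs2867125", "rs4074134", "rs29941"),       # 3 BMI SNPs
    study12 = c("rs7498665", "rs10913469"),                 # 2 BMI SNPs
    study14 = c("rs7138803", "rs3101336"),                  # 2 BMI SNPs
    study13 = c("rs10838738", "rs10938397", "rs17782313"),  # 3 BMI SNPs
    study04 = "rs12785878",                                 # 1 synthesis SNP
    study18 = c("rs10741657", "rs6013897")                  # 1 from each vitD score
  )
  lapply(tab, function(r) {
    cohort_spec(
      name = r[[1]], n = r[[2]], prop_female = r[[3]],
      age_mean = r[[4]], age_sd = r[[5]], continent = r[[6]], assay = r[[7]],
      missing_snps = if (r[[1]] %in% names(missing)) missing[[r[[1]]]] else character(),
      mean_shift_lnbmi = log(r[[8]] / 26.5),
      mean_shift_lnvitd = log(r[[9]] / 55)
    )
  })
}
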
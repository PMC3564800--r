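# Instrument panel: 12 BMI-associated SNPs plus 4 vitamin D SNPs split into
# a "synthesis" axis (DHCR7, CYP2R1; upstream of 25(OH)D production) and a
# "metabolism" axis (GC, CYP24A1; transport/clearance).
#
# Effect-allele conventions: for BMI SNPs the effect allele is the
# BMI-raising allele (weight > 0); for vitamin D SNPs it is the
# 25(OH)D-lowering allele (weight < 0).  Weights are per-allele effects on
# the ln phenotype x100, i.e. percent per allele, and are used both as the
# simulation truth and as the score weights.

# relative per-allele effect shapes (percent per allele before calibration);
# BMI shapes follow the usual GWAS ordering with FTO largest.
.panel_base <- function() {
  data.frame(
    rsid = c("rs9939609", "rs17782313", "rs2867125", "rs7498665",
             "rs4074134", "rs29941", "rs7647305", "rs10913469",
             "rs7138803", "rs3101336", "rs10838738", "rs10938397",
             "rs12785878", "rs10741657", "rs2282679", "rs6013897"),
    gene = c("FTO", "MC4R", "TMEM18", "SH2B1", "BDNF", "KCTD15", "ETV5",
             "SEC16B", "FAIM2", "NEGR1", "MTCH2", "GNPDA2",
             "DHCR7", "CYP2R1", "GC", "CYP24A1"),
    axis = c(rep("bmi", 12),
             "vitd_synthesis", "vitd_synthesis",
             "vitd_metabolism", "vitd_metabolism"),
    base_weight = c(0.40, 0.23, 0.31, 0.15, 0.19, 0.06, 0.14, 0.22,
                    0.12, 0.13, 0.10, 0.18,
                    -3.5, -3.0, -5.5, -2.5),
    stringsAsFactors = FALSE
  )
}

#' Build the calibrated 16-SNP instrument panel
#'
#' Draws effect-allele frequencies and rescales the per-axis weights so that,
#' under the reference cohort model, the weighted BMI allele score and the
#' unweighted synthesis and metabolism scores explain the target fractions of
#' ln-phenotype variance (defaults 0.97%, 0.64% and 1.26%).
#'
#' The calibration is closed-form.  For a score S built from SNPs with
#' simulated per-allele effects c*b_i and Hardy-Weinberg genotype variance
#' v_i = 2 p_i (1 - p_i), the variance explained is
#' R^2(c) = c^2 K / (c^2 V + sigma^2), where V = sum b_i^2 v_i is the axis'
#' genetic variance, K = cov(S, G)^2 / var(S) (equal to V for the weighted
#' score, slightly below V for unweighted scores), and sigma^2 collects all
#' non-axis variance of the phenotype.  Solving R^2(c) = target for c, with
#' the two vitamin D axes solved jointly because both contribute to
#' var(ln 25(OH)D), gives the per-axis constants directly.
#'
#' @param seed Integer seed for the frequency draw.
#' @param freq_range Interval (within (0.05, 0.95)) from which effect-allele
#'   frequencies are drawn uniformly.  Default c(0.2, 0.5), typical of common
#'   GWAS instruments.
#' @param r2_targets Named vector of target variance-explained fractions for
#'   the three scores (`bmi`, `synthesis`, `metabolism`).
#' @param reference_spec A [cohort_spec()] supplying the residual SDs and
#'   seasonal amplitude the calibration assumes.
#' @param truth A [true_model()] supplying causal effects and confounder
#'   loadings for the variance bookkeeping.
#' @return A `data.frame` of class `snp_panel` with columns
#'   `rsid, gene, axis, eaf, weight` (12 rows with weight > 0, 4 with
#'   weight < 0).
#' @export
#' @examples
#' panel <- make_snp_panel(seed = 1)
#' table(panel$axis)
make_snp_panel <- function(seed = 1,
                           freq_range = c(0.2, 0.5),
                           r2_targets = c(bmi = 0.0097, synthesis = 0.0064,
                                          metabolism = 0.0126),
                           reference_spec = cohort_spec("reference", n = 1000),
                           truth = true_model()) {
  if (length(freq_range) != 2 || any(!is.finite(freq_range)) ||
      freq_range[1] >= freq_range[2] ||
      freq_range[1] <= 0.05 || freq_range[2] >= 0.95) {
    stop("freq_range must be an increasing interval strictly inside (0.05, 0.95)")
  }
  stopifnot(all(c("bmi", "synthesis", "metabolism") %in% names(r2_targets)),
            all(r2_targets > 0), all(r2_targets < 1))

  panel <- .panel_base()
  panel$eaf <- with_seed(seed, stats::runif(nrow(panel), freq_range[1], freq_range[2]))
  panel$weight <- calibrate_weights(panel, r2_targets, reference_spec, truth)
  panel$base_weight <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

# Closed-form per-axis weight calibration (see make_snp_panel for algebra).
# Assumes the feedback effect delta_vitd_to_bmi = 0 for the variance
# bookkeeping; with the default truth this holds exactly.
calibrate_weights <- function(panel, r2_targets, spec, truth) {
  v <- 2 * panel$eaf * (1 - panel$eaf)   # HWE genotype variance
  b <- panel$base_weight / 100           # ln-scale per-allele shapes
  ax <- panel$axis

  axis_V <- function(a) sum(b[ax == a]^2 * v[ax == a])
  # K for the unweighted (allele-count) score; for the weighted score the
  # score weights are proportional to the effects, so K = V exactly.
  axis_K_unw <- function(a) sum(b[ax == a] * v[ax == a])^2 / sum(v[ax == a])

  t_b <- r2_targets[["bmi"]]
  t_s <- r2_targets[["synthesis"]]
  t_m <- r2_targets[["metabolism"]]

  # BMI axis: non-genetic variance of ln BMI
  sigma2_b <- truth$confounder_effect_bmi^2 + spec$resid_sd_lnbmi^2
  V_b <- axis_V("bmi")
  c_b <- sqrt(t_b * sigma2_b / ((1 - t_b) * V_b))
  var_lnbmi <- c_b^2 * V_b + sigma2_b

  # vitamin D axes: non-vitD-genetic variance of ln 25(OH)D; the causal term
  # gamma * lnBMI covaries with the shared confounder, hence the cross term.
  gam <- truth$gamma_bmi_to_vitd
  sigma2_v <- gam^2 * var_lnbmi +
    truth$confounder_effect_vitd^2 +
    2 * gam * truth$confounder_effect_bmi * truth$confounder_effect_vitd +
    spec$month_amplitude^2 / 2 +
    spec$resid_sd_lnvitd^2
  V_s <- axis_V("vitd_synthesis"); K_s <- axis_K_unw("vitd_synthesis")
  V_m <- axis_V("vitd_metabolism"); K_m <- axis_K_unw("vitd_metabolism")
  denom <- 1 - t_s * V_s / K_s - t_m * V_m / K_m
  if (denom <= 0) stop("r2 targets too large for the configured variance model")
  X <- sigma2_v / denom                  # implied var(ln 25(OH)D)
  c_s <- sqrt(t_s * X / K_s)
  c_m <- sqrt(t_m * X / K_m)

  scale <- c(bmi = c_b, vitd_synthesis = c_s, vitd_metabolism = c_m)
  unname(panel$base_weight * scale[ax])
}

#' Write / read an instrument panel as TSV
#'
#' Columns: `rsid, gene, axis, eaf, weight`.
#'
#' @param panel An `snp_panel`.
#' @param path File path.
#' @return `read_panel` returns an `snp_panel`; `write_panel` returns the
#'   path invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "gene", "axis", "eaf", "weight") %in% names(panel)))
  class(panel) <- c("snp_panel", "data.frame")
  panel
}
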
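# shared fixtures, built once per test run

# default calibrated panel used across tests
test_panel <- make_snp_panel(seed = 42)

# a hand-built two-axis mini panel with exact frequencies, for HWE and
# score arithmetic tests
mini_panel <- function(eaf = 0.3, weight_bmi = 1, weight_vitd = -4) {
  p <- data.frame(
    rsid = c("rsB1", "rsB2", "rsS1", "rsS2", "rsM1", "rsM2"),
    gene = c("G1", "G2", "S1", "S2", "M1", "M2"),
    axis = c("bmi", "bmi", "vitd_synthesis", "vitd_synthesis",
             "vitd_metabolism", "vitd_metabolism"),
    eaf = eaf,
    weight = c(weight_bmi, weight_bmi, weight_vitd, weight_vitd,
               weight_vitd, weight_vitd),
    stringsAsFactors = FALSE
  )
  class(p) <- c("snp_panel", "data.frame")
  p
}

# truth with no genetics-independent structure: no confounding, chosen gamma
plain_truth <- function(gamma = -0.42, delta = 0) {
  true_model(gamma_bmi_to_vitd = gamma, delta_vitd_to_bmi = delta,
             confounder_effect_bmi = 0, confounder_effect_vitd = 0)
}
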
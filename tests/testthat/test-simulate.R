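test_that("genotypes respect allele frequency and Hardy-Weinberg proportions", {
  panel <- mini_panel(eaf = 0.3)
  tab <- simulate_cohort(cohort_spec("hwe", 5000), panel, plain_truth(),
                         seed = 3)
  g <- tab$rsB1
  n <- length(g)
  # observed effect-allele frequency within 3 binomial SEs of 0.3
  se_f <- sqrt(0.3 * 0.7 / (2 * n))
  expect_lt(abs(mean(g) / 2 - 0.3), 3 * se_f)
  # genotype class proportions within 3 SEs of p^2 / 2pq / q^2
  exp_p <- c(`0` = 0.49, `1` = 0.42, `2` = 0.09)
  obs_p <- tabulate(g + 1, 3) / n
  for (k in 1:3) {
    expect_lt(abs(obs_p[k] - exp_p[k]), 3 * sqrt(exp_p[k] * (1 - exp_p[k]) / n))
  }
})

test_that("HWE chi-square GoF rejects at about the nominal rate", {
  panel <- mini_panel(eaf = 0.25)
  pvals <- vapply(1:60, function(s) {
    tab <- simulate_cohort(cohort_spec("hwe", 2000, n_pc = 0), panel,
                           plain_truth(0), seed = 100 + s)
    g <- tab$rsM1
    p_hat <- mean(g) / 2
    expected <- 2000 * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    chi <- sum((tabulate(g + 1, 3) - expected)^2 / expected)
    stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }, 1)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("null truth gives no BMI-25(OH)D association", {
  panel <- mini_panel()
  panel$weight <- 0
  tab <- simulate_cohort(cohort_spec("null", 5000), panel, plain_truth(0, 0),
                         seed = 5)
  fit <- summary(lm(ln_vitd ~ ln_bmi, data = tab))$coefficients
  expect_lt(abs(fit["ln_bmi", "t value"]), 3)
})

test_that("unconfounded OLS recovers the causal elasticity", {
  tab <- simulate_cohort(cohort_spec("rec", 20000), test_panel,
                         plain_truth(-0.42), seed = 9)
  fit <- summary(lm(ln_vitd ~ ln_bmi + factor(month), data = tab))$coefficients
  expect_lt(abs(fit["ln_bmi", "Estimate"] - (-0.42)),
            3 * fit["ln_bmi", "Std. Error"])
})

test_that("reduced-form ratio of covariances converges to gamma", {
  # a strong two-SNP instrument keeps the ratio's sampling noise small
  panel <- mini_panel(weight_bmi = 8, weight_vitd = -8)
  truth <- true_model(gamma_bmi_to_vitd = -0.42, delta_vitd_to_bmi = 0,
                      confounder_effect_bmi = 0.3, confounder_effect_vitd = 0.3)
  tab <- simulate_cohort(cohort_spec("rf", 60000), panel, truth, seed = 21)
  s <- allele_score(tab, score_def("b", c("rsB1", "rsB2"), weights = c(8, 8)))
  ratio <- cov(s, tab$ln_vitd) / cov(s, tab$ln_bmi)
  expect_lt(abs(ratio - (-0.42)), 0.1)
})

test_that("vitamin D scores are marginally independent of ln BMI when delta = 0", {
  tab <- simulate_cohort(cohort_spec("ind", 20000), test_panel, true_model(),
                         seed = 13)
  syn <- allele_score(tab, synthesis_score_def(test_panel))
  met <- allele_score(tab, metabolism_score_def(test_panel))
  expect_lt(abs(cor(syn, tab$ln_bmi)), 3 / sqrt(nrow(tab)))
  expect_lt(abs(cor(met, tab$ln_bmi)), 3 / sqrt(nrow(tab)))
})

test_that("bi-directional truths use the reduced form and reject |gamma*delta| >= 1", {
  panel <- mini_panel(weight_bmi = 8, weight_vitd = -8)
  truth <- true_model(gamma_bmi_to_vitd = -0.5, delta_vitd_to_bmi = -0.3)
  tab <- simulate_cohort(cohort_spec("bidir", 40000), panel, truth, seed = 2)
  # covariance ratio through the BMI SNPs still recovers gamma under feedback
  s <- allele_score(tab, score_def("b", c("rsB1", "rsB2"), weights = c(8, 8)))
  expect_lt(abs(cov(s, tab$ln_vitd) / cov(s, tab$ln_bmi) - (-0.5)), 0.12)
  bad <- true_model(gamma_bmi_to_vitd = -2, delta_vitd_to_bmi = 0.5)
  expect_error(simulate_cohort(cohort_spec("bad", 100), test_panel, bad, 1),
               "non-invertible")
})

test_that("whole-SNP missingness masks exactly the configured columns", {
  spec <- cohort_spec("miss", 500, missing_snps = "rs9939609")
  tab <- simulate_cohort(spec, test_panel, true_model(), seed = 4)
  expect_true(all(is.na(tab$rs9939609)))
  others <- setdiff(test_panel$rsid, "rs9939609")
  expect_false(any(is.na(tab[, others])))
  expect_error(
    simulate_cohort(cohort_spec("bad", 100, missing_snps = "rs000"),
                    test_panel, true_model(), 1),
    "absent from the panel")
})

test_that("default collaboration reproduces the 21-cohort size template", {
  specs <- default_cohort_specs()
  expect_length(specs, 21)
  expect_equal(sum(vapply(specs, function(s) s$n, 1)), 42024)
  tabs <- simulate_collaboration(specs[1:4], test_panel, true_model(), seed = 77)
  expect_equal(vapply(tabs, nrow, 1L),
               vapply(specs[1:4], function(s) s$n, 1L),
               ignore_attr = TRUE)
  # male-only and female-only cohorts honour their sex mix
  tab11 <- simulate_cohort(specs[[11]], test_panel, true_model(), seed = 1)
  expect_true(all(tab11$sex == "M"))
})

test_that("collaboration output is reproducible and validates its inputs", {
  specs <- lapply(1:3, function(i) cohort_spec(paste0("c", i), 100))
  a <- simulate_collaboration(specs, test_panel, true_model(), seed = 6)
  b <- simulate_collaboration(specs, test_panel, true_model(), seed = 6)
  expect_identical(a, b)
  expect_error(simulate_collaboration(specs[1], test_panel, true_model(), 1),
               "at least 2")
  dup <- c(specs, list(cohort_spec("c1", 50)))
  expect_error(simulate_collaboration(dup, test_panel, true_model(), 1),
               "duplicate")
})

test_that("cohort TSVs round-trip with empty cells for missing genotypes", {
  spec <- cohort_spec("io", 60, missing_snps = "rs29941")
  tab <- simulate_cohort(spec, test_panel, true_model(), seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(tab, path)
  expect_false(grepl("NA", readLines(path)[2]))
  back <- read_cohort_tsv(path, cohort = "io")
  expect_equal(back$ln_vitd, tab$ln_vitd, tolerance = 1e-12)
  expect_true(all(is.na(back$rs29941)))
  # byte-identical rewrite (determinism contract for file outputs)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(tab, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("truth record round-trips through YAML", {
  truth <- true_model(gamma_bmi_to_vitd = -0.3, confounder_effect_bmi = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, path)
  expect_equal(read_truth(path), truth, tolerance = 1e-6)
})
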
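Package: scoremr
Title: Bi-Directional Mendelian Randomization with Allele Scores Across
    Cohort Collaborations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bi-directional Mendelian randomization analyses of
    body mass index and 25-hydroxyvitamin D across multi-cohort
    collaborations: weighted and unweighted allele-score construction,
    covariate-adjusted per-cohort associations on the ln (percent) scale,
    fixed-effects and DerSimonian-Laird random-effects meta-analysis with
    heterogeneity-based model selection, univariate meta-regression,
    bivariate multivariate pooling, instrumental-variable ratio estimation
    with Taylor-expansion (delta-method) variance, instrument F-statistics,
    summary-statistic score combination, and simulation-based power for IV
    regression.  Includes a synthetic multi-cohort generator that emulates
    the statistical structure the analysis assumes (Hardy-Weinberg
    genotypes, ln-scale phenotypes, seasonal variation in vitamin D, shared
    confounding, configurable causal effects in both directions) together
    with a pipeline driver that runs the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    metafor,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
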
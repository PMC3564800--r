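# scoremr

Bi-directional Mendelian randomization (MR) with allele scores across
multi-cohort collaborations, built for the question of whether adiposity
causally lowers vitamin D status or vice versa.

Observational studies consistently find lower circulating
25-hydroxyvitamin D (25(OH)D) in people with higher body mass index, but
cannot tell cause from effect from confounding. The MR design breaks the
tie with genetics: a weighted score of 12 BMI-associated SNPs instruments
adiposity, and two unweighted scores of vitamin D pathway SNPs — a
*synthesis* score (DHCR7, CYP2R1) and a *metabolism* score (GC, CYP24A1) —
instrument 25(OH)D. Each instrument is tested against the opposite
phenotype; because alleles are assigned at random before birth, these
gene–outcome associations are shielded from reverse causation and lifestyle
confounding.

## The estimator

Per cohort, OLS of the ln outcome on score and covariates gives
coefficients that (×100) read as percent difference per score unit. Cohort
coefficients are pooled by inverse-variance meta-analysis — fixed effects,
switching to DerSimonian–Laird random effects when Cochran's Q is
significant — and the causal effect is the IV (Wald) ratio

    theta = beta(score -> outcome) / beta(score -> exposure)

with delta-method (first-order Taylor) variance

    var(theta) = se_num^2 / beta_den^2 + beta_num^2 * se_den^2 / beta_den^4.

Instrument strength is assessed as F = R²(n−2)/(1−R²) from the marginal
variance explained by each score. The package also provides univariate
meta-regression on study-level factors, bivariate GLS pooling of the joint
synthesis + metabolism model with its within-study covariance, combination
of published per-SNP summary statistics into score-level estimates, and IV
power by simulation. A synthetic 21-cohort generator with a recorded causal
truth (Hardy–Weinberg genotypes, ln-scale phenotypes, seasonal 25(OH)D
variation, shared confounding, configurable effects in both directions)
supports end-to-end recovery testing.

## Worked example

Feeding the published pooled score coefficients (standard errors recovered
from their 95% CIs) into the ratio estimator:

```r
library(scoremr)
bmi_iv <- iv_ratio(
  num = list(beta = -0.06, se = ci_to_se(-0.10, -0.02)),  # score -> 25(OH)D
  den = list(beta =  0.14, se = ci_to_se( 0.12,  0.16)))  # score -> BMI
round(bmi_iv[, c("ratio", "se", "ci_low", "ci_high", "p")], 4)
#>     ratio     se  ci_low ci_high     p
#> 1 -0.4286 0.1491 -0.7208 -0.1364 0.004
```

Each 1% higher BMI causes an estimated 0.43% lower 25(OH)D; rescaled,

```r
iv10 <- percent_change_per_10pct(bmi_iv)
sprintf("per 10%% BMI: %s%% (%s to %s)", format_estimate(iv10$ratio),
        format_estimate(iv10$ci_low), format_estimate(iv10$ci_high))
#> "per 10% BMI: -4.29% (-7.21 to -1.36)"
```

i.e. a 10% BMI increase lowers 25(OH)D by about 4.3% (CI roughly −7.2% to
−1.4%), and all three instruments are strong:

```r
min(instrument_f(c(0.0097, 0.0064, 0.0126), c(32391, 35873, 38191)))
#> [1] 231.0531
```

The full pipeline on the bundled synthetic 21-cohort scenario (42,024
subjects, true elasticity −0.42 for BMI→25(OH)D and 0 for the reverse):

```r
res <- run_pipeline(run_config(out_dir = "mr_out", seed = 20130205))
res$iv[, c("direction", "instrument", "ratio", "ci_low", "ci_high", "p", "f_stat", "model")]
#>    direction       instrument   ratio  ci_low ci_high      p f_stat model
#>  bmi_to_vitd        bmi_score -0.2305 -0.4715  0.0105 0.0609    387 fixed
#>  vitd_to_bmi  synthesis_score  0.0291 -0.0206  0.0788 0.2517    211 fixed
#>  vitd_to_bmi metabolism_score  0.0195 -0.0157  0.0548 0.2775    378 fixed
```

The BMI-direction confidence interval covers the generating truth of −0.42
and both reverse-direction ratios cover 0, the pattern the design is meant
to recover. `mr_out/` holds every stage table as TSV (per-cohort
associations, pooled estimates with heterogeneity decisions, forest-plot
data, meta-regressions, the bivariate joint model, IV ratios, power grid),
a run log, and `index.tsv` with an MD5 hash per table — reruns with the
same config are byte-identical.

A thin command-line wrapper with subcommands `simulate`, `associate`,
`meta`, `mr`, `power` and `all` is installed at
`inst/cli/mr_pipeline.R`:

```sh
Rscript inst/cli/mr_pipeline.R all --out mr_out --seed 20130205
```

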
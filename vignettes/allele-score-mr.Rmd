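---
title: "Bi-directional Mendelian randomization with allele scores: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-directional Mendelian randomization with allele scores: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoremr)
```

## The scientific question

Obesity and low vitamin D status travel together in observational data, but
the direction of the association is ambiguous: adiposity might sequester or
dilute vitamin D, or low vitamin D might promote fat accumulation.
`scoremr` implements the bi-directional Mendelian randomization (MR) design
used to separate the two: genetic variants robustly associated with BMI
serve as instruments for adiposity, variants in the vitamin D synthesis and
metabolism pathways serve as instruments for 25-hydroxyvitamin D
(25(OH)D), and each instrument set is tested against the *other* phenotype.
Because genotypes are assigned at conception, the gene–outcome associations
are protected from the confounding and reverse causation that plague the
direct phenotype–phenotype association.

Everything operates on the natural-log scale: coefficients of a regression
with an ln-transformed outcome, multiplied by 100, read as percent
difference in the outcome per unit of the exposure, and a ratio of two such
coefficients is a percent-per-percent elasticity.

## The estimator

For an allele score $S$ (instrument), exposure $X$ and outcome $Y$, each
cohort contributes covariate-adjusted OLS coefficients
$\hat\beta_{SY}$ and $\hat\beta_{SX}$ on the percent scale.  These are
pooled across cohorts by inverse-variance meta-analysis and combined into
the Wald / IV ratio

$$\hat\theta = \frac{\hat\beta_{SY}^{pooled}}{\hat\beta_{SX}^{pooled}},
\qquad
\widehat{var}(\hat\theta) =
\frac{\sigma_{SY}^2}{\beta_{SX}^2} +
\frac{\beta_{SY}^2\,\sigma_{SX}^2}{\beta_{SX}^4},$$

the variance being the first-order Taylor (delta-method) expansion of the
ratio.  Design choices for this layer, made where the method description
left room:

* **No numerator–denominator covariance by default.** The two pooled
  coefficients come from overlapping samples, so their covariance is not
  zero, but the standard ratio-variance form omits it; `iv_ratio()` accepts
  an optional `cov_num_den` for users who can estimate it.
* **Normal-theory inference.** p-values come from $z = \hat\theta/se$; with
  first-stage F statistics in the hundreds there is no need for
  weak-instrument-robust (Fieller-type) intervals.  A denominator with
  $|\beta|/se < 2$ flags the result (`weak_denominator`) and warns rather
  than switching estimators.
* **Per-10% reading.** The elasticity is rescaled to "percent change in the
  outcome per 10% increase in the exposure" by linear multiplication by 10,
  not by $\exp(\hat\theta \ln 1.1)$; the linear form is the convention used
  with these ratios and the difference is negligible at these magnitudes.
* **Report rounding.** Ratios are printed to two decimals with the sign of
  values rounding to zero preserved (`format_estimate(-0.003)` is
  `"-0.00"`), so a null-ish estimate still shows its direction.

## Allele scores

The weighted BMI score multiplies each genotype count (0–2 effect alleles,
BMI-raising convention) by its published per-allele weight and rescales by
the sum of weights over the SNPs the cohort actually has:
$S = \sum_i w_i g_i / \sum_i w_i \in [0, 2]$.  Whole-SNP missingness (a
cohort never typed a variant) simply drops the SNP from both sums.

The two vitamin D scores are unweighted allele counts (25(OH)D-lowering
convention): a *synthesis* score (DHCR7, CYP2R1 — variants acting upstream
of 25(OH)D production) and a *metabolism* score (GC, CYP24A1 — transport
and clearance).  External weights are not used for these because
internally-derived weights would bias the IV estimate.  A cohort missing
any constituent SNP skips that score entirely rather than imputing
(`allele_score()` returns `NULL` with a warning); the pipeline records the
skip and pools over the remaining cohorts.

Instrument strength is summarised by the marginal variance explained,
$R^2 = cor(S, \ln\text{phenotype})^2$, and the approximation
$F = R^2(n-2)/(1-R^2)$.  $R^2$ is deliberately *marginal* (score only, not
incremental over covariates), matching how the quantity is reported in this
literature.

## Meta-analytic machinery

* **Fixed effects**: inverse-variance weights $w_i = 1/se_i^2$.
* **Random effects**: DerSimonian–Laird moment estimator
  $\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$,
  re-weighting by $1/(se_i^2 + \hat\tau^2)$.
* **Model selection**: Cochran's Q with threshold $p_Q < 0.05$ (strict;
  configurable via `alpha_het`) selects random effects, otherwise fixed —
  the rule applied separately to every pooled association, and logged.
* **Meta-regression**: weighted least squares of study coefficients on a
  study-level factor with method-of-moments residual $\tau^2$, delegated to
  `metafor::rma(method = "DL")`; inference is a plain z test (no
  Knapp–Hartung small-sample adjustment, consistent with reporting plain
  CIs at $k \approx 21$).  Categorical factors require an explicit
  reference level.
* **Bivariate pooling**: the joint synthesis + metabolism model is pooled
  by fixed-effects GLS using each cohort's within-study 2×2 covariance
  matrix, $\hat b = (\sum C_i^{-1})^{-1} \sum C_i^{-1} b_i$, with a 2-df
  Wald test of the joint null.  Cohorts with singular $C_i$ are dropped
  with a warning.

## What the synthetic generator emulates

`simulate_cohort()` draws genotypes as Binomial(2, EAF) — Hardy–Weinberg,
linkage equilibrium — and builds the phenotypes from the linear structural
system

$$\ln BMI = a_b + G_b + c_b U + \delta\,(\ln 25(OH)D - \mu_v) + e_b,
\qquad
\ln 25(OH)D = a_v + G_v + M + c_v U + \gamma\,(\ln BMI - \mu_b) + e_v,$$

solved in reduced form when both causal effects are nonzero (requires
$|\gamma\delta| < 1$).  $U$ is a shared standard-normal confounder, $M$ a
cosine seasonal term on the month of blood draw, and $G$ the per-allele
genetic sums.  Key parameter choices, all configurable:

* **Causal truth.** Defaults $\gamma = -0.42$ (the elasticity the analysis
  is designed to estimate) and $\delta = 0$ (no vitamin-D-to-BMI effect) —
  the scenario the bi-directional analysis concludes in favour of.
* **Confounding.** Default loadings $(c_b, c_v) = (0.06, 0.06)$.  The sign
  and size are chosen so the *observational* ln-ln association is
  attenuated relative to the causal elasticity — about $-1.1\%$ per
  kg/m² against a causal $-1.58\%$ per kg/m² at the reference BMI of
  26.5 — reproducing the qualitative pattern the MR design exists to
  resolve.  The coverage tests use stronger loadings (0.3/0.3) to make the
  observational bias unmistakable while leaving the IV estimator unbiased.
* **Seasonality.** $M = A\cos(2\pi(month - 7)/12)$ with default amplitude
  $A = 0.15$ (≈ ±15% peak-to-mean on 25(OH)D) and a July peak; month is
  uniform over 1–12.  Adjustment uses month *indicators*, so any smooth
  seasonal shape is absorbed; the cosine is only the generating form.
* **Residual scales.** $sd(e_b) = 0.16$ and $sd(e_v) = 0.42$ ln-units,
  matching typical adult dispersions of BMI and 25(OH)D; intercepts
  $\ln 26.5$ kg/m² and $\ln 55$ nmol/l.
* **Weight calibration.** Per-axis multiplicative constants rescale the
  relative SNP effect shapes so that, under the reference model, the
  weighted BMI score explains 0.97% of ln-BMI variance and the synthesis /
  metabolism scores 0.64% / 1.26% of ln-25(OH)D variance.  The constants
  have a closed form: for a score with base effects $b_i$ and genotype
  variances $v_i = 2p_i(1-p_i)$, $R^2(c) = c^2K / (c^2V + \sigma^2)$ with
  $V = \sum b_i^2 v_i$ and $K = cov(S,G)^2/var(S)$, so solving
  $R^2(c) = t$ (jointly for the two vitamin D axes, which share the
  phenotype variance) gives $c$ directly — no iterative search is needed.
* **Allele frequencies** are drawn uniformly from (0.2, 0.5) by default,
  typical of common-variant GWAS instruments.
* **The 21-cohort template** (`default_cohort_specs()`) reproduces the
  structure of a large trans-Atlantic collaboration: 42,024 subjects across
  cohorts of 330–7,414, three male-only and two female-only studies,
  heterogeneous ages (19–75) and geometric means (BMI 22.1–27.2 kg/m²,
  25(OH)D 34–74 nmol/l, expressed as ln-mean shifts), five cohorts missing
  1–3 BMI SNPs, one missing a synthesis SNP and one missing one SNP from
  each vitamin D score.

What it deliberately does **not** emulate: linkage disequilibrium between
instrument SNPs, population stratification (the principal-component
columns are pure noise, so adjusting for them is harmless but inert),
assay error models or laboratory batch effects, family relatedness, and
sporadic per-subject genotype missingness (only whole-SNP-per-cohort
missingness occurs, as in the emulated design).  Consequently, passing
recovery tests demonstrates that the estimator chain is correct under the
model's assumptions — not that real cohort data satisfy those assumptions.

## Power by simulation

The emulated power calculation is stated as "ln-units per decile of the
exposure", which leaves the simulation design open; `iv_power()`
operationalises it as follows, one of several defensible readings and
therefore documented prominently.  Per replicate, an instrument score
$S \sim N(0,1)$ is drawn for $n$ subjects; the standardized exposure is
$X = \sqrt{r^2} S + \sqrt{1 - r^2}\,\varepsilon$ so the score explains
$r^2$ of its variance; the outcome mean is shifted by
$effect \times (decile(X) - 5.5)$ with $N(0, resid\_sd^2)$ noise
(default 0.45 ln-units); the two regression slopes are combined with the
package's own `iv_ratio()` and power is the rejection fraction at `alpha`.
At $n = 40{,}000$ and $r^2 = 0.97\%$, an effect of 0.02 ln-units/decile
yields power around 0.67, and halving the effect drops power below 0.3 —
the qualitative conclusion that the reverse-direction analysis was
underpowered for effects half the size of the forward one.

## Numerical and degenerate-input conventions

* Heterogeneity $I^2$ is clamped to $[0, 100]$ and set to 0 when
  $Q \le k-1$; $\tau^2$ is floored at 0.
* The fixed/random threshold comparison is strict (`p_Q < alpha_het`), so a
  p-value exactly at the threshold stays fixed-effects.
* Covariates that are constant within a cohort (e.g. month in a cohort
  bled in a single campaign, sex in a single-sex cohort) are dropped with a
  warning rather than erroring; rank-deficient designs beyond that raise an
  error naming the collinear columns.
* Outcomes must be strictly positive before the ln transform; violations
  are errors, not silent omissions.
* Child seeds for cohorts and power-grid rows are derived from the master
  seed by a fixed affine map modulo a prime below $2^{31}$, so any
  sub-stream can be regenerated in isolation.

## Problem sizes used in the test-suite

The packaged tests run the full estimator chain at reduced scale chosen to
keep Monte Carlo error well inside the asserted bands: coverage and
reverse-direction size use 200 simulated collaborations of 5 cohorts ×
4,000 subjects (coverage band [0.90, 0.98] against a binomial SE of ~1.5%),
calibration checks use single cohorts of 20,000–60,000, the delta-method /
bootstrap comparison uses $10^6$ draws, and power curves use 1,000–2,000
replicates.  The bundled default scenario runs the full 42,024-subject
collaboration once, which takes a few seconds.

## Known limitations

The IV ratio on meta-analysed coefficients assumes linearity on the ln
scale and a homogeneous causal effect across cohorts; it cannot see
threshold effects at the extremes of the 25(OH)D distribution.  The
delta-method variance understates uncertainty when the denominator is
weak (hence the flag).  The no-covariance default in the ratio variance is
mildly conservative or anticonservative depending on the sign of the true
covariance.  Pleiotropy is diluted by multi-SNP scores but not modelled;
there are no MR-Egger/median robust estimators in scope.
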
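---
title: "Corrected target-height prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected target-height prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetheight)
```

## The prediction model

A child's target height is their mid-parental height adjusted for sex; the
classical procedure adds 13 cm to the mother's height, averages, and shifts
by ±6.5 cm for the child's sex. `targetheight` replaces each step with a
correction grounded in how adult heights are actually distributed:

1. **Age correction.** Adults shrink from about age 30, and the rate of
   loss grows with age. We model cumulative shrinkage as
   $s(a) = \gamma\,(a - 30)_+^2$ — a shrinkage *rate* that increases at a
   constant rate — and restore each parent's measured height to peak height
   before any other step. Children in the evaluation pipeline pass through
   the same correction; for most clinical queries they are under 30 and it
   is a no-op.
2. **Sex correction.** Three schemes place the sexes on a common scale: an
   additive constant (+13 cm classical, +10.82 cm cohort-fitted), a
   multiplicative factor on female heights (×1.08 from growth-chart
   percentiles, ×1.066 cohort-fitted), or per-sex Z-score standardization.
   The male–female gap at matched percentiles is linear in height, which is
   why the multiplicative and Z-score schemes outperform a constant — the
   error of the additive scheme is concentrated at the height extremes,
   exactly where clinical decisions are made.
3. **Regression to the mean.** On the standardized scale the expected child
   height is $z_{\text{child}} = \beta z_{\text{mp}} + \alpha$ with the
   shipped default $(\beta, \alpha) = (0.79, -0.077)$. $\beta$ is the
   midparent-sense heritability; $\beta < 1$ pulls extreme midparents
   toward the population mean, so two 3rd-percentile parents are predicted
   a 6th-percentile child, a few centimetres taller than themselves.

For cm-scale schemes (additive/multiplicative) the regression step
standardizes the male-equivalent midparent against the **male** reference
mean/SD, applies $(\beta, \alpha)$, and de-standardizes. This makes all
schemes structurally parallel — one linear map on one common scale — and is
exactly equivalent to fitting the line directly in male-equivalent
centimetres.

Finally, the deviation of a projected height from the target is scored as a
one-sided normal tail probability $P(D \le d)$ with
$D \sim N(0, \sigma_{\text{sex}})$, the empirical residual distribution of
adult children around their family target. One-sided probabilities match
the clinical question ("at least this much shorter"); the two-sided value
is reported alongside. Displayed probabilities are rounded to the nearest
percent, and heights to 0.1 cm, only at presentation — all internal
arithmetic is double precision.

## Parameters, defaults, and where they come from

| Parameter | Default | Units | Basis |
|---|---|---|---|
| shrinkage onset | 30 | years | longitudinal shrinkage studies |
| shrinkage acceleration $\gamma$ | 0.00264 | cm/y² | calibrated (below) |
| additive constants | 13, 10.82 | cm | classical / cohort-fitted |
| multiplicative factors | 1.08, 1.066 | — | chart-derived / cohort-fitted |
| rtm slope $\beta$ | 0.79 | — | fitted offspring-on-midparent slope |
| rtm intercept $\alpha$ | −0.077 | SDS | same fit |
| residual SD (sons) | 4.7 pooled / 4.5 within-family | cm | empirical |
| residual SD (daughters) | 4.4 pooled / 4.2 within-family | cm | empirical |
| cutoffs | ±10 / ±9 cm; ±1.64 SDS | — | classical guidelines |

**The shrinkage calibration.** The per-sex coefficients of the published
longitudinal shrinkage model are not available to us, so the default uses a
single acceleration for both sexes, calibrated to the one quantitative
anchor the cohort analysis provides: parents average 62 years of age, and
without age correction children are on average 2.7 cm taller than their
midparent — a bias attributable to parental shrinkage. Solving
$\gamma\,(62-30)^2 = 2.7$ gives $\gamma \approx 0.00264$ cm/y². This is a
documented stand-in, not a fitted longitudinal model; per-sex values are
configurable in `age_shrinkage_model()`.

**The derived reference population.** `cdc_reference()` is built from four
published anchor points rather than the raw chart files: ±1.64 SDS equals
±10.6 cm for women and ±11.7 cm for men (fixing the SDs), 163 cm is the
female median, and 163 cm is the male 3rd percentile (fixing the means).
The percentile machinery uses the normal quantile model, which these
anchors make self-consistent; monotone table interpolation is available via
`percentile_table()` readers when a chart file is supplied. The packaged
chart fixture (`inst/extdata/cdc_statage_240mo_synthetic.csv`) is a
synthetic stand-in generated from this derived reference; it reproduces the
published sex-difference anchors (12.2 cm at P3, 14.7 cm at P97, zero-
intercept factor 1.08) and is labelled synthetic in its filename.

**Residual basis.** The clinical default is the pooled basis (4.7/4.4 cm):
a child walking into a clinic is compared against the variability of all
children around their family targets, not only their own (unobserved)
siblings. The within-family basis (4.5/4.2 cm) is available for the
family-level analyses. At a −10 cm deviation the pooled daughter SD gives a
tail probability of ~1%; the son value depends on whether the pooled or
within-family SD is used (~1.7% vs ~1.3%), and the package always reports
the computed value rather than a rounded headline number.

**Percentile representation.** Percentiles are fractions in (0,1)
internally; the CLI accepts and prints the 0–100 scale. This avoids the
0.03-versus-3 ambiguity at the 3rd percentile.

## The evaluation pipeline

`midparent_regression()` regresses each child's common-scale height on the
family midparent value — each child is one observation, which is what makes
the per-child scatter and its $R^2$ meaningful; `family_level_rtm()` is the
separate family-mean view, where regression to the mean appears as a
negative correlation between family midparent height and the children's
mean deviation from it. Systematic error is the mean of child minus
midparent on the common scale; for Z-score schemes it is reported in SDS
and labelled as such, since a standardized bias and a cm bias are not
comparable numbers. Pearson correlations use the exact t-test with
$n-2$ degrees of freedom, two-sided.

`within_family_residuals()` computes residuals against the fully corrected
family target (age + sex + regression to the mean) on each child's own sex
scale, per the definition of the within-family spread; a
`raw_midparent = TRUE` switch measures residuals around the uncorrected
midparent for sensitivity analysis. Families contribute a within-family SD
for a sex only with at least two children of that sex — fewer is not an
error, just no information about spread.

## The simulator: what it emulates and what it does not

`simulate_cohort()` mirrors the generative structure the analysis assumes:
parents' peak standardized heights are bivariate normal with spousal
correlation 0.2 (assortative mating; the value is not published for the
study cohort, so we chose a typical spousal height correlation once and
expose it as a parameter, including 0), children's standardized heights are
$\beta z_{\text{mp}} + \varepsilon$ with per-sex residual SDs, sexes are
Bernoulli(½), and measured heights equal peak heights minus shrinkage at
each person's age. Defaults reproduce the study conditions: 23 families,
7–16 children each, parental ages 62 ± 5 y, $\beta = 0.79$, residual SDs
4.5/4.2 cm. Child ages are uniform on 20–45 y — not published either — so
child-side age correction is a near no-op for most children. No secular
trend is generated by default, encoding the finding that the
intergenerational height difference is explained by parental shrinkage; a
constant-trend hook exists for sensitivity tests.

What the simulator does **not** emulate: measurement error and technical
replicates, non-normal height distributions, genotypes or within-family
genetic structure beyond the midparent value, ethnic or secular
heterogeneity, and heteroscedasticity of the residuals. Passing
parameter-recovery tests on simulated cohorts therefore validates the
*pipeline* — that the estimators recover what the generative model puts in
— not the biological adequacy of the model for any real population.
`ideal_cohort()` is the noise-free variant ($\varepsilon \equiv 0$, ages
below onset) used for exact-identity tests.

## Numerical choices

- Round trips (`to_common_scale`/`from_common_scale`,
  percentile/height conversions) are exact up to floating-point rounding
  and tested at 1e−9.
- The correlation analyses declare a vector *degenerate* when its standard
  deviation is below 1e−9 relative to its magnitude: the family-level
  regression-to-the-mean correlation is then reported as undefined
  (`NA`), while a constant residual spread is reported as exactly no trend
  (`r = 0`, `p = 1`). Exact zeros cannot survive scale transformations in
  floating point, so a tolerance, not `== 0`, is the correct guard.
- Missing parental age is an error unless `assume_peak = TRUE` is passed
  explicitly; a silent "no correction" fallback would quietly reintroduce
  the ~2.7 cm age bias the method exists to remove.
- OLS fits go through `stats::lm`; the test suite cross-checks slope,
  intercept and $R^2$ against closed-form formulas computed from raw sums.

## Problem sizes

The test suite exercises stochastic parameter recovery at 300–1000 families
(about 3,500–11,500 children), where the slope standard error is ~0.01–0.02
and pooled residual-SD estimates sit in ±4% chi-square 99% bands; moment-
convergence checks use 3,000 families. These sizes make the property tests
sharp while keeping the full suite under a minute.

## Limitations

- The fitted constants ($\beta$, $\alpha$, residual SDs, the 1.066/10.82
  sample constants) come from one cohort of large families of
  predominantly Ashkenazi ancestry; transfer to other populations is an
  empirical question, and the residual-SD coefficient of variation (~20%)
  means the deviation probabilities are approximate.
- The shrinkage default is a calibrated stand-in (above), adequate near the
  calibration point but not a substitute for a fitted longitudinal model
  at extreme ages.
- Projected height is an *input*: the package does not extrapolate a
  child's current height or bone age to adult height.
- The normal model for percentile conversion ignores the mild skew real
  growth-chart LMS parameters encode; within the adult 3rd–97th percentile
  range the discrepancy is small.
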
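---
title: "Methods: the HBSR score, its statistics, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HBSR score, its statistics, and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hbsr)
library(dplyr)
```

## The scoring model

The Health Behavior Stroke Risk (HBSR) score summarizes five lifestyle
factors — smoking status, body-mass index, physical exercise, diet, and
alcohol use — into a single 0–10 total. Each factor is graded low,
moderate, or high risk and contributes 0, 1 or 2 points; the fixed
grade→point bijection is what pins the total of five factors to the 0–10
range. Totals of 6–10 form the *high band*, 0–5 the *low band*; both
boundary values are encoded (and tested) as constants, not tunables.

Two of the factors are *composites* of two questionnaire answers:

* **diet** = meal-salting habit + vegetable days/week. Adverse
  sub-answers: salting ready-made food *before tasting*, and vegetables on
  fewer than 6 days a week.
* **alcohol** = drinking frequency + 7-day quantity. Adverse sub-answers:
  drinking once a week or more, and more than 8 (women) / 16 (men)
  standard drink units in the last 7 days.

A composite grades high when both sub-answers are adverse, moderate when
exactly one is, and low when neither is.

### Which mappings are design choices

The binary high-risk definitions (daily smoking, BMI ≥ 30, exercise less
than twice a week, salting before tasting, vegetables < 6 days/week,
drinking ≥ weekly, sex-specific 7-day excess) fix the *high* category of
each factor. The placement of the intermediate categories — whether an
ex-smoker is moderate or low, whether exercising 2–3 times a week is low —
is not derivable from those definitions, so the default mapping in
`hbsr_config()` takes the conservative middle road: categories between the
clearly protective and the clearly adverse answer grade moderate
(occasional and ex-smokers; BMI 25–29.9; exercise once a week to 2–3 times
a month). The full mapping is data, not code: any alternative
categorization can be supplied as a config object or YAML file
(`read_scoring_config()`), and the shipped default lives at
`inst/extdata/default_scoring.yaml` as a versioned file.

Two further choices deserve a note:

* **Salting "when the food needs more salt"** counts as non-adverse; only
  the habitual pre-tasting salter is flagged. Configurable via
  `diet$adverse_salting`.
* **The excess-alcohol comparison operator.** Survey materials are
  ambiguous between `> 8/16` and `≥ 8/16` units; the package defaults to
  the strict inequality and exposes `alcohol$units_comparison = ">="` for
  the other convention. With continuous unit data the choice is almost
  immaterial; with integer self-reports it moves the boundary case.

### Missing answers

The default policy is `require_complete`: a respondent missing any of the
five factors (or either sub-answer of a composite) receives a missing
total and band, and drops out of mean-score analyses — the same
complete-case convention used per variable in the prevalence tables.
`treat_missing_as_low` is available for sensitivity analyses but
understates risk by construction; nothing in the pipeline prorates or
imputes.

## The statistics

**Prevalence cells.** Every `n (%)` cell uses the complete-case
denominator: respondents in the group × age-band stratum with a
non-missing answer to that variable. Percentages are rounded half away
from zero to one decimal (the convention of printed tables; base R's
half-to-even rounding differs on exact halves).

**Two-proportion z-test.** Pooled-variance normal approximation without
continuity correction, two-sided; the statistic carries the sign of
p̂₁ − p̂₂. Its square is algebraically the 1-df Pearson chi-square, which
the tests verify against `prop.test(correct = FALSE)`. A degenerate pooled
proportion (0 or 1) returns z = 0, p = 1 rather than NaN.

**Bonferroni families.** Published tables mark significance per category
within a variable block, so the default family is the set of category
tests inside one variable × age-band block (4 for smoking, 5 for exercise,
…). Binary variables are tested once — the complementary row would repeat
the identical test and double-count the family. The sex/age-stratified
high-band comparisons form their own family of four; the overall
comparison is reported unadjusted. Which tests shared a family in any
given publication is rarely recoverable, so both raw and adjusted p-values
are always reported side by side.

**Logistic regression.** Odds ratios come from an internally implemented
iteratively reweighted least squares fit (`fit_logistic()`): starting from
β = 0, solve (XᵀWX)β = XᵀWz with W = diag(μ(1−μ)) and working response
z = η + (y−μ)/w, stopping when the largest absolute score component falls
below 1e-8 or the relative deviance change below 1e-10 (at most 50
iterations). Coefficients wandering beyond ±30 on the logit scale are
reported as perfect separation — an explicit error, not a silent huge OR.
The test suite pins the fit against `stats::glm` coefficients and standard
errors (the independent oracle) and against the closed-form cross-product
OR for single-exposure 2×2 designs. Wald 95% intervals are exponentiated
from the log-odds scale. Adjustment tiers mirror standard case-control
practice: crude; age + sex; age + sex + education + marital status, with
age continuous, sex as a male indicator, and education/marital
reference-coded against *higher education* and *married/cohabiting*. Zero
cells in a 2×2 are an error by default with an optional Haldane–Anscombe
+0.5 correction (`crude_or(haldane = TRUE)`).

**Mean scores.** Welch's two-sided t-test by default (`var_equal = TRUE`
gives the pooled-variance variant); each group also gets a
normal-approximation 95% CI, mean ± 1.96·sd/√n, matching how such tables
are usually printed.

## The synthetic cohort generator

`generate_cohort()` exists so every pipeline stage is testable without
individual-level registry or survey data. What it emulates, per group
(342 patients, 1789 controls by default):

* **Behavioral marginals.** Category probabilities per group × age band
  equal published count / complete-case denominator (`table1_counts()`),
  e.g. control 18–44 daily smoking 254/1249.
* **Missingness.** Injected completely at random per variable at the rate
  implied by the published denominators (e.g. patient 18–44 smoking
  1 − 133/135).
* **Covariates.** 62% vs 41% male; higher education 20% vs 34%; single
  15% vs 22% (the unpublished remainder of the education and marital
  distributions is split once — basic 15%/10%, secondary 65%/56%;
  divorced/widowed 20%/15% — and not revisited). Ages are drawn uniformly
  within quartile-anchored bands, each carrying mass 1/4 with edges at the
  published Q1/median/Q3 (patients 39/47/51, controls 28/37/46), which
  reproduces the printed medians and IQRs up to discreteness.
* **Dependence.** Behaviors are thresholded latent standard normals (a
  Gaussian copula), independent by default because only marginals are
  published; a 7×7 latent correlation matrix can be supplied to induce
  clustering. The copula cleanly separates marginals (always honored)
  from association (freely tunable).
* **Determinism.** One root seed with documented stream-splitting per
  drawing step (ages, sex, education, marital, the latent copula block,
  continuous fill-ins, missingness — separately per group), so adding a
  variable later cannot perturb earlier draws; the caller's RNG state is
  saved and restored.

Continuous carriers are drawn inside their target category — BMI uniform
in [18.5, 24.9], [25, 29.9] or [30, 40]; vegetable days uniform within the
≥6 / <6 split; 7-day units above or below the sex threshold per the drawn
excess flag — so the categorical view recovers the intended class exactly.

One deliberate incoherence: the excess-units flag is drawn from its own
marginal, so a respondent can report "never drinks" yet carry an excessive
7-day amount (about 1% of rows under the defaults). Forcing coherence
would bias the excess marginal by roughly a percentage point — more than
the generator's own recovery tolerance — and such self-report
inconsistencies do occur in real surveys; the validator flags them with a
warning, as it would on real data.

### What passing tests do and do not show

The generator reproduces *marginals* and covariate mixes, not the joint
distribution of behaviors, which is unpublished. Real risk behaviors
cluster (smokers drink more), so the synthetic cohorts understate the
variance and the tail mass of the score: the default-spec synthetic means
land close to published values (≈ 4.5 vs ≈ 3.5 at typical seeds) but
high-band prevalences run lower than the published 52.5% / 30.4%.
End-to-end assertions are therefore directional (patient mean above
control mean, odds ratios above 1 for the planted adverse factors), and
nothing in the package claims to reproduce individual-level results.
Reproducing the published mean scores exactly is explicitly out of scope.

## Numerical choices and degenerate inputs

* Percentage rounding half away from zero; all CSV outputs keep full
  precision, rounding is display-only.
* z-test: degenerate pooled proportions return (0, 1), not NaN.
* IRLS: working weights floored at 1e-10; log-likelihood terms floored at
  1e-300; separation detected at |β| > 30.
* `prevalence_cell()` refuses zero denominators; `build_table1()` refuses
  empty group × band strata; `run_score_analysis()` reports NA (rather
  than testing) for empty sex/age strata, which occur in tiny or
  single-sex cohorts.
* BMI classes are closed on the left: [25, 30) is the middle class, 30.0
  is obese. Age bands are inclusive: 44 → 18–44, 45 → 45–54.

## Problem sizes used in the test suite

Simulation-backed tests use cohorts of 150–2,000 respondents per group;
the marginal-recovery check draws 100,000 per group; logistic parameter
recovery uses n = 50,000 with planted β = (−1.0, 0.8, −0.5, 0.02)
recovered within ±0.05; the monotonicity property runs 10,000 randomized
single-answer degradations; the end-to-end direction check runs 20 seeds
at the default 342/1789 sizes. These sizes keep each check's Monte-Carlo
error well below its assertion margin.

## Known limitations

* The default intermediate-category mapping is a documented
  reconstruction, not a published ground truth; treat factor-level point
  assignments as configuration.
* Identity dependence understates real behavioral clustering (see above).
* Wald intervals and the normal-approximation z-test are large-sample
  tools; with very sparse cells prefer the Haldane-corrected OR and read
  p-values with care. No exact tests, survey weighting, matching, or
  imputation are provided.
* The score is descriptive: it has not been calibrated against stroke
  outcomes, and the package deliberately offers no risk prediction.
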
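# hbsr

Composite health-behavior risk scoring and case–control comparison for
young-stroke epidemiology.

Behavioral risk factors — smoking, excess weight, inactivity, poor diet,
alcohol — are highly prevalent in young adults who suffer an ischemic
stroke. `hbsr` implements the Health Behavior Stroke Risk (HBSR) score, a
simple 0–10 composite built from a nine-question lifestyle questionnaire,
together with the complete statistical pipeline used to compare a patient
cohort against population-survey controls, and a seedable synthetic cohort
generator so the whole pipeline can be exercised without individual-level
survey data.

## The score

Five factors are each graded **low / moderate / high** risk, worth
**0 / 1 / 2** points, and summed:

| factor   | low (0)                  | moderate (1)                | high (2) |
|----------|--------------------------|-----------------------------|----------|
| smoking  | never                    | occasional / ex-smoker      | daily smoker |
| BMI      | < 25                     | 25–29.9                     | ≥ 30 |
| exercise | ≥ 2×/week                | 1×/week – 2–3×/month        | a few times a year or none |
| diet     | neither adverse          | one adverse                 | salts before tasting **and** vegetables < 6 days/week |
| alcohol  | neither adverse          | one adverse                 | drinks ≥ 1×/week **and** > 8 (F) / > 16 (M) units in 7 days |

The total *S* ∈ {0, …, 10}; *S* ≥ 6 defines the **high-risk band**.
The whole mapping is a configurable `hbsr_config()` object, so an
alternative categorization can be dropped in without code changes.

## The statistics

* complete-case prevalence cells `n (%)` per category × group × age band
  (18–44 / 45–54), with the pooled two-proportion z-test
  *z = (p̂₁ − p̂₂) / √(p̂(1−p̂)(1/n₁ + 1/n₂))* and Bonferroni correction
  within each variable block (`build_table1()`);
* crude and adjusted odds ratios from an internally implemented
  iteratively-reweighted-least-squares logistic fit with Wald 95% CIs
  (`fit_logistic()`, `run_or_analysis()`; adjustment tiers: none,
  age + sex, age + sex + education + marital status);
* Welch two-sided t-test on mean scores plus high-band prevalence overall
  and stratified by sex and age band (`run_score_analysis()`);
* a Gaussian-copula synthetic cohort generator whose defaults reproduce
  the published category marginals, missingness and covariate mix
  (`generate_cohort()`, `default_table1_spec()`).

Fitted logistic models support broom-style `tidy()` / `glance()`, and every
result type has an `autoplot()` method.

## Worked example

```r
library(hbsr)
library(dplyr)

cohort   <- generate_cohort(seed = 42)          # synthetic study: 342 + 1789
patients <- filter(cohort, group == "patient")
controls <- filter(cohort, group == "control")

run_score_analysis(patients, controls)
#> Mean HBSR score: patients 4.5 [CI 4.4-4.7, SD 1.57] vs controls 3.5 [CI 3.5-3.6, SD 1.63]; two-sided t-test (Welch) p .000
#>
#> High band (score 6-10) prevalence:
#>   overall    28.0% vs 12.3%  p .000 (adj .000)
#>   male       29.2% vs 12.0%  p .000 (adj .000)
#>   female     25.6% vs 12.5%  p .001 (adj .003)
#>   age_18_44  21.4% vs 10.5%  p .001 (adj .002)
#>   age_45_54  33.1% vs 17.2%  p .000 (adj .000)

run_or_analysis(patients, controls, models = "age_sex",
                exposures = c("hr_daily_smoking", "hr_obesity", "high_hbsr"))
#> Odds ratios, patients vs controls (Wald 95% CI)
#>   models: crude | age_sex (age + sex) | full (+ education + marital)
#>
#>   hr_daily_smoking
#>     age_sex  OR  3.14 [2.44-4.04]  p .000  n=2110
#>   hr_obesity
#>     age_sex  OR  1.61 [1.20-2.15]  p .001  n=2099
#>   high_hbsr
#>     age_sex  OR  2.43 [1.76-3.37]  p .000  n=1945
```

Patients score about one point higher on average and are two to three
times as likely to sit in the high band or to smoke daily — the direction
and rough size expected when the generator's group-specific marginals are
pushed through the score. Percentages are complete-case: respondents
missing an answer are excluded from that variable's denominator only.

A command-line wrapper covers the same pipeline:

```sh
inst/exec/hbsr simulate --seed 1 --out cohort.csv
inst/exec/hbsr analyze  --input cohort.csv --out results/
```

## Package layout

* `R/` — cohort data model and CSV reader, scoring engine, statistics,
  synthetic generator, report pipeline, plots, CLI
* `inst/extdata/` — data dictionary (JSON) and the versioned default
  scoring configuration (YAML)
* `vignettes/hbsr-methods.Rmd` — model, assumptions, design choices and
  limitations
* `tests/testthat/` — unit, property and acceptance suites
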
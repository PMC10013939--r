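# Build small cohorts in code. make_respondent() gives a fully low-risk
# respondent; override any field.
make_respondent <- function(id = "r1", group = "patient", age = 40L,
                            sex = "male", education = "higher",
                            marital = "married_cohabiting",
                            smoking = "never", bmi = 22,
                            exercise = "ge4_per_week", veg_days = 7L,
                            salting = "never", alcohol_freq = "none",
                            alcohol_units_7d = 0) {
  tibble::tibble(id = id, group = group, age = as.integer(age), sex = sex,
                 education = education, marital = marital, smoking = smoking,
                 bmi = bmi, exercise = exercise,
                 veg_days = as.integer(veg_days), salting = salting,
                 alcohol_freq = alcohol_freq,
                 alcohol_units_7d = alcohol_units_7d)
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(rows)
  out$id <- sprintf("r%03d", seq_len(nrow(out)))
  out
}

# A maximally high-risk respondent under the default configuration.
make_worst_respondent <- function(id = "w1", sex = "male") {
  make_respondent(id = id, sex = sex, smoking = "daily", bmi = 32,
                  exercise = "rare_or_none", veg_days = 2L,
                  salting = "before_tasting", alcohol_freq = "ge2_per_week",
                  alcohol_units_7d = if (sex == "male") 20 else 10)
}

# Random valid respondents (all answers present) for property tests.
random_cohort <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("x%05d", seq_len(n)),
    group = sample(c("patient", "control"), n, TRUE),
    age = sample(18:54, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    education = sample(c("basic", "secondary", "higher"), n, TRUE),
    marital = sample(c("married_cohabiting", "single", "divorced_widowed"), n, TRUE),
    smoking = sample(c("daily", "occasional", "ex_smoker", "never"), n, TRUE),
    bmi = runif(n, 17, 42),
    exercise = sample(c("ge4_per_week", "w2_3_per_week", "once_per_week",
                        "m2_3_per_month", "rare_or_none"), n, TRUE),
    veg_days = sample(0:7, n, TRUE),
    salting = sample(c("before_tasting", "when_needed", "never"), n, TRUE),
    alcohol_freq = sample(c("ge2_per_week", "once_per_week", "m2_3_per_month",
                            "few_per_year", "none"), n, TRUE),
    alcohol_units_7d = runif(n, 0, 30)
  )
}

# Small simulation spec: cuts both group sizes for fast pipeline tests.
small_spec <- function(n_patient = 150L, n_control = 400L) {
  spec <- default_table1_spec()
  spec$covariates$n <- c(patient = n_patient, control = n_control)
  spec
}
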
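test_that("single factors grade per the default mapping", {
  d <- make_respondent(smoking = "daily")
  expect_equal(grade_factor(d, "smoking"), "high")
  expect_equal(grade_factor(make_respondent(smoking = "ex_smoker"), "smoking"),
               "moderate")
  expect_equal(grade_factor(make_respondent(bmi = 30), "bmi"), "high")
  expect_equal(grade_factor(make_respondent(exercise = "rare_or_none"),
                            "exercise"), "high")
  expect_error(grade_factor(d, "sleep"))
})

test_that("composite diet grades match exhaustive enumeration of the answer grid", {
  grid <- expand.grid(salting = c("before_tasting", "when_needed", "never"),
                      veg_days = c(3L, 7L), stringsAsFactors = FALSE)
  d <- make_respondent()[rep(1, nrow(grid)), ]
  d$salting <- grid$salting
  d$veg_days <- grid$veg_days
  got <- grade_factor(d, "diet")
  # independent enumeration: count adverse sub-answers directly
  want <- sapply(seq_len(nrow(grid)), function(i) {
    n <- (grid$salting[i] == "before_tasting") + (grid$veg_days[i] < 6)
    c("low", "moderate", "high")[n + 1]
  })
  expect_equal(got, want)
  # the spec'd corner cases
  expect_equal(got[grid$salting == "never" & grid$veg_days == 7L], "low")
  expect_equal(got[grid$salting == "before_tasting" & grid$veg_days == 3L],
               "high")
})

test_that("totals span 0-10 and the 5/6 band boundary is exact", {
  best <- hbsr_score(make_respondent())
  expect_equal(best$total, 0L)
  expect_equal(best$band, "low")
  worst <- hbsr_score(make_worst_respondent())
  expect_equal(worst$total, 10L)
  expect_equal(worst$band, "high")
  # totals 5 and 6 straddle the band boundary: moderate on all five factors
  # gives 5 (low); upgrading one factor to high gives 6 (high)
  five <- make_respondent(smoking = "occasional", bmi = 27,
                          exercise = "once_per_week", veg_days = 3L,
                          alcohol_freq = "once_per_week")
  s5 <- hbsr_score(five)
  expect_equal(s5$total, 5L)
  expect_equal(s5$band, "low")
  six <- dplyr::mutate(five, smoking = "daily")
  s6 <- hbsr_score(six)
  expect_equal(s6$total, 6L)
  expect_equal(s6$band, "high")
})

test_that("missing-factor policies behave as documented", {
  d <- make_respondent(smoking = NA)
  strict <- hbsr_score(d)
  expect_true(is.na(strict$total))
  expect_true(is.na(strict$band))
  expect_equal(strict$n_missing_factors, 1L)
  lenient <- hbsr_score(d, hbsr_config(missing_policy = "treat_missing_as_low"))
  expect_equal(lenient$total, 0L)
  expect_equal(lenient$band, "low")
})

test_that("vectorized scores agree with the per-respondent oracle", {
  cohort <- random_cohort(400, seed = 21)
  set.seed(22)
  for (col in c("smoking", "bmi", "veg_days", "alcohol_freq")) {
    cohort[[col]][sample(400, 30)] <- NA
  }
  got <- hbsr_score(cohort)$total
  expect_equal(got, oracle_scores(cohort))
})

test_that("score distribution counts match brute-force recomputation", {
  expect_equal(score_distribution(make_respondent()[rep(1, 3), ])$n,
               c(3L, rep(0L, 10)))
  empty <- score_distribution(make_respondent()[0, ])
  expect_equal(sum(empty$n), 0L)

  cohort <- generate_cohort(spec = small_spec(), seed = 31)
  d <- score_distribution(cohort)
  want <- oracle_scores(cohort)
  expect_equal(d$n, as.integer(tabulate(factor(want, levels = 0:10), 11)))
  expect_equal(attr(d, "n_missing"), sum(is.na(want)))
  expect_equal(sum(d$n) + attr(d, "n_missing"), nrow(cohort))
})

test_that("scoring any combination of valid categories never errors", {
  grid <- expand.grid(
    smoking = hbsr:::hbsr_levels$smoking,
    bmi = c(22, 27, 32),
    exercise = hbsr:::hbsr_levels$exercise,
    stringsAsFactors = FALSE)
  d <- make_respondent()[rep(1, nrow(grid)), ]
  d[names(grid)] <- grid
  expect_no_error(s <- hbsr_score(d))
  expect_true(all(s$total >= 0 & s$total <= 10))
})

test_that("degrading any single answer never decreases the total", {
  worse <- list(
    smoking = c("never", "occasional", "ex_smoker", "daily"),
    bmi = c(22, 27, 32),
    exercise = c("ge4_per_week", "w2_3_per_week", "once_per_week",
                 "m2_3_per_month", "rare_or_none"),
    veg_days = 7:0,
    salting = c("never", "when_needed", "before_tasting"),
    alcohol_freq = c("none", "few_per_year", "m2_3_per_month",
                     "once_per_week", "ge2_per_week"),
    alcohol_units_7d = c(0, 5, 20))
  cohort <- random_cohort(500, seed = 41)
  cohort$bmi <- sample(worse$bmi, 500, TRUE)
  cohort$alcohol_units_7d <- sample(worse$alcohol_units_7d, 500, TRUE)
  base <- hbsr_score(cohort)$total
  set.seed(42)
  fields <- sample(names(worse), 500, TRUE)
  degraded <- cohort
  for (i in seq_len(500)) {
    ladder <- worse[[fields[i]]]
    pos <- match(degraded[[fields[i]]][i], ladder)
    new_pos <- pos - 1L + sample.int(length(ladder) - pos + 1L, 1)
    degraded[[fields[i]]][i] <- ladder[new_pos]
  }
  expect_true(all(hbsr_score(degraded)$total >= base))
})

test_that("sample mean converges to the closed-form expectation under independence", {
  # single-band spec with no missingness so the expectation is exact
  spec <- small_spec(20000L, 20000L)
  for (g in c("patient", "control")) {
    spec$covariates$age_bands[[g]] <- tibble::tibble(lo = 18L, hi = 44L, prob = 1)
  }
  spec$missingness$miss_rate <- 0
  cohort <- generate_cohort(spec = spec, seed = 51)
  marg <- spec$marginals
  for (g in c("patient", "control")) {
    p <- function(v, cats) {
      sum(marg$prob[marg$group == g & marg$band == "b18_44" &
                      marg$variable == v & marg$category %in% cats])
    }
    e_total <-
      (2 * p("smoking", "daily") + p("smoking", c("occasional", "ex_smoker"))) +
      (2 * p("bmi", "ge30") + p("bmi", "b25_29_9")) +
      (2 * p("exercise", "rare_or_none") +
         p("exercise", c("once_per_week", "m2_3_per_month"))) +
      (2 * p("salting", "before_tasting") * p("vegetables", "lt6") +
         p("salting", "before_tasting") * p("vegetables", "ge6") +
         (1 - p("salting", "before_tasting")) * p("vegetables", "lt6")) +
      (2 * p("alcohol_freq", c("ge2_per_week", "once_per_week")) *
         p("alcohol_excess", "yes") +
         p("alcohol_freq", c("ge2_per_week", "once_per_week")) *
         p("alcohol_excess", "no") +
         p("alcohol_freq", c("m2_3_per_month", "few_per_year", "none")) *
         p("alcohol_excess", "yes"))
    totals <- hbsr_score(cohort[cohort$group == g, ])$total
    mc_se <- stats::sd(totals) / sqrt(length(totals))
    expect_lt(abs(mean(totals) - e_total), 4 * mc_se)
  }
})
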
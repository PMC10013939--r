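# Engineer a patient stratum with exactly 62/133 daily smokers aged 18-44
# (2 of 135 respondents missing the smoking answer), plus any controls.
engineered_cohorts <- function() {
  pat <- make_respondent()[rep(1, 135), ]
  pat$id <- sprintf("p%03d", 1:135)
  pat$age <- 30L
  pat$smoking <- c(rep("daily", 62), rep("never", 71), NA, NA)
  ctr <- make_respondent(group = "control")[rep(1, 300), ]
  ctr$id <- sprintf("c%03d", 1:300)
  ctr$age <- rep(c(30L, 50L), 150)
  ctr$smoking <- rep(c("daily", "never", "never"), 100)
  pat2 <- make_respondent()[rep(1, 40), ]    # non-empty patient 45-54 stratum
  pat2$id <- sprintf("q%03d", 1:40)
  pat2$age <- 50L
  list(patients = dplyr::bind_rows(pat, pat2), controls = ctr)
}

test_that("prevalence cells render published-style counts and percentages", {
  co <- engineered_cohorts()
  t1 <- build_table1(co$patients, co$controls)
  row <- t1[t1$band == "b18_44" & t1$variable == "smoking" &
              t1$category == "daily", ]
  expect_equal(row$patients_count, 62L)
  expect_equal(row$patients_denom, 133L)
  expect_equal(row$patients_pct, 46.6)
  rendered <- sprintf("%d (%.1f)", row$patients_count, row$patients_pct)
  expect_equal(rendered, "62 (46.6)")
})

test_that("every cell matches a brute-force per-respondent recount", {
  cohort <- generate_cohort(spec = small_spec(), seed = 12)
  pats <- cohort[cohort$group == "patient", ]
  ctrs <- cohort[cohort$group == "control", ]
  t1 <- build_table1(pats, ctrs)
  cats <- hbsr:::derive_categories(dplyr::bind_rows(pats, ctrs))
  for (i in sample(nrow(t1), 25)) {
    r <- t1[i, ]
    inb <- cats[cats$band == r$band & !is.na(cats[[r$variable]]), ]
    expect_equal(r$patients_count,
                 sum(inb$group == "patient" & inb[[r$variable]] == r$category))
    expect_equal(r$patients_denom, sum(inb$group == "patient"))
    expect_equal(r$controls_count,
                 sum(inb$group == "control" & inb[[r$variable]] == r$category))
    expect_equal(r$controls_denom, sum(inb$group == "control"))
  }
})

test_that("identical groups produce no significance marks", {
  base <- generate_cohort(spec = small_spec(250L, 1L), seed = 13)
  pat <- base[base$group == "patient", ]
  ctr <- dplyr::mutate(pat, group = "control", id = paste0("c", id))
  t1 <- build_table1(pat, ctr)
  expect_false(any(t1$significant))
  expect_true(all(t1$p[!is.na(t1$p)] > 0.999))
})

test_that("binary variable blocks carry one test, multi-category blocks m tests", {
  co <- engineered_cohorts()
  t1 <- build_table1(co$patients, co$controls)
  veg <- t1[t1$band == "b18_44" & t1$variable == "vegetables", ]
  expect_equal(sum(!is.na(veg$p)), 1)
  smo <- t1[t1$band == "b18_44" & t1$variable == "smoking", ]
  expect_equal(sum(!is.na(smo$p)), 4)
  expect_equal(smo$p_adjusted, pmin(1, 4 * smo$p))
})

test_that("empty strata are an explicit error", {
  co <- engineered_cohorts()
  young_only <- co$patients[co$patients$age < 45, ]
  expect_error(build_table1(young_only, co$controls), "stratum")
})

test_that("crude OR tier equals the closed-form 2x2 odds ratio", {
  cohort <- generate_cohort(spec = small_spec(), seed = 14)
  pats <- cohort[cohort$group == "patient", ]
  ctrs <- cohort[cohort$group == "control", ]
  ors <- run_or_analysis(pats, ctrs, models = "crude")
  ind <- add_risk_indicators(dplyr::bind_rows(pats, ctrs))
  for (ex in c("hr_daily_smoking", "hr_obesity", "hr_low_veg")) {
    flag <- ind[[ex]]
    case <- ind$group == "patient"
    keep <- !is.na(flag)
    tab <- crude_or(sum(case & flag & keep), sum(!case & flag & keep),
                    sum(case & !flag & keep), sum(!case & !flag & keep))
    row <- ors[ors$exposure == ex, ]
    expect_equal(row$or, tab$or, tolerance = 1e-6)
    expect_equal(row$ci_low, tab$ci_low, tolerance = 1e-4)
    expect_equal(row$n_used, tab$n_used)
  }
})

test_that("adjustment removes planted confounding by sex", {
  # exposure depends on sex; outcome depends on sex and exposure
  set.seed(15)
  n <- 20000
  sex <- sample(c("male", "female"), n, TRUE)
  expo <- rbinom(n, 1, ifelse(sex == "male", 0.55, 0.15))
  y <- rbinom(n, 1, plogis(-2 + 0.9 * expo + 1.2 * (sex == "male")))
  base <- make_respondent()[rep(1, n), ]
  base$id <- sprintf("s%05d", 1:n)
  base$group <- ifelse(y == 1, "patient", "control")
  base$sex <- sex
  base$smoking <- ifelse(expo == 1, "daily", "never")
  base$age <- sample(18:54, n, TRUE)
  pats <- base[base$group == "patient", ]
  ctrs <- base[base$group == "control", ]
  ors <- run_or_analysis(pats, ctrs, models = c("crude", "age_sex"),
                         exposures = "hr_daily_smoking")
  crude <- log(ors$or[ors$exposure == "hr_daily_smoking" & ors$model == "crude"])
  adj <- log(ors$or[ors$exposure == "hr_daily_smoking" & ors$model == "age_sex"])
  expect_lt(abs(adj - 0.9), 0.15)    # adjusted recovers the planted log-OR
  expect_gt(crude, adj + 0.1)        # crude biased upward by the sex mix
})

test_that("OR confidence intervals cover the null for a null exposure", {
  covered <- vapply(1:100, function(s) {
    d <- random_cohort(700, seed = 1000 + s)   # every field independent of group
    ors <- run_or_analysis(d[d$group == "patient", ],
                           d[d$group == "control", ], models = "crude",
                           exposures = "hr_daily_smoking")
    row <- ors[ors$exposure == "hr_daily_smoking", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("identical cohorts give a null mean-score comparison", {
  cohort <- generate_cohort(spec = small_spec(200L, 1L), seed = 16)
  pat <- cohort[cohort$group == "patient", ]
  ctr <- dplyr::mutate(pat, group = "control", id = paste0("c", id))
  sa <- run_score_analysis(pat, ctr)
  expect_equal(sa$mean_comparison$mean1, sa$mean_comparison$mean2)
  expect_equal(sa$mean_comparison$p, 1, tolerance = 1e-12)
  expect_true(all(sa$high_band$patients_pct == sa$high_band$controls_pct))
})

test_that("a hand-built four-respondent cohort scores as computed by hand", {
  pat <- dplyr::bind_rows(
    make_worst_respondent(),                       # 10
    make_respondent(smoking = "occasional",        # 1 + 1 + 2 + 1 + 1 = 6
                    bmi = 26, exercise = "rare_or_none", veg_days = 5L,
                    alcohol_freq = "once_per_week", alcohol_units_7d = 2))
  pat$id <- c("p1", "p2")
  ctr <- dplyr::bind_rows(
    make_respondent(group = "control"),            # 0
    make_respondent(group = "control", smoking = "ex_smoker",  # 1 + 1 = 2
                    bmi = 27))
  ctr$id <- c("c1", "c2")
  sa <- run_score_analysis(pat, ctr)
  expect_equal(sort(hbsr_score(pat)$total), c(6L, 10L))
  expect_equal(sort(hbsr_score(ctr)$total), c(0L, 2L))
  expect_equal(sa$mean_comparison$mean1, 8)
  expect_equal(sa$mean_comparison$mean2, 1)
  dist <- sa$distribution
  expect_equal(sum(dist$n[dist$group == "patient"]), 2)
  expect_equal(dist$n[dist$group == "patient" & dist$score == 10], 1)
})

test_that("distribution counts conserve the number of complete scores", {
  cohort <- generate_cohort(spec = small_spec(), seed = 17)
  pat <- cohort[cohort$group == "patient", ]
  ctr <- cohort[cohort$group == "control", ]
  sa <- run_score_analysis(pat, ctr)
  nm <- attr(sa$distribution, "n_missing")
  expect_equal(sum(sa$distribution$n[sa$distribution$group == "patient"]) +
                 nm[["patient"]], nrow(pat))
  expect_equal(sum(sa$distribution$n[sa$distribution$group == "control"]) +
                 nm[["control"]], nrow(ctr))
})

test_that("the full report is reproducible and written to disk as pure views", {
  cohort <- generate_cohort(spec = small_spec(), seed = 18)
  pat <- cohort[cohort$group == "patient", ]
  ctr <- cohort[cohort$group == "control", ]
  r1 <- analyze_cohorts(pat, ctr)
  r2 <- analyze_cohorts(pat, ctr)
  expect_identical(r1, r2)

  dir <- withr::local_tempdir()
  write_report(r1, dir)
  files <- c("table1.csv", "odds_ratios.csv", "score_summary.csv",
             "score_distribution.csv", "report.txt")
  expect_true(all(file.exists(file.path(dir, files))))
  # report is a pure view: the CSV reloads to the same numbers
  back <- readr::read_csv(file.path(dir, "table1.csv"),
                          show_col_types = FALSE)
  expect_equal(back$patients_count, r1$table1$patients_count)
  expect_equal(back$p, r1$table1$p, tolerance = 1e-12)
})
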
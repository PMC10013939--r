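#' Grade one behavior factor for every respondent
#'
#' Maps each respondent's answers for a single factor to a risk grade
#' (`low`, `moderate`, `high`). The two composite factors combine two
#' sub-answers: diet (meal-salting habit + vegetable days) and alcohol
#' (drinking frequency + 7-day amount) grade high when both sub-answers are
#' adverse, moderate when exactly one is, low when neither is. A factor is
#' missing whenever any of its required answers is missing.
#'
#' @param data A cohort data frame.
#' @param factor One of `"smoking"`, `"bmi"`, `"exercise"`, `"diet"`,
#'   `"alcohol"`.
#' @param config An [hbsr_config()].
#' @return Character vector of grades (`NA` where unscorable).
#' @export
#' @examples
#' d <- tibble::tibble(
#'   id = "a", group = "patient", age = 40L, sex = "male",
#'   education = "higher", marital = "single", smoking = "daily",
#'   bmi = 27, exercise = "rare_or_none", veg_days = 3L,
#'   salting = "before_tasting", alcohol_freq = "once_per_week",
#'   alcohol_units_7d = 4)
#' grade_factor(d, "smoking")
#' grade_factor(d, "diet")
grade_factor <- function(data, factor, config = hbsr_config()) {
  factor <- match.arg(factor, c("smoking", "bmi", "exercise", "diet", "alcohol"))
  data <- tibble::as_tibble(data)
  switch(
    factor,
    smoking = unname(config$smoking[as.character(data$smoking)]),
    bmi = unname(config$bmi[bmi_class(data$bmi)]),
    exercise = unname(config$exercise[as.character(data$exercise)]),
    diet = {
      a1 <- in_set_na(data$salting, config$diet$adverse_salting)
      a2 <- data$veg_days < config$diet$veg_days_threshold
      composite_grade(a1, a2, config)
    },
    alcohol = {
      ind <- add_risk_indicators(data, config)
      composite_grade(ind$hr_alcohol_freq, ind$hr_alcohol_units, config)
    }
  )
}

composite_grade <- function(adverse1, adverse2, config) {
  n_adv <- as.integer(adverse1) + as.integer(adverse2)
  unname(config$composite_grades[n_adv + 1L])
}

#' Compute the HBSR score
#'
#' Scores every respondent: each of the five factors (smoking, BMI,
#' exercise, diet, alcohol) is graded low / moderate / high and worth
#' 0 / 1 / 2 points; the total ranges 0-10, with 10 the highest behavioral
#' risk. Totals of `high_cutoff` (default 6) or more fall in the high band,
#' lower totals in the low band. Under the default `require_complete`
#' policy a respondent missing any factor gets a missing total and band
#' (excluded from mean-score analyses); under `treat_missing_as_low`
#' missing factors contribute 0 points.
#'
#' @param data A cohort data frame.
#' @param config An [hbsr_config()].
#' @return A tibble with one row per respondent: `id`, the five
#'   `<factor>_pts` columns (0-2 or `NA`), `n_missing_factors`, `total`
#'   (0-10 or `NA`) and `band` (`"low"` / `"high"` / `NA`).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' scores <- hbsr_score(cohort)
#' table(scores$band, useNA = "ifany")
hbsr_score <- function(data, config = hbsr_config()) {
  data <- tibble::as_tibble(data)
  factors <- c("smoking", "bmi", "exercise", "diet", "alcohol")
  pts <- lapply(factors, function(f) {
    unname(grade_points[grade_factor(data, f, config)])
  })
  names(pts) <- paste0(factors, "_pts")
  pts_mat <- do.call(cbind, pts)
  n_missing <- as.integer(rowSums(is.na(pts_mat)))

  if (config$missing_policy == "require_complete") {
    total <- ifelse(n_missing == 0L, as.integer(rowSums(pts_mat)), NA_integer_)
  } else {
    total <- as.integer(rowSums(pts_mat, na.rm = TRUE))
  }
  band <- ifelse(is.na(total), NA_character_,
                 ifelse(total >= config$high_cutoff, "high", "low"))

  tibble::tibble(id = data$id, !!!pts,
                 n_missing_factors = n_missing,
                 total = total, band = band)
}

#' Tabulate the HBSR score distribution
#'
#' Counts respondents at each total score 0-10. Respondents whose score is
#' missing (incomplete answers under the `require_complete` policy) are
#' reported separately in the `n_missing` attribute, so counts sum to the
#' number of completely scored respondents.
#'
#' @param data A cohort data frame, or a tibble already carrying a `total`
#'   column as returned by [hbsr_score()].
#' @param config An [hbsr_config()].
#' @return A tibble of class `hbsr_distribution` with columns `score`
#'   (0-10) and `n`, and attribute `n_missing`.
#' @export
#' @examples
#' d <- score_distribution(generate_cohort(seed = 1))
#' sum(d$n) + attr(d, "n_missing")
score_distribution <- function(data, config = hbsr_config()) {
  totals <- if ("total" %in% names(data)) data$total else hbsr_score(data, config)$total
  counts <- tabulate(factor(totals, levels = 0:10), nbins = 11L)
  out <- tibble::tibble(score = 0:10, n = counts)
  attr(out, "n_missing") <- sum(is.na(totals))
  class(out) <- c("hbsr_distribution", class(out))
  out
}
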
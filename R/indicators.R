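#' Derive the seven binary high-risk indicators
#'
#' Adds one logical column per high-risk behavior: daily smoking, obesity
#' (BMI >= 30), exercising less than twice a week, salting ready-made meals
#' before tasting, vegetable consumption on fewer than 6 days a week,
#' drinking once a week or more, and an excessive 7-day alcohol intake
#' (more than 8 standard units for women / 16 for men under the default
#' configuration). Each flag is `NA` whenever its source answer is missing;
#' the flags depend only on the respondent's own fields and the
#' configuration.
#'
#' @param data A cohort data frame.
#' @param config An [hbsr_config()].
#' @return `data` with logical columns `hr_daily_smoking`, `hr_obesity`,
#'   `hr_low_exercise`, `hr_salting`, `hr_low_veg`, `hr_alcohol_freq`,
#'   `hr_alcohol_units` appended.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   id = "a", group = "patient", age = 40L, sex = "female",
#'   education = "higher", marital = "single", smoking = "never",
#'   bmi = 31, exercise = "w2_3_per_week", veg_days = 7L,
#'   salting = "never", alcohol_freq = "none", alcohol_units_7d = 0)
#' add_risk_indicators(d)[hbsr_indicator_names]
add_risk_indicators <- function(data, config = hbsr_config()) {
  data <- tibble::as_tibble(data)
  thr <- config$alcohol$units_threshold[data$sex]
  over <- if (config$alcohol$units_comparison == ">") {
    data$alcohol_units_7d > thr
  } else {
    data$alcohol_units_7d >= thr
  }
  dplyr::mutate(
    data,
    hr_daily_smoking = in_set_na(.data$smoking, "daily"),
    hr_obesity = in_set_na(bmi_class(.data$bmi), "ge30"),
    hr_low_exercise = in_set_na(.data$exercise,
                                c("once_per_week", "m2_3_per_month",
                                  "rare_or_none")),
    hr_salting = in_set_na(.data$salting, config$diet$adverse_salting),
    hr_low_veg = .data$veg_days < config$diet$veg_days_threshold,
    hr_alcohol_freq = in_set_na(.data$alcohol_freq, config$alcohol$adverse_freq),
    hr_alcohol_units = unname(over)
  )
}

#' Names of the seven high-risk indicator columns
#' @export
hbsr_indicator_names <- c(
  "hr_daily_smoking", "hr_obesity", "hr_low_exercise", "hr_salting",
  "hr_low_veg", "hr_alcohol_freq", "hr_alcohol_units"
)
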
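# Canonical category tokens for every questionnaire variable. These are the
# tokens the CSV reader accepts and the generator emits; the shipped data
# dictionary (inst/extdata/data_dictionary.json) documents them for users.

hbsr_levels <- list(
  group        = c("patient", "control"),
  sex          = c("male", "female"),
  education    = c("basic", "secondary", "higher"),
  marital      = c("married_cohabiting", "single", "divorced_widowed"),
  smoking      = c("daily", "occasional", "ex_smoker", "never"),
  exercise     = c("ge4_per_week", "w2_3_per_week", "once_per_week",
                   "m2_3_per_month", "rare_or_none"),
  salting      = c("before_tasting", "when_needed", "never"),
  alcohol_freq = c("ge2_per_week", "once_per_week", "m2_3_per_month",
                   "few_per_year", "none"),
  bmi_class    = c("lt25", "b25_29_9", "ge30"),
  age_band     = c("b18_44", "b45_54"),
  vegetables   = c("ge6", "lt6"),
  alcohol_excess = c("yes", "no")
)

# Columns of a cohort data frame, in canonical order.
cohort_columns <- c(
  "id", "group", "age", "sex", "education", "marital",
  "smoking", "bmi", "exercise", "veg_days", "salting",
  "alcohol_freq", "alcohol_units_7d"
)

# The seven behavioral variables as they appear in stratified prevalence
# tables, with their category sets.
table_variables <- list(
  smoking        = hbsr_levels$smoking,
  bmi            = hbsr_levels$bmi_class,
  exercise       = hbsr_levels$exercise,
  vegetables     = hbsr_levels$vegetables,
  salting        = hbsr_levels$salting,
  alcohol_freq   = hbsr_levels$alcohol_freq,
  alcohol_excess = hbsr_levels$alcohol_excess
)

#' Questionnaire data dictionary
#'
#' Reads the data dictionary shipped with the package: the cohort CSV column
#' names, their types, and the accepted category tokens for every enumerated
#' variable.
#'
#' @return A named list with one entry per cohort column.
#' @export
#' @examples
#' names(hbsr_data_dictionary())
hbsr_data_dictionary <- function() {
  path <- system.file("extdata", "data_dictionary.json", package = "hbsr")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
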
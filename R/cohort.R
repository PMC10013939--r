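#' Classify body-mass index
#'
#' Class boundaries follow the usual epidemiological convention and are
#' closed on the left: `< 25` is `lt25`, `[25, 30)` is `b25_29_9`, and
#' `>= 30` (obesity) is `ge30`. Missing BMI stays missing.
#'
#' @param bmi Numeric vector of BMI values (kg/m2), possibly with `NA`.
#' @return Character vector with values `"lt25"`, `"b25_29_9"`, `"ge30"`
#'   or `NA`.
#' @export
#' @examples
#' bmi_class(c(24.9, 25, 29.9, 30, NA))
bmi_class <- function(bmi) {
  dplyr::case_when(
    is.na(bmi) ~ NA_character_,
    bmi < 25 ~ "lt25",
    bmi < 30 ~ "b25_29_9",
    TRUE ~ "ge30"
  )
}

#' Assign the study age band
#'
#' Bands are inclusive: ages 18-44 fall in `b18_44`, ages 45-54 in
#' `b45_54`. Ages outside 18-54 return `NA` (such records are rejected by
#' [read_cohort()]).
#'
#' @param age Integer vector of ages in years.
#' @return Character vector with values `"b18_44"`, `"b45_54"` or `NA`.
#' @export
#' @examples
#' age_band(c(18, 44, 45, 54))
age_band <- function(age) {
  dplyr::case_when(
    is.na(age) ~ NA_character_,
    age >= 18 & age <= 44 ~ "b18_44",
    age >= 45 & age <= 54 ~ "b45_54",
    TRUE ~ NA_character_
  )
}

# Row-level hard-invariant screen. Returns a character vector of problem
# descriptions, zero-length when the cohort is clean.
cohort_problems <- function(data) {
  probs <- character()
  bad_age <- which(is.na(data$age) | data$age < 18 | data$age > 54)
  if (length(bad_age)) {
    probs <- c(probs, sprintf("row %d: age outside 18-54", bad_age))
  }
  bad_bmi <- which(!is.na(data$bmi) & (data$bmi <= 10 | data$bmi >= 80))
  if (length(bad_bmi)) {
    probs <- c(probs, sprintf("row %d: BMI outside (10, 80)", bad_bmi))
  }
  bad_veg <- which(!is.na(data$veg_days) &
                     !(data$veg_days %in% 0:7))
  if (length(bad_veg)) {
    probs <- c(probs, sprintf("row %d: veg_days not in 0..7", bad_veg))
  }
  bad_units <- which(!is.na(data$alcohol_units_7d) & data$alcohol_units_7d < 0)
  if (length(bad_units)) {
    probs <- c(probs, sprintf("row %d: negative alcohol units", bad_units))
  }
  for (col in c("group", "sex")) {
    bad <- which(is.na(data[[col]]) | !data[[col]] %in% hbsr_levels[[col]])
    if (length(bad)) probs <- c(probs, sprintf("row %d: invalid %s", bad, col))
  }
  for (col in c("education", "marital", "smoking", "exercise", "salting",
                "alcohol_freq")) {
    bad <- which(!is.na(data[[col]]) & !data[[col]] %in% hbsr_levels[[col]])
    if (length(bad)) {
      probs <- c(probs, sprintf("row %d: unknown %s token '%s'",
                                bad, col, data[[col]][bad]))
    }
  }
  probs
}

rows_with_problems <- function(probs) {
  unique(as.integer(sub("^row (\\d+):.*$", "\\1", probs)))
}

#' Validate a cohort data frame
#'
#' Applies the hard row invariants (age 18-54, BMI in (10, 80), vegetable
#' days 0-7, non-negative alcohol units, known category tokens, valid group
#' and sex) and the soft consistency check that respondents who report never
#' drinking have zero 7-day units. In strict mode any violation (or a
#' duplicated id) is an error; otherwise offending rows are dropped with a
#' single summarized warning. Soft inconsistencies only ever warn.
#'
#' @param data A cohort data frame (see [hbsr_data_dictionary()]).
#' @param strict Logical; error instead of dropping bad rows.
#' @return The validated tibble (bad rows removed when `strict = FALSE`).
#' @export
validate_cohort <- function(data, strict = FALSE) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(cohort_columns, names(data))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- data[cohort_columns]

  probs <- cohort_problems(data)
  if (length(probs)) {
    if (strict) {
      abort(c("cohort validation failed", head(probs, 10)))
    }
    drop <- rows_with_problems(probs)
    warn(sprintf("dropping %d invalid row(s): %s%s",
                 length(drop), paste(head(probs, 5), collapse = "; "),
                 if (length(probs) > 5) "; ..." else ""))
    data <- data[-drop, , drop = FALSE]
  }

  if (anyDuplicated(data$id)) {
    msg <- "duplicate respondent ids in cohort"
    if (strict) abort(msg) else warn(msg)
  }

  incons <- which(!is.na(data$alcohol_freq) & data$alcohol_freq == "none" &
                    !is.na(data$alcohol_units_7d) & data$alcohol_units_7d > 0)
  if (length(incons)) {
    warn(sprintf(
      "%d respondent(s) report alcohol_freq = 'none' but non-zero units in the last 7 days",
      length(incons)))
  }
  data
}

#' Read a cohort CSV
#'
#' Reads one questionnaire cohort (or a combined patient + control file)
#' from a UTF-8, comma-delimited CSV with a header row, then validates it
#' with [validate_cohort()]. Empty cells become missing values, never zero.
#' BMI may be given directly (`bmi` column) or as `height_cm` / `weight_kg`
#' columns; when both are present the direct value wins and a discrepancy
#' above 0.5 kg/m2 triggers a warning. Vegetable consumption may be given
#' as `veg_days` (0-7) or as a binary `vegetables` column (`ge6` / `lt6`,
#' mapped to sentinel day counts 6 and 0).
#'
#' @param path Path to the CSV file.
#' @param strict Logical; reject the file on any invalid row instead of
#'   dropping rows with a warning.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE)

  if (!"id" %in% names(data)) abort("cohort file has no 'id' column")

  # height/weight fallback for BMI
  direct_bmi <- if ("bmi" %in% names(data)) as.numeric(data$bmi) else NULL
  if (all(c("height_cm", "weight_kg") %in% names(data))) {
    computed <- as.numeric(data$weight_kg) / (as.numeric(data$height_cm) / 100)^2
    if (is.null(direct_bmi)) {
      direct_bmi <- computed
    } else {
      both <- !is.na(direct_bmi) & !is.na(computed)
      if (any(both & abs(direct_bmi - computed) > 0.5)) {
        warn(sprintf(
          "%d row(s): reported BMI and height/weight disagree by > 0.5 kg/m2; using reported BMI",
          sum(both & abs(direct_bmi - computed) > 0.5)))
      }
      direct_bmi <- ifelse(is.na(direct_bmi), computed, direct_bmi)
    }
  }
  if (is.null(direct_bmi)) direct_bmi <- rep(NA_real_, nrow(data))

  veg <- if ("veg_days" %in% names(data)) {
    suppressWarnings(as.integer(data$veg_days))
  } else if ("vegetables" %in% names(data)) {
    dplyr::case_when(data$vegetables == "ge6" ~ 6L,
                     data$vegetables == "lt6" ~ 0L,
                     TRUE ~ NA_integer_)
  } else {
    rep(NA_integer_, nrow(data))
  }

  get_chr <- function(col) {
    if (col %in% names(data)) as.character(data[[col]]) else rep(NA_character_, nrow(data))
  }
  out <- tibble::tibble(
    id = as.character(data$id),
    group = get_chr("group"),
    age = suppressWarnings(as.integer(data$age)),
    sex = get_chr("sex"),
    education = get_chr("education"),
    marital = get_chr("marital"),
    smoking = get_chr("smoking"),
    bmi = direct_bmi,
    exercise = get_chr("exercise"),
    veg_days = veg,
    salting = get_chr("salting"),
    alcohol_freq = get_chr("alcohol_freq"),
    alcohol_units_7d = suppressWarnings(as.numeric(get_chr("alcohol_units_7d")))
  )
  validate_cohort(out, strict = strict)
}

#' Write a cohort CSV
#'
#' Writes the cohort in the same CSV dialect [read_cohort()] accepts, so a
#' write-then-read round trip preserves every field including missingness.
#'
#' @param data A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data[cohort_columns], path, na = "", progress = FALSE)
  invisible(path)
}
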
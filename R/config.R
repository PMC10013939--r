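#' Scoring configuration for the HBSR score
#'
#' Builds the answer-to-risk-grade mapping used to score the five behavior
#' factors (smoking, BMI, exercise, diet, alcohol). Each factor is graded
#' low / moderate / high, worth 0 / 1 / 2 points, so the total ranges 0-10.
#' The default mapping grades daily smoking, obesity (BMI >= 30), exercising
#' less than twice a week, salting food before tasting combined with eating
#' vegetables on fewer than 6 days a week, and at-least-weekly drinking
#' combined with an excessive 7-day intake (> 8 standard units for women,
#' > 16 for men) as the high-risk categories; intermediate answers grade
#' moderate. Every element can be overridden, so an alternative published
#' categorization can be dropped in without code changes.
#'
#' The two composite factors (diet and alcohol) each combine two
#' sub-variables: they grade high when both sub-answers are adverse,
#' moderate when exactly one is, and low when neither is.
#'
#' @param smoking,bmi,exercise Named character vectors mapping each answer
#'   category (for BMI, each BMI class) to a grade in
#'   `c("low", "moderate", "high")`.
#' @param diet List with `adverse_salting` (salting categories counted as
#'   adverse) and `veg_days_threshold` (days/week below which vegetable
#'   consumption is adverse; default 6).
#' @param alcohol List with `adverse_freq` (drinking-frequency categories
#'   counted as adverse), `units_threshold` (named vector, 7-day standard
#'   drink units per sex) and `units_comparison` (`">"` or `">="`).
#' @param composite_grades Character vector of length 3 giving the grade for
#'   0, 1 or 2 adverse sub-variables of a composite factor.
#' @param high_cutoff Lowest total score assigned to the high band
#'   (default 6: totals 0-5 are low, 6-10 high).
#' @param missing_policy `"require_complete"` (a respondent missing any
#'   factor gets a missing total) or `"treat_missing_as_low"` (missing
#'   factors contribute 0 points).
#'
#' @return An object of class `hbsr_config`.
#' @export
#' @examples
#' cfg <- hbsr_config()
#' cfg$smoking
#' # count ex-smokers as low risk instead:
#' hbsr_config(smoking = c(daily = "high", occasional = "moderate",
#'                         ex_smoker = "low", never = "low"))
hbsr_config <- function(smoking = NULL, bmi = NULL, exercise = NULL,
                        diet = NULL, alcohol = NULL,
                        composite_grades = NULL,
                        high_cutoff = 6L,
                        missing_policy = c("require_complete",
                                           "treat_missing_as_low")) {
  cfg <- list(
    smoking = smoking %||% c(daily = "high", occasional = "moderate",
                             ex_smoker = "moderate", never = "low"),
    bmi = bmi %||% c(ge30 = "high", b25_29_9 = "moderate", lt25 = "low"),
    exercise = exercise %||% c(ge4_per_week = "low", w2_3_per_week = "low",
                               once_per_week = "moderate",
                               m2_3_per_month = "moderate",
                               rare_or_none = "high"),
    diet = utils::modifyList(
      list(adverse_salting = "before_tasting", veg_days_threshold = 6),
      diet %||% list()),
    alcohol = utils::modifyList(
      list(adverse_freq = c("ge2_per_week", "once_per_week"),
           units_threshold = c(female = 8, male = 16),
           units_comparison = ">"),
      alcohol %||% list()),
    composite_grades = composite_grades %||% c("low", "moderate", "high"),
    high_cutoff = as.integer(high_cutoff),
    missing_policy = match.arg(missing_policy)
  )
  class(cfg) <- "hbsr_config"
  validate_config(cfg)
  cfg
}

# Every answer category of every factor must be mapped exactly once, so
# scoring can never hit an unknown-category error.
validate_config <- function(cfg) {
  grades <- c("low", "moderate", "high")
  for (fct in c("smoking", "exercise")) {
    want <- hbsr_levels[[fct]]
    map <- cfg[[fct]]
    if (!setequal(names(map), want) || anyDuplicated(names(map))) {
      abort(sprintf("config: %s mapping must cover categories {%s} exactly once",
                    fct, paste(want, collapse = ", ")))
    }
    if (!all(map %in% grades)) {
      abort(sprintf("config: %s mapping contains an unknown grade", fct))
    }
  }
  if (!setequal(names(cfg$bmi), hbsr_levels$bmi_class) ||
      !all(cfg$bmi %in% grades)) {
    abort("config: bmi mapping must cover classes lt25, b25_29_9, ge30")
  }
  if (!all(cfg$diet$adverse_salting %in% hbsr_levels$salting)) {
    abort("config: unknown salting category in diet$adverse_salting")
  }
  if (!all(cfg$alcohol$adverse_freq %in% hbsr_levels$alcohol_freq)) {
    abort("config: unknown category in alcohol$adverse_freq")
  }
  thr <- cfg$alcohol$units_threshold
  if (!setequal(names(thr), c("female", "male")) || any(thr < 0)) {
    abort("config: alcohol$units_threshold needs non-negative 'female' and 'male' entries")
  }
  if (!cfg$alcohol$units_comparison %in% c(">", ">=")) {
    abort("config: alcohol$units_comparison must be '>' or '>='")
  }
  if (length(cfg$composite_grades) != 3L ||
      !all(cfg$composite_grades %in% grades)) {
    abort("config: composite_grades must be 3 grades (for 0, 1, 2 adverse answers)")
  }
  if (!cfg$high_cutoff %in% 1:10) abort("config: high_cutoff must be in 1..10")
  invisible(cfg)
}

# Points carried by each grade; fixed bijection that makes five factors sum
# to at most 10.
grade_points <- c(low = 0L, moderate = 1L, high = 2L)

#' @export
print.hbsr_config <- function(x, ...) {
  cat("<hbsr_config>\n")
  cat("  smoking: ", paste(names(x$smoking), x$smoking, sep = "=", collapse = ", "), "\n")
  cat("  bmi:     ", paste(names(x$bmi), x$bmi, sep = "=", collapse = ", "), "\n")
  cat("  exercise:", paste(names(x$exercise), x$exercise, sep = "=", collapse = ", "), "\n")
  cat("  diet:     adverse salting {", paste(x$diet$adverse_salting, collapse = ", "),
      "}, vegetables < ", x$diet$veg_days_threshold, " days/week\n", sep = "")
  cat("  alcohol:  adverse freq {", paste(x$alcohol$adverse_freq, collapse = ", "),
      "}, units ", x$alcohol$units_comparison, " ",
      x$alcohol$units_threshold[["female"]], " (F) / ",
      x$alcohol$units_threshold[["male"]], " (M)\n", sep = "")
  cat("  high band: total >=", x$high_cutoff,
      "| missing policy:", x$missing_policy, "\n")
  invisible(x)
}

#' Read or write a scoring configuration as YAML
#'
#' The package ships its default configuration at
#' `system.file("extdata", "default_scoring.yaml", package = "hbsr")`;
#' `read_scoring_config()` of that file reproduces `hbsr_config()`.
#'
#' @param path Path to a YAML file.
#' @return `read_scoring_config()` returns an `hbsr_config`;
#'   `write_scoring_config()` returns `path` invisibly.
#' @export
read_scoring_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fct in c("smoking", "bmi", "exercise")) {
    raw[[fct]] <- unlist(raw[[fct]])
  }
  raw$alcohol$units_threshold <- unlist(raw$alcohol$units_threshold)
  raw$composite_grades <- unlist(raw$composite_grades)
  hbsr_config(smoking = raw$smoking, bmi = raw$bmi, exercise = raw$exercise,
              diet = raw$diet, alcohol = raw$alcohol,
              composite_grades = raw$composite_grades,
              high_cutoff = raw$high_cutoff,
              missing_policy = raw$missing_policy)
}

#' @rdname read_scoring_config
#' @param config An `hbsr_config` object.
#' @export
write_scoring_config <- function(config, path) {
  stopifnot(inherits(config, "hbsr_config"))
  out <- unclass(config)
  out$smoking <- as.list(out$smoking)
  out$bmi <- as.list(out$bmi)
  out$exercise <- as.list(out$exercise)
  out$alcohol$units_threshold <- as.list(out$alcohol$units_threshold)
  yaml::write_yaml(out, path)
  invisible(path)
}
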
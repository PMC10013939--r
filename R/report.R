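# Derive the categorical analysis view of a cohort: age band plus the seven
# table variables on their published category scales.
derive_categories <- function(data, config = hbsr_config()) {
  ind <- add_risk_indicators(data, config)
  tibble::tibble(
    group = data$group,
    band = age_band(data$age),
    sex = data$sex,
    smoking = data$smoking,
    bmi = bmi_class(data$bmi),
    exercise = data$exercise,
    vegetables = dplyr::case_when(is.na(data$veg_days) ~ NA_character_,
                                  data$veg_days >= 6 ~ "ge6",
                                  TRUE ~ "lt6"),
    salting = data$salting,
    alcohol_freq = data$alcohol_freq,
    alcohol_excess = dplyr::case_when(is.na(ind$hr_alcohol_units) ~ NA_character_,
                                      ind$hr_alcohol_units ~ "yes",
                                      TRUE ~ "no")
  )
}

# Binary table variables are tested once (on their flagged category); the
# complementary row would repeat the identical z-test.
binary_table_vars <- c("vegetables", "alcohol_excess")

#' Build the stratified prevalence table
#'
#' Renders the case-control comparison table: for every behavioral
#' variable and age band (18-44, 45-54), the per-category count, the
#' complete-case denominator and the percentage in each group, with a
#' pooled two-proportion z-test per category and a Bonferroni adjustment
#' whose family is the set of category tests within the variable block
#' (binary variables are tested once). The asterisk convention of the
#' printed table is available through `print()`: p-values below 0.05 after
#' adjustment are flagged.
#'
#' @param patients,controls Validated cohort tibbles.
#' @param config An [hbsr_config()].
#' @param alpha Significance level applied to the adjusted p-value.
#' @return A tibble of class `hbsr_table1`, one row per band x variable x
#'   category, with columns for both groups' cells, `statistic`, `p`,
#'   `p_adjusted` and `significant`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' t1 <- build_table1(dplyr::filter(cohort, group == "patient"),
#'                    dplyr::filter(cohort, group == "control"))
#' head(t1)
build_table1 <- function(patients, controls, config = hbsr_config(),
                         alpha = 0.05) {
  cats <- dplyr::bind_rows(derive_categories(patients, config),
                           derive_categories(controls, config))
  strata <- expand.grid(group = hbsr_levels$group, band = hbsr_levels$age_band,
                        stringsAsFactors = FALSE)
  present <- dplyr::count(cats, .data$group, .data$band)
  if (nrow(dplyr::inner_join(strata, present, by = c("group", "band"))) < 4) {
    abort("build_table1: empty group x age-band stratum")
  }

  rows <- purrr::map_dfr(hbsr_levels$age_band, function(b) {
    purrr::map_dfr(names(table_variables), function(v) {
      sub <- cats[cats$band == b & !is.na(cats[[v]]), c("group", v)]
      denom <- table(factor(sub$group, hbsr_levels$group))
      purrr::map_dfr(table_variables[[v]], function(cat) {
        cnt <- vapply(hbsr_levels$group, function(g) {
          sum(sub$group == g & sub[[v]] == cat)
        }, integer(1))
        tested <- !(v %in% binary_table_vars) ||
          cat == table_variables[[v]][1]
        zt <- if (tested) {
          two_proportion_z(cnt[["patient"]], denom[["patient"]],
                           cnt[["control"]], denom[["control"]])
        } else {
          tibble::tibble(statistic = NA_real_, p = NA_real_)
        }
        p_cell <- prevalence_cell(cnt[["patient"]], denom[["patient"]])
        c_cell <- prevalence_cell(cnt[["control"]], denom[["control"]])
        tibble::tibble(
          band = b, variable = v, category = cat,
          patients_count = p_cell$count, patients_denom = p_cell$denominator,
          patients_pct = p_cell$pct,
          controls_count = c_cell$count, controls_denom = c_cell$denominator,
          controls_pct = c_cell$pct,
          statistic = zt$statistic, p = zt$p)
      })
    })
  })

  rows <- rows |>
    dplyr::group_by(.data$band, .data$variable) |>
    dplyr::mutate(p_adjusted = bonferroni(.data$p, m = sum(!is.na(.data$p)))) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p_adjusted) &
                    .data$p_adjusted < alpha)
  class(rows) <- c("hbsr_table1", class(rows))
  rows
}

#' @export
print.hbsr_table1 <- function(x, ...) {
  cat("Stratified prevalence table (complete-case denominators; ",
      "p: pooled z-test, * Bonferroni-significant within block)\n\n", sep = "")
  for (b in unique(x$band)) {
    cat(if (b == "b18_44") "Age 18-44" else "Age 45-54", "\n")
    sub <- x[x$band == b, ]
    for (v in unique(sub$variable)) {
      cat("  ", v, "\n", sep = "")
      vv <- sub[sub$variable == v, ]
      for (i in seq_len(nrow(vv))) {
        pstr <- if (is.na(vv$p[i])) "" else
          paste0(format_p(vv$p[i]), if (vv$significant[i]) "*" else "")
        cat(sprintf("    %-16s %5d (%4.1f)  %5d (%4.1f)  %s\n",
                    vv$category[i],
                    vv$patients_count[i], vv$patients_pct[i],
                    vv$controls_count[i], vv$controls_pct[i], pstr))
      }
    }
  }
  invisible(x)
}

# Build the covariate model frame with the documented reference coding:
# age continuous, sex indicator (male = 1), education referenced to
# 'higher', marital referenced to 'married_cohabiting'.
covariate_frame <- function(data, tier) {
  out <- tibble::tibble(
    age = as.numeric(data$age),
    sex_male = as.numeric(data$sex == "male"))
  if (tier == "full") {
    out$edu_basic <- as.numeric(data$education == "basic")
    out$edu_secondary <- as.numeric(data$education == "secondary")
    out$mar_single <- as.numeric(data$marital == "single")
    out$mar_divorced_widowed <- as.numeric(data$marital == "divorced_widowed")
  }
  out
}

or_model_tiers <- c("crude", "age_sex", "full")

#' Crude and adjusted odds ratios for the high-risk behaviors
#'
#' Pools the two cohorts (outcome: patient vs control) and fits, for each
#' of the seven binary high-risk indicators and for membership in the high
#' HBSR band, three logistic models: crude (exposure only), adjusted for
#' age and sex, and fully adjusted for age, sex, education and marital
#' status. Each model uses the complete cases for its own variables and
#' reports the sample size retained.
#'
#' @param patients,controls Validated cohort tibbles.
#' @param config An [hbsr_config()].
#' @param models Subset of `c("crude", "age_sex", "full")`.
#' @param exposures Exposure columns to model; defaults to the seven
#'   indicators plus `"high_hbsr"`.
#' @return A tibble of class `hbsr_or_table`: one row per exposure x
#'   model, with `or`, `ci_low`, `ci_high`, `p`, `n_used`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' ors <- run_or_analysis(dplyr::filter(cohort, group == "patient"),
#'                        dplyr::filter(cohort, group == "control"))
#' subset(ors, exposure == "hr_daily_smoking")
run_or_analysis <- function(patients, controls, config = hbsr_config(),
                            models = or_model_tiers,
                            exposures = c(hbsr_indicator_names, "high_hbsr")) {
  models <- match.arg(models, or_model_tiers, several.ok = TRUE)
  pooled <- dplyr::bind_rows(patients, controls)
  pooled <- add_risk_indicators(pooled, config)
  scores <- hbsr_score(pooled, config)
  pooled$high_hbsr <- scores$band == "high"
  y_all <- as.numeric(pooled$group == "patient")
  out <- purrr::map_dfr(exposures, function(ex) {
    purrr::map_dfr(models, function(tier) {
      xf <- tibble::tibble(exposure = as.numeric(pooled[[ex]]))
      if (tier != "crude") {
        xf <- dplyr::bind_cols(xf, covariate_frame(pooled, tier))
      }
      keep <- stats::complete.cases(xf) & !is.na(y_all)
      X <- cbind(`(Intercept)` = 1, as.matrix(xf[keep, , drop = FALSE]))
      fit <- fit_logistic(y_all[keep], X)
      td <- tidy(fit, exponentiate = TRUE)
      row <- td[td$term == "exposure", ]
      tibble::tibble(exposure = ex, model = tier,
                     or = row$estimate, ci_low = row$conf.low,
                     ci_high = row$conf.high, p = row$p.value,
                     n_used = fit$n_used)
    })
  })
  class(out) <- c("hbsr_or_table", class(out))
  out
}

#' @export
print.hbsr_or_table <- function(x, ...) {
  cat("Odds ratios, patients vs controls (Wald 95% CI)\n")
  cat("  models: crude | age_sex (age + sex) | full (+ education + marital)\n\n")
  for (ex in unique(x$exposure)) {
    cat("  ", ex, "\n", sep = "")
    vv <- x[x$exposure == ex, ]
    for (i in seq_len(nrow(vv))) {
      cat(sprintf("    %-8s OR %5.2f [%.2f-%.2f]  p %s  n=%d\n",
                  vv$model[i], vv$or[i], vv$ci_low[i], vv$ci_high[i],
                  format_p(vv$p[i]), vv$n_used[i]))
    }
  }
  invisible(x)
}

#' Mean-score comparison, high-band prevalence and score distributions
#'
#' Scores both cohorts and reports: each group's mean HBSR score with SD
#' and normal-approximation 95% CI plus the two-sided t-test; the
#' prevalence of the high band (score 6-10 by default) overall and
#' stratified by sex and by age band, each with a pooled z-test (the four
#' stratum tests share one Bonferroni family; the overall test is
#' reported raw); and the full 0-10 score distribution per group.
#'
#' @param patients,controls Validated cohort tibbles.
#' @param config An [hbsr_config()].
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A list of class `hbsr_score_analysis` with elements
#'   `mean_comparison`, `high_band` and `distribution`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' sa <- run_score_analysis(dplyr::filter(cohort, group == "patient"),
#'                          dplyr::filter(cohort, group == "control"))
#' sa$mean_comparison[c("mean1", "mean2", "p")]
run_score_analysis <- function(patients, controls, config = hbsr_config(),
                               var_equal = FALSE) {
  sp <- hbsr_score(patients, config)
  sc <- hbsr_score(controls, config)
  if (all(is.na(sp$total)) || all(is.na(sc$total))) {
    abort("run_score_analysis: a group has no complete scores")
  }
  mean_cmp <- mean_score_ttest(sp$total, sc$total, var_equal = var_equal)

  strata <- list(
    overall = list(p = rep(TRUE, nrow(patients)), c = rep(TRUE, nrow(controls))),
    male = list(p = patients$sex == "male", c = controls$sex == "male"),
    female = list(p = patients$sex == "female", c = controls$sex == "female"),
    age_18_44 = list(p = age_band(patients$age) == "b18_44",
                     c = age_band(controls$age) == "b18_44"),
    age_45_54 = list(p = age_band(patients$age) == "b45_54",
                     c = age_band(controls$age) == "b45_54")
  )
  high_band <- purrr::imap_dfr(strata, function(s, nm) {
    hp <- sp$band[s$p]; hc <- sc$band[s$c]
    xp <- sum(hp == "high", na.rm = TRUE); np <- sum(!is.na(hp))
    xc <- sum(hc == "high", na.rm = TRUE); nc <- sum(!is.na(hc))
    if (np == 0 || nc == 0) {
      # empty stratum (e.g. a single-sex cohort): report NA, do not test
      return(tibble::tibble(
        stratum = nm, patients_count = xp, patients_denom = np,
        patients_pct = NA_real_, controls_count = xc, controls_denom = nc,
        controls_pct = NA_real_, statistic = NA_real_, p = NA_real_))
    }
    zt <- two_proportion_z(xp, np, xc, nc)
    dplyr::bind_cols(
      tibble::tibble(stratum = nm),
      setNames(prevalence_cell(xp, np),
               c("patients_count", "patients_denom", "patients_pct")),
      setNames(prevalence_cell(xc, nc),
               c("controls_count", "controls_denom", "controls_pct")),
      zt[c("statistic", "p")])
  })
  m_strata <- sum(high_band$stratum != "overall")
  high_band$p_adjusted <- ifelse(high_band$stratum == "overall",
                                 high_band$p,
                                 bonferroni(high_band$p, m = m_strata))

  dist <- dplyr::bind_rows(
    patient = tibble::as_tibble(score_distribution(sp, config)),
    control = tibble::as_tibble(score_distribution(sc, config)),
    .id = "group")
  attr(dist, "n_missing") <- c(patient = sum(is.na(sp$total)),
                               control = sum(is.na(sc$total)))

  structure(list(mean_comparison = mean_cmp, high_band = high_band,
                 distribution = dist),
            class = "hbsr_score_analysis")
}

#' @export
print.hbsr_score_analysis <- function(x, ...) {
  m <- x$mean_comparison
  cat(sprintf(
    "Mean HBSR score: patients %.1f [CI %.1f-%.1f, SD %.2f] vs controls %.1f [CI %.1f-%.1f, SD %.2f]; %s p %s\n",
    m$mean1, m$ci1_low, m$ci1_high, m$sd1,
    m$mean2, m$ci2_low, m$ci2_high, m$sd2, m$method, format_p(m$p)))
  cat("\nHigh band (score 6-10) prevalence:\n")
  hb <- x$high_band
  for (i in seq_len(nrow(hb))) {
    cat(sprintf("  %-10s %4.1f%% vs %4.1f%%  p %s (adj %s)\n",
                hb$stratum[i], hb$patients_pct[i], hb$controls_pct[i],
                format_p(hb$p[i]), format_p(hb$p_adjusted[i])))
  }
  invisible(x)
}

#' Run the full case-control analysis
#'
#' One-call orchestration: builds the stratified prevalence table, the
#' crude/adjusted odds-ratio models and the score analysis, and returns
#' them as a study report. Every number in the report is recomputable from
#' the input cohorts; rerunning on the same inputs and configuration is
#' byte-identical.
#'
#' @param patients,controls Validated cohort tibbles.
#' @param config An [hbsr_config()].
#' @return A list of class `hbsr_report` with elements `table1`,
#'   `odds_ratios`, `scores` and `meta`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' rep <- analyze_cohorts(dplyr::filter(cohort, group == "patient"),
#'                        dplyr::filter(cohort, group == "control"))
#' rep$scores$mean_comparison$mean1
analyze_cohorts <- function(patients, controls, config = hbsr_config()) {
  structure(list(
    table1 = build_table1(patients, controls, config),
    odds_ratios = run_or_analysis(patients, controls, config),
    scores = run_score_analysis(patients, controls, config),
    meta = list(n_patients = nrow(patients), n_controls = nrow(controls),
                config_hash = rlang::hash(config))
  ), class = "hbsr_report")
}

#' @export
print.hbsr_report <- function(x, ...) {
  cat(sprintf("HBSR study report: %d patients vs %d controls (config %s)\n\n",
              x$meta$n_patients, x$meta$n_controls, x$meta$config_hash))
  print(x$table1)
  cat("\n")
  print(x$odds_ratios)
  cat("\n")
  print(x$scores)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the machine-readable views (`table1.csv`, `odds_ratios.csv`,
#' `score_summary.csv`, `score_distribution.csv`; full precision) and the
#' human-readable `report.txt` (display rounding only).
#'
#' @param report An `hbsr_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$table1, file.path(dir, "table1.csv"), progress = FALSE)
  readr::write_csv(report$odds_ratios, file.path(dir, "odds_ratios.csv"),
                   progress = FALSE)
  summary_rows <- dplyr::bind_rows(
    dplyr::mutate(report$scores$mean_comparison, section = "mean_comparison"),
    dplyr::mutate(report$scores$high_band, section = "high_band"))
  readr::write_csv(summary_rows, file.path(dir, "score_summary.csv"),
                   progress = FALSE)
  readr::write_csv(report$scores$distribution,
                   file.path(dir, "score_distribution.csv"), progress = FALSE)
  writeLines(utils::capture.output(print(report)), file.path(dir, "report.txt"))
  invisible(dir)
}
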
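#' Plot an HBSR score distribution
#'
#' Bar chart of the 0-10 score counts produced by [score_distribution()].
#'
#' @param object An `hbsr_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbsr_distribution
#' @export
autoplot.hbsr_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$score, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_x_continuous(breaks = 0:10) +
    ggplot2::labs(x = "HBSR score", y = "Respondents") +
    ggplot2::theme_minimal()
}

#' Plot the grouped score distributions of a score analysis
#'
#' Side-by-side bars of the patient and control HBSR score distributions,
#' shown as within-group percentages so unequal cohort sizes compare
#' fairly.
#'
#' @param object An `hbsr_score_analysis` from [run_score_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbsr_score_analysis
#' @export
autoplot.hbsr_score_analysis <- function(object, ...) {
  d <- object$distribution |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$pct,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_x_continuous(breaks = 0:10) +
    ggplot2::labs(x = "HBSR score", y = "% of group", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of the odds-ratio models
#'
#' Odds ratios with Wald 95% intervals per exposure, faceted by model
#' tier, on a log scale with the null line at 1.
#'
#' @param object An `hbsr_or_table` from [run_or_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbsr_or_table
#' @export
autoplot.hbsr_or_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$or, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of prevalence by group
#'
#' Compares patient and control percentages for every category of the
#' stratified prevalence table, faceted by age band.
#'
#' @param object An `hbsr_table1` from [build_table1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbsr_table1
#' @export
autoplot.hbsr_table1 <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("patients_pct", "controls_pct"),
    names_to = "group", values_to = "pct")
  d$group <- sub("_pct$", "", d$group)
  d$label <- paste(d$variable, d$category, sep = ": ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$label,
                                  colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$band)) +
    ggplot2::labs(x = "Prevalence (%)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.hbsr_score_analysis
#' @export
plot_score_distribution <- function(object, ...) autoplot(object, ...)

#' @rdname autoplot.hbsr_or_table
#' @export
plot_or_forest <- function(object, ...) autoplot(object, ...)
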
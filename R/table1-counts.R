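#' Published stratified prevalence counts
#'
#' The category counts of the published case-control health-behavior table
#' (young Estonian stroke patients vs. the 2014 Health Behavior among
#' Estonian Adult Population survey controls), stratified by age band.
#' These counts are the inputs the default simulation spec and the
#' pooled-prevalence recomputations are built from: per variable and
#' stratum, the complete-case denominator is the sum of its category
#' counts, which is smaller than the stratum size whenever answers are
#' missing.
#'
#' @return A tibble with columns `group`, `band`, `variable`, `category`,
#'   `count`, plus the attribute `stratum_n` (respondents per group x
#'   band: patients 135/206, controls 1263/526).
#' @export
#' @examples
#' t1 <- table1_counts()
#' # complete-case smoking denominator, patients 18-44:
#' sum(t1$count[t1$group == "patient" & t1$band == "b18_44" &
#'              t1$variable == "smoking"])
table1_counts <- function() {
  specs <- list(
    # patients 18-44 (n = 135)
    list("patient", "b18_44", "smoking",        c(62, 10, 17, 44)),
    list("patient", "b18_44", "bmi",            c(53, 45, 32)),
    list("patient", "b18_44", "exercise",       c(16, 24, 18, 17, 52)),
    list("patient", "b18_44", "vegetables",     c(51, 78)),
    list("patient", "b18_44", "salting",        c(9, 86, 36)),
    list("patient", "b18_44", "alcohol_freq",   c(26, 20, 34, 38, 13)),
    list("patient", "b18_44", "alcohol_excess", c(23, 103)),
    # patients 45-54 (n = 206)
    list("patient", "b45_54", "smoking",        c(103, 16, 48, 38)),
    list("patient", "b45_54", "bmi",            c(45, 74, 76)),
    list("patient", "b45_54", "exercise",       c(15, 32, 23, 16, 103)),
    list("patient", "b45_54", "vegetables",     c(87, 112)),
    list("patient", "b45_54", "salting",        c(19, 118, 55)),
    list("patient", "b45_54", "alcohol_freq",   c(54, 33, 38, 51, 25)),
    list("patient", "b45_54", "alcohol_excess", c(20, 171)),
    # controls 18-44 (n = 1263)
    list("control", "b18_44", "smoking",        c(254, 112, 344, 539)),
    list("control", "b18_44", "bmi",            c(740, 352, 159)),
    list("control", "b18_44", "exercise",       c(189, 344, 152, 158, 406)),
    list("control", "b18_44", "vegetables",     c(537, 721)),
    list("control", "b18_44", "salting",        c(66, 782, 411)),
    list("control", "b18_44", "alcohol_freq",   c(232, 206, 334, 379, 101)),
    list("control", "b18_44", "alcohol_excess", c(174, 1075)),
    # controls 45-54 (n = 526)
    list("control", "b45_54", "smoking",        c(148, 33, 133, 206)),
    list("control", "b45_54", "bmi",            c(197, 202, 122)),
    list("control", "b45_54", "exercise",       c(66, 99, 68, 48, 238)),
    list("control", "b45_54", "vegetables",     c(226, 294)),
    list("control", "b45_54", "salting",        c(15, 346, 163)),
    list("control", "b45_54", "alcohol_freq",   c(92, 73, 145, 170, 42)),
    list("control", "b45_54", "alcohol_excess", c(64, 454))
  )
  out <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(group = s[[1]], band = s[[2]], variable = s[[3]],
                   category = table_variables[[s[[3]]]],
                   count = as.integer(s[[4]]))
  })
  attr(out, "stratum_n") <- tibble::tibble(
    group = c("patient", "patient", "control", "control"),
    band = c("b18_44", "b45_54", "b18_44", "b45_54"),
    n = c(135L, 206L, 1263L, 526L))
  out
}
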
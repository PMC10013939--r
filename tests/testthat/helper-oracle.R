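# Independent scalar scoring oracle: plain if/else re-statement of the
# default mapping, deliberately separate from the package's vectorized path.
oracle_score_one <- function(r) {
  pts <- function(grade) c(low = 0, moderate = 1, high = 2)[[grade]]
  vals <- c()

  if (is.na(r$smoking)) return(NA_integer_)
  vals <- c(vals, pts(switch(r$smoking, daily = "high", occasional = "moderate",
                             ex_smoker = "moderate", never = "low")))
  if (is.na(r$bmi)) return(NA_integer_)
  vals <- c(vals, pts(if (r$bmi >= 30) "high" else if (r$bmi >= 25) "moderate" else "low"))
  if (is.na(r$exercise)) return(NA_integer_)
  vals <- c(vals, pts(switch(r$exercise,
                             ge4_per_week = "low", w2_3_per_week = "low",
                             once_per_week = "moderate", m2_3_per_month = "moderate",
                             rare_or_none = "high")))
  if (is.na(r$salting) || is.na(r$veg_days)) return(NA_integer_)
  n_adv_diet <- (r$salting == "before_tasting") + (r$veg_days < 6)
  vals <- c(vals, n_adv_diet)
  if (is.na(r$alcohol_freq) || is.na(r$alcohol_units_7d)) return(NA_integer_)
  thr <- if (r$sex == "male") 16 else 8
  n_adv_alc <- (r$alcohol_freq %in% c("ge2_per_week", "once_per_week")) +
    (r$alcohol_units_7d > thr)
  vals <- c(vals, n_adv_alc)
  as.integer(sum(vals))
}

oracle_scores <- function(cohort) {
  vapply(seq_len(nrow(cohort)), function(i) {
    oracle_score_one(as.list(cohort[i, ]))
  }, integer(1))
}
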
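# Shared internal helpers.

# Round half away from zero, the convention used for printed percentages
# (base round() is half-to-even, which would turn 0.25 into 0.2).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Format a p-value the way epidemiology tables print them: three decimals,
# no leading zero, values below 0.0005 shown as ".000".
format_p <- function(p) {
  out <- sub("^0", "", sprintf("%.3f", p))
  out[is.na(p)] <- NA_character_
  out
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# NA-safe set membership: NA %in% set is FALSE in base R, but a missing
# answer must propagate as a missing flag.
in_set_na <- function(x, set) {
  out <- x %in% set
  out[is.na(x)] <- NA
  out
}
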
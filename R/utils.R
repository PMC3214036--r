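# Internal helpers shared across modules.

# Half-up rounding at `digits` decimals. base::round() rounds half to even,
# which would report 84.5 as 84; reported percentages follow the half-up
# convention instead (85% not 84%).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Percentage of a count over a denominator; NA_real_ when the denominator is 0
# so callers can report "share absent" rather than NaN.
pct_of <- function(num, denom, digits = 1) {
  if (length(denom) == 0 || is.na(denom) || denom == 0) {
    return(NA_real_)
  }
  round_half_up(100 * num / denom, digits)
}

# Seed sub-stream derivation: independent stage seeds from one master seed,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647L)
}
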
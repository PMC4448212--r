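# presentation rounding: survey tables round halves away from zero, whereas
# round() rounds half to even (33 x 1.65 = 54.45 must present as 54.5)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
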
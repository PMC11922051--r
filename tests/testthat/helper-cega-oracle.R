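# Independent brute-force coding of the published Clarke error grid
# regions, structured as per-zone membership predicates evaluated point by
# point. Used only as the oracle against which the package's vectorized
# assignment is checked.

# Boundary-line comparisons (the 20 percent band and the 1.2 r slant) are
# written in the same floating-point form as the package so the check
# exercises the region logic, not IEEE-754 rounding of grid points that land
# exactly on a line.
cega_oracle_one <- function(r, p) {
  # zone A: within 20 percent, or both hypoglycemic (< 70)
  if (abs(p - r) <= 0.2 * r || (r < 70 && p < 70)) return("A")
  # zone C (overcorrection): two open regions
  upper_c <- (r - 70) * (290 - r) > 0 && p - r > 110
  lower_c <- (r - 130) * (180 - r) > 0 && p < 1.4 * r - 182
  # zone D (dangerous failure to detect): predictions stuck in 70..180
  band <- p > 70 && p < 180
  left_d <- band && (r < 175 / 3 ||
                       (r < 70 && r > 175 / 3 && p > 1.2 * r))
  right_d <- band && r > 240
  # zone E (erroneous treatment): opposite corners
  e_corner <- (r < 70 && p > 180) || (p < 70 && r > 180)
  members <- c(C = upper_c || lower_c, D = left_d || right_d, E = e_corner)
  if (any(members)) names(members)[which(members)[1]] else "B"
}

cega_oracle <- function(reference, predicted) {
  mapply(cega_oracle_one, reference, predicted, USE.NAMES = FALSE)
}
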
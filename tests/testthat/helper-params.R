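# Random valid parameter sets for property-style tests. Ranges are wider
# than the defaults so the properties are exercised well away from the
# base case; assumes the RNG seed is set by the calling test.
random_parameters <- function() {
  p <- default_parameters()
  wage_labels <- c("wageBedsideMD", "wageRadiologist", "wageRN", "wageTech")
  for (lab in wage_labels) {
    p <- set_parameter(p, lab, runif(1, 0.3, 3))
  }
  for (lab in c("mdTimeA", "mdTimeB", "radiologistRead", "rnTimeB",
                "techTimeA")) {
    p <- set_parameter(p, lab, runif(1, 0.5, 25))
  }
  p <- set_parameter(p, "pMalposition", runif(1, 0, 0.45))
  p <- set_parameter(p, "pPneumothorax", runif(1, 0, 0.45))
  p
}

# Independent bisection root finder (oracle for break_even's analytic root).
bisect_root <- function(f, lo, hi, tol = 1e-9, max_iter = 200) {
  f_lo <- f(lo)
  f_hi <- f(hi)
  stopifnot(f_lo * f_hi <= 0)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(hi - lo) < tol) break
    if (f_lo * f_mid <= 0) {
      hi <- mid; f_hi <- f_mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  (lo + hi) / 2
}
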
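# Shared fixtures for the test suite. Everything is built in code.

d_boin_02 <- design_spec(0.2, "boin")
d_boin_03 <- design_spec(0.3, "boin")
d_aboin_02 <- design_spec(0.2, "aboin")
d_aboin_03 <- design_spec(0.3, "aboin")

# Independent one-line evaluations of the boundary formulas, used as the
# oracle against the package's (differently structured) implementation.
oracle_l1 <- function(phi, phi1, pt = 0) {
  (log((1 - phi1) / (1 - phi)) + pt) / log(phi * (1 - phi1) / (phi1 * (1 - phi)))
}
oracle_l2 <- function(phi, phi2, pt = 0) {
  (log((1 - phi) / (1 - phi2)) + pt) / log(phi2 * (1 - phi) / (phi * (1 - phi2)))
}

# A gently sloped unimodal MTD-confidence vector for property tests: the
# peak sits at `peak` and confidence decays in small steps, leaving room
# for the anchor odds on both sides.
random_unimodal_pi0 <- function(J, peak) {
  v <- numeric(J)
  v[peak] <- runif(1, 0.5, 0.6)
  if (peak > 1) {
    for (j in (peak - 1):1) v[j] <- max(0.1, v[j + 1] - runif(1, 0.04, 0.07))
  }
  if (peak < J) {
    for (j in (peak + 1):J) v[j] <- max(0.1, v[j - 1] - runif(1, 0.04, 0.07))
  }
  v
}
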
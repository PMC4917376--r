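# Shared fixtures and independent brute-force oracles.

chamber_default <- chamber_spec()
chamber_800 <- chamber_spec(plane_sad_mm = 800)

step_profile <- beam_profile(penumbra_mm = 0)
sigmoid_profile <- beam_profile(penumbra_mm = 3)

# Constant (flat) OF table spanning the clinical range: isolates pure
# area scaling.
flat_of <- of_table(c(1, 100), c(1, 1))

# Midpoint-rule oracle for the aligned radial DAP integral.
dap_radial_oracle <- function(model, aperture, of, chamber, n = 1e5) {
  r_max <- chamber$r_max_mm
  h <- r_max / n
  r <- (seq_len(n) - 0.5) * h
  of * sum(ocr(model, aperture, r, chamber) * 2 * pi * r) * h
}

# 2-D midpoint-rule oracle on a polar grid over the offset chamber disk.
dap_offset_oracle <- function(model, aperture, of, chamber, shift,
                              n_r = 1500, n_phi = 1500) {
  r_max <- chamber$r_max_mm
  hr <- r_max / n_r
  hphi <- 2 * pi / n_phi
  rho <- (seq_len(n_r) - 0.5) * hr
  phi <- (seq_len(n_phi) - 0.5) * hphi
  r <- sqrt(outer(rho^2 + shift^2, rep(1, n_phi)) +
              2 * shift * outer(rho, cos(phi)))
  of * sum(ocr(model, aperture, as.vector(r), chamber) *
             rep(rho, times = n_phi)) * hr * hphi
}

# Noiseless configuration: every stochastic term switched off.
quiet_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, output_drift_sd = 0, mu_delivery_sd = 0,
             aperture_jitter_sd = 0, ...)
}
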
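# Monte-Carlo isotope-pairing oracle: samples individual N2 molecules.
# Anammox pairs one nitrite-derived N (15N fraction f_no3, inherited from
# nitrate) with one ammonium-derived N (fraction f_nh4); denitrification
# pairs two nitrite-derived N. Returns mass-29/30 molecule fractions per
# process with their Monte-Carlo standard errors.
mc_pairing_oracle <- function(f_no3, f_nh4, n_mol = 1e6) {
  n1 <- stats::rbinom(n_mol, 1, f_no3) + stats::rbinom(n_mol, 1, f_nh4)
  n2 <- stats::rbinom(n_mol, 1, f_no3) + stats::rbinom(n_mol, 1, f_no3)
  frac <- function(x, m) {
    p <- mean(x == m)
    c(p = p, se = sqrt(p * (1 - p) / n_mol))
  }
  list(anammox_29 = frac(n1, 1), anammox_30 = frac(n1, 2),
       denit_29 = frac(n2, 1), denit_30 = frac(n2, 2))
}

# shorthand for liquid concentration series on a daily grid
liquid_series <- function(analyte, values, times = seq_along(values) - 1) {
  concentration_series(analyte, times, values, phase = "liquid")
}

# reactor geometry of the labelled-batch vessel (scenario D)
batch_reactor <- function() reactor_config(0.48, 0.17)

# planted-parameter recovery for one scenario-D replicate: invert the noisy
# isotopologue series with the known batch dosing rates
recover_denit_share <- function(seed, noise_rel = 0.05) {
  out <- simulate_reactor(sim_config("D", seed = seed, noise_rel = noise_rel))
  v <- out$config$reactor$v_liquid
  est <- estimate_denit_share(out$observed$N2_29, out$observed$N2_30,
                              out$config$label,
                              r_nh4 = out$planted$observable$NH4,
                              r_no3 = out$planted$r_no3_gross * v,
                              config = out$config$reactor)
  est$share
}
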
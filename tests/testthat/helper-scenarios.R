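# End-to-end single-species scenario: simulate at a random mass, process,
# pick windows around the expected charge states, assign, return truth vs
# estimate. Charge centre follows the empirical native-ESI charging scale
# z ~ 0.0778 * sqrt(mass).
run_recovery_scenario <- function(seed, mass_range = c(2e4, 1e6)) {
  set.seed(seed)
  mass <- 10^stats::runif(1, log10(mass_range[1]), log10(mass_range[2]))
  zc <- round(0.0778 * sqrt(mass))
  fwhm <- mass / 2e5 + 1
  sim <- suppressWarnings(simulate_spectrum(
    species_spec("X", mass, zc, max(1, zc / 12), peak_fwhm = fwhm),
    mz_range = range(mz_from_mass(mass, c(max(1, zc - 8), zc + 8))) * c(0.95, 1.05),
    n_points = 20000, noise_sigma = 0.005, seed = seed
  ))
  zs <- (zc - 3):(zc + 3)
  wins <- dplyr::transmute(
    mass_finder(mass, min(zs), max(zs)),
    mz_lo = mz - fwhm - 2, mz_hi = mz + fwhm + 2
  )
  cs <- macsed_assign(pick_peaks(smooth_spectrum(sim$spectrum, 1.5), wins))
  list(mass = mass, estimate = cs$mass, charges = cs$charges, true_charges = zs)
}
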
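#' Describe a species for spectrum simulation
#'
#' One row per molecular species: its neutral mass, a Gaussian charge-state
#' envelope (centre and spread, in charges), an overall abundance scale and
#' the peak full width at half maximum in Thomson. Vectorized, so several
#' species build a multi-species (e.g. overlapping-envelope) table in one
#' call.
#'
#' @param name Species label(s).
#' @param mass Neutral mass(es) in Da (> 0).
#' @param charge_center Mean of the charge envelope (>= 1).
#' @param charge_spread Standard deviation of the envelope in charges (> 0).
#' @param abundance Relative intensity scale (> 0, default 1).
#' @param peak_fwhm Peak full width at half maximum in Th (> 0, default 2).
#' @return A tibble with one row per species.
#' @examples
#' species_spec("mono", 10000, charge_center = 10, charge_spread = 1)
#' @export
species_spec <- function(name, mass, charge_center, charge_spread,
                         abundance = 1, peak_fwhm = 2) {
  tab <- tibble::tibble(
    name = as.character(name),
    mass = as.double(mass),
    charge_center = as.double(charge_center),
    charge_spread = as.double(charge_spread),
    abundance = as.double(abundance),
    peak_fwhm = as.double(peak_fwhm)
  )
  if (any(tab$mass <= 0) || any(tab$charge_center < 1) ||
    any(tab$charge_spread <= 0) || any(tab$abundance <= 0) ||
    any(tab$peak_fwhm <= 0)) {
    stop(paste(
      "species require mass > 0, charge_center >= 1, charge_spread > 0,",
      "abundance > 0, peak_fwhm > 0"
    ), call. = FALSE)
  }
  tab
}

# envelope weights below this are dropped, bounding the peak table
.envelope_cutoff <- 1e-4

#' Simulate a native mass spectrum with known ground truth
#'
#' Builds a synthetic electrospray spectrum on a uniform m/z grid as a
#' first-order model of native MS data: each species contributes one
#' Gaussian peak per charge state z, centred exactly at
#' `mz_from_mass(mass, z)`, with height `abundance * w(z)` where
#' `w(z) = exp(-(z - charge_center)^2 / (2 * charge_spread^2))` is the
#' charge envelope (truncated where `w < 1e-4`). An optional baseline
#' (linear ramp or broad Gaussian hump) and seeded additive Gaussian
#' intensity noise are added, negative intensities are clamped at zero, and
#' the result is normalized to base peak 100.
#'
#' The model deliberately omits isotope structure, adduct heterogeneity and
#' detector effects: it exercises the analysis algorithms, not the physics.
#'
#' @param species A species table from [species_spec()].
#' @param mz_range Length-2 numeric `(lo, hi)` in Th.
#' @param n_points Grid size (>= 100, default 20000).
#' @param baseline `"none"` (default), `list(type = "linear", slope = s)`
#'   (intensity per Th, anchored at zero at the low edge) or
#'   `list(type = "curved", amplitude = a)` (Gaussian hump spanning the
#'   range, centred at its midpoint, sd = range/4).
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise, in pre-normalization intensity units (default 0).
#' @param seed Integer seed making the simulation fully reproducible.
#' @return A list with elements `spectrum` (an `ms_spectrum`, normalized to
#'   100) and `truth` (class `sim_truth`): the species table, the exact
#'   `peak_table` (species, charge, m/z, relative height), baseline
#'   parameters, `noise_sigma` and `seed`.
#' @examples
#' sim <- simulate_spectrum(
#'   species_spec("mono", 10000, 10, 1),
#'   mz_range = c(800, 1400), n_points = 6000, seed = 1
#' )
#' sim$truth$peak_table
#' @export
simulate_spectrum <- function(species, mz_range, n_points = 20000,
                              baseline = "none", noise_sigma = 0, seed = 1) {
  if (!is.data.frame(species) || nrow(species) == 0) {
    stop("`species` must be a non-empty species table", call. = FALSE)
  }
  species <- species_spec(
    species$name, species$mass, species$charge_center,
    species$charge_spread, species$abundance, species$peak_fwhm
  )
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2]) {
    stop("`mz_range` must be (lo, hi) with lo < hi", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 100) {
    stop("`n_points` must be an integer >= 100", call. = FALSE)
  }
  if (noise_sigma < 0) {
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  }

  mz <- seq(mz_range[1], mz_range[2], length.out = n_points)
  y <- numeric(n_points)

  peak_table <- purrr::pmap_dfr(species, function(name, mass, charge_center,
                                                  charge_spread, abundance,
                                                  peak_fwhm) {
    # charges with envelope weight above the cutoff
    half_span <- charge_spread * sqrt(-2 * log(.envelope_cutoff))
    z <- seq.int(
      max(1L, floor(charge_center - half_span)),
      ceiling(charge_center + half_span)
    )
    w <- exp(-(z - charge_center)^2 / (2 * charge_spread^2))
    keep <- w > .envelope_cutoff
    tibble::tibble(
      species = name,
      charge = as.integer(z[keep]),
      mz = mz_from_mass(mass, z[keep]),
      height = abundance * w[keep]
    )
  })

  clipped <- peak_table$mz < mz_range[1] | peak_table$mz > mz_range[2]
  if (any(clipped)) {
    warning(sprintf(
      "%d peak(s) fall outside mz_range and are clipped: %s",
      sum(clipped),
      paste(sprintf(
        "%s z=%d (m/z %.2f)",
        peak_table$species[clipped], peak_table$charge[clipped],
        peak_table$mz[clipped]
      ), collapse = "; ")
    ), call. = FALSE)
  }

  sd_by_species <- stats::setNames(
    species$peak_fwhm / (2 * sqrt(2 * log(2))), species$name
  )
  for (i in seq_len(nrow(peak_table))) {
    s_mz <- sd_by_species[[peak_table$species[i]]]
    y <- y + peak_table$height[i] *
      exp(-(mz - peak_table$mz[i])^2 / (2 * s_mz^2))
  }

  baseline_params <- list(type = "none")
  if (is.list(baseline)) {
    baseline_params <- baseline
    y <- y + switch(baseline$type,
      linear = baseline$slope * (mz - mz_range[1]),
      curved = baseline$amplitude *
        exp(-(mz - mean(mz_range))^2 / (2 * (diff(mz_range) / 4)^2)),
      stop("baseline$type must be 'linear' or 'curved'", call. = FALSE)
    )
  } else if (!identical(baseline, "none")) {
    stop("`baseline` must be \"none\" or a list(type=, ...)", call. = FALSE)
  }

  if (noise_sigma > 0) {
    withr_seed <- seed %% .Machine$integer.max
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(withr_seed)
    y <- y + stats::rnorm(n_points, sd = noise_sigma)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  y <- pmax(y, 0)
  spectrum <- normalize_spectrum(new_ms_spectrum(mz, y))
  # the simulator's normalization is part of spectrum construction, not a
  # user processing step: reset the history so sessions start clean
  attr(spectrum, "processing") <- list()

  truth <- structure(
    list(
      species = species,
      peak_table = peak_table,
      baseline_params = baseline_params,
      noise_sigma = noise_sigma,
      seed = seed
    ),
    class = "sim_truth"
  )
  list(spectrum = spectrum, truth = truth)
}

#' Write simulation ground truth as JSON
#'
#' Stores the species table, exact peak table, baseline parameters, noise
#' level and seed next to the simulated CSV so downstream checks can compare
#' recovered values with the truth.
#'
#' @param truth A `sim_truth` object from [simulate_spectrum()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  if (!inherits(truth, "sim_truth")) {
    stop("`truth` must come from simulate_spectrum()", call. = FALSE)
  }
  jsonlite::write_json(
    list(
      species = truth$species,
      peak_table = truth$peak_table,
      baseline_params = truth$baseline_params,
      noise_sigma = truth$noise_sigma,
      seed = truth$seed
    ),
    path,
    digits = I(17), auto_unbox = TRUE, dataframe = "columns"
  )
  invisible(path)
}
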
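#' Mass of a proton in Da, the default electrospray charge carrier
#' @export
PROTON_MASS <- 1.007276

#' m/z of a charged species
#'
#' For a neutral species of mass M carrying z charge carriers of mass
#' `adduct_mass`, the observed mass-to-charge ratio is
#' `(M + z * adduct_mass) / z`. The default carrier is the proton
#' (positive-ion mode); pass a different `adduct_mass` for other adducts or
#' negative mode.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z Charge state, a positive integer (vectorized).
#' @param adduct_mass Charge-carrier mass in Da (default [PROTON_MASS]).
#' @return m/z in Thomson.
#' @examples
#' mz_from_mass(10000, 9:11)
#' @export
mz_from_mass <- function(mass, z, adduct_mass = PROTON_MASS) {
  if (!is.numeric(mass) || any(mass <= 0)) {
    stop("`mass` must be positive", call. = FALSE)
  }
  if (!is.numeric(z) || any(z < 1) || any(z != round(z))) {
    stop("`z` must be a positive integer", call. = FALSE)
  }
  (mass + z * adduct_mass) / z
}

#' Pick peaks inside m/z windows
#'
#' Selects one peak per window: the sample of maximum intensity inside the
#' closed interval `[mz_lo, mz_hi]` (the programmatic equivalent of selecting
#' a range on the m/z axis with the cursor). Ties are broken toward the
#' lowest m/z. The peak m/z is the apex sample itself (grid-exact), not an
#' intensity-weighted centroid. Windows containing only zero intensity yield
#' no peak and are dropped with a warning.
#'
#' @param s A spectrum.
#' @param windows A data frame with numeric columns `mz_lo` and `mz_hi`, or a
#'   list of length-2 vectors `c(lo, hi)`.
#' @return A tibble of peaks with columns `mz`, `intensity`, `window_lo`,
#'   `window_hi`, one row per non-empty window.
#' @examples
#' s <- ms_spectrum(seq(995, 1010, by = 0.5), dnorm(seq(995, 1010, by = 0.5), 1001, 1))
#' pick_peaks(s, list(c(999, 1003)))
#' @export
pick_peaks <- function(s, windows) {
  s <- as_ms_spectrum(s)
  if (is.list(windows) && !is.data.frame(windows)) {
    windows <- purrr::map_dfr(windows, ~ tibble::tibble(mz_lo = .x[1], mz_hi = .x[2]))
  }
  if (!is.data.frame(windows) || !all(c("mz_lo", "mz_hi") %in% names(windows)) ||
    nrow(windows) == 0) {
    stop("`windows` must be a non-empty data frame with columns mz_lo, mz_hi",
      call. = FALSE
    )
  }
  if (any(windows$mz_lo > windows$mz_hi)) {
    stop("each window must have mz_lo <= mz_hi", call. = FALSE)
  }
  mz_min <- min(s$mz)
  mz_max <- max(s$mz)
  peaks <- purrr::pmap_dfr(
    windows[c("mz_lo", "mz_hi")],
    function(mz_lo, mz_hi) {
      if (mz_hi < mz_min || mz_lo > mz_max) {
        stop(sprintf(
          "window [%g, %g] lies outside the spectrum range [%g, %g]",
          mz_lo, mz_hi, mz_min, mz_max
        ), call. = FALSE)
      }
      inside <- which(s$mz >= mz_lo & s$mz <= mz_hi)
      if (length(inside) == 0 || all(s$intensity[inside] == 0)) {
        warning(sprintf("window [%g, %g] contains no nonzero intensity; skipped",
          mz_lo, mz_hi
        ), call. = FALSE)
        return(tibble::tibble(
          mz = double(), intensity = double(),
          window_lo = double(), window_hi = double()
        ))
      }
      apex <- inside[which.max(s$intensity[inside])] # which.max: lowest index on ties
      tibble::tibble(
        mz = s$mz[apex], intensity = s$intensity[apex],
        window_lo = mz_lo, window_hi = mz_hi
      )
    }
  )
  peaks
}

new_charge_series <- function(name, peaks, charges, mass, uncertainty,
                              adduct_mass = PROTON_MASS) {
  structure(
    list(
      name = name, peaks = peaks, charges = charges,
      mass = mass, uncertainty = uncertainty, adduct_mass = adduct_mass
    ),
    class = "charge_series"
  )
}

#' Assign consecutive charge states to picked peaks (MacSED)
#'
#' Deconvolves a set of peaks assumed to belong to one species with no
#' missing charge states. Peaks are sorted descending by m/z; for every
#' candidate base charge z0 the i-th peak (0-based) receives charge z0 + i,
#' implying a neutral mass `mz * z - z * adduct_mass` per peak. The candidate
#' whose implied masses have minimal variance is selected (ties break toward
#' the smallest z0, i.e. the lower-charge interpretation); the reported mass
#' is their mean and the uncertainty their sample standard deviation
#' (n - 1 denominator).
#'
#' @param peaks A data frame of >= 2 peaks with distinct `mz` (as returned by
#'   [pick_peaks()]; columns `window_lo`/`window_hi`/`intensity` are optional).
#' @param name Label for the series (default `"series"`).
#' @param z_max Largest candidate charge to consider (default 500, enough
#'   for MDa assemblies; the variance objective grows without bound at
#'   implausibly high charges, so the cap mainly bounds runtime).
#' @param adduct_mass Charge-carrier mass in Da (default [PROTON_MASS]).
#' @return A `charge_series` object: peaks (descending m/z), aligned
#'   consecutive ascending charges, deconvolved `mass` (Da) and
#'   `uncertainty` (Da). Inspect with [tidy()] (per-peak table) and
#'   [glance()] (one-row summary).
#' @examples
#' pk <- tibble::tibble(mz = mz_from_mass(10000, 9:11))
#' macsed_assign(pk)
#' @export
macsed_assign <- function(peaks, name = "series", z_max = 500,
                          adduct_mass = PROTON_MASS) {
  if (!is.data.frame(peaks) || !"mz" %in% names(peaks)) {
    stop("`peaks` must be a data frame with an `mz` column", call. = FALSE)
  }
  k <- nrow(peaks)
  if (k < 2) {
    stop("charge assignment needs at least 2 peaks", call. = FALSE)
  }
  if (anyDuplicated(peaks$mz)) {
    stop("peaks must have distinct m/z values", call. = FALSE)
  }
  z_max <- as.integer(z_max)
  if (is.na(z_max) || z_max < k) {
    stop(sprintf(
      "`z_max` (%d) must be at least the number of peaks (%d)", z_max, k
    ), call. = FALSE)
  }
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  if (!"window_lo" %in% names(peaks)) peaks$window_lo <- peaks$mz
  if (!"window_hi" %in% names(peaks)) peaks$window_hi <- peaks$mz
  peaks <- dplyr::arrange(tibble::as_tibble(peaks), dplyr::desc(.data$mz))

  # candidate charge matrix: row = base charge z0, column = peak
  z0 <- seq_len(z_max - k + 1L)
  zmat <- outer(z0, 0:(k - 1L), "+")
  masses <- sweep(zmat, 2, peaks$mz, "*") - zmat * adduct_mass
  mu <- rowMeans(masses)
  ss <- rowSums((masses - mu)^2)
  best <- which.min(ss) # ties: smallest z0 wins
  charges <- zmat[best, ]
  mass_vec <- masses[best, ]
  new_charge_series(
    name = name,
    peaks = peaks[c("mz", "intensity", "window_lo", "window_hi")],
    charges = as.integer(charges),
    mass = mean(mass_vec),
    uncertainty = stats::sd(mass_vec),
    adduct_mass = adduct_mass
  )
}

#' @export
print.charge_series <- function(x, ...) {
  cat(sprintf(
    "# Charge series '%s': %d peaks, charges %d-%d\n#   mass %.4f Da +/- %.4f Da (adduct %.6f Da)\n",
    x$name, nrow(x$peaks), min(x$charges), max(x$charges),
    x$mass, x$uncertainty, x$adduct_mass
  ))
  print(tidy(x))
  invisible(x)
}

#' Per-peak table of a charge series
#'
#' @param x A `charge_series`.
#' @param ... Ignored.
#' @return A tibble with one row per peak: `mz`, `intensity`, the selection
#'   window, the assigned `charge` and the `mass` implied by that peak.
#' @export
tidy.charge_series <- function(x, ...) {
  tibble::tibble(
    mz = x$peaks$mz,
    intensity = x$peaks$intensity,
    window_lo = x$peaks$window_lo,
    window_hi = x$peaks$window_hi,
    charge = x$charges,
    mass = x$peaks$mz * x$charges - x$charges * x$adduct_mass
  )
}

#' One-row summary of a charge series
#'
#' @param x A `charge_series`.
#' @param ... Ignored.
#' @return A one-row tibble: `name`, `n_peaks`, `charge_min`, `charge_max`,
#'   `mass`, `uncertainty`.
#' @export
glance.charge_series <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_peaks = nrow(x$peaks),
    charge_min = min(x$charges),
    charge_max = max(x$charges),
    mass = x$mass,
    uncertainty = x$uncertainty
  )
}

#' Plot a charge series
#'
#' Per-peak deconvolved masses against charge state, with the series mean
#' (dashed) and its uncertainty band.
#'
#' @param object A `charge_series`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.charge_series <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$charge, y = .data$mass)) +
    ggplot2::geom_hline(yintercept = object$mass, linetype = 2) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = object$mass - object$uncertainty,
        ymax = object$mass + object$uncertainty
      ),
      alpha = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Charge state", y = "Implied neutral mass (Da)",
      title = sprintf("%s: %.2f +/- %.2f Da", object$name, object$mass, object$uncertainty)
    )
}

#' Mass finder: expected m/z positions of a known mass
#'
#' Lists the m/z positions where a complex of known mass would appear over a
#' charge range, for highlighting candidate regions in crowded spectra (e.g.
#' direct-from-vesicle measurements with many overlapping series).
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z_lo,z_hi Charge range, positive integers with `z_lo <= z_hi`.
#' @param adduct_mass Charge-carrier mass in Da (default [PROTON_MASS]).
#' @return A tibble with columns `charge` (ascending) and `mz` (descending).
#' @examples
#' mass_finder(100000, 10, 12)
#' @export
mass_finder <- function(mass, z_lo, z_hi, adduct_mass = PROTON_MASS) {
  if (!is.numeric(z_lo) || !is.numeric(z_hi) || length(z_lo) != 1 ||
    length(z_hi) != 1 || z_lo < 1 || z_hi < z_lo ||
    z_lo != round(z_lo) || z_hi != round(z_hi)) {
    stop("`z_lo`/`z_hi` must be positive integers with z_lo <= z_hi", call. = FALSE)
  }
  z <- seq.int(z_lo, z_hi)
  tibble::tibble(charge = as.integer(z), mz = mz_from_mass(mass, z, adduct_mass))
}

#' Predict peaks adjacent to an assigned series
#'
#' Returns the expected m/z of the `n` charge states below the series
#' minimum and the `n` above its maximum (discarding charges below 1), from
#' the series' deconvolved mass. Useful for confirming an assignment or
#' extending a series through a crowded region.
#'
#' @param series A `charge_series`.
#' @param n Number of adjacent charges on each side (default 1).
#' @return A tibble with columns `charge` (ascending) and `mz`, consistent
#'   with [mass_finder()] at the same charges.
#' @export
predict_adjacent <- function(series, n = 1) {
  if (!inherits(series, "charge_series")) {
    stop("`series` must be a charge_series", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  lo <- min(series$charges)
  hi <- max(series$charges)
  z <- c(seq.int(lo - n, lo - 1L), seq.int(hi + 1L, hi + n))
  z <- sort(z[z >= 1])
  tibble::tibble(
    charge = as.integer(z),
    mz = mz_from_mass(series$mass, z, series$adduct_mass)
  )
}
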
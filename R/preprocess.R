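# Unit-area Gaussian kernel on the data-point grid, truncated at 4 sigma.
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve with nearest-value (replicate) edge extension; kernel length odd.
convolve_edge_extend <- function(y, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(y)
  if (r == 0L) {
    return(y * kernel)
  }
  padded <- c(rep(y[1], r), y, rep(y[n], r))
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  as.double(out[(r + 1L):(r + n)])
}

#' Gaussian smoothing
#'
#' Convolves the intensity trace with a unit-area Gaussian kernel of width
#' `sigma` (in data points, not Thomson, since exported CSVs may be
#' non-uniformly gridded), truncated at 4 sigma, with nearest-value edge
#' extension. Smoothing can be applied several times in one call via
#' `repeats`, matching the common practice of repeated light smoothing.
#'
#' The unit-area kernel conserves total intensity for signal further than
#' 4 sigma from the spectrum edges and leaves a constant trace unchanged.
#'
#' @param s A spectrum.
#' @param sigma Kernel standard deviation in data points (> 0).
#' @param repeats Number of smoothing passes (>= 1, default 1).
#' @return The smoothed `ms_spectrum`, with a `smooth` step appended.
#' @export
smooth_spectrum <- function(s, sigma, repeats = 1) {
  s <- as_ms_spectrum(s)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number (data points)", call. = FALSE)
  }
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1) {
    stop("`repeats` must be a positive integer", call. = FALSE)
  }
  kernel <- gaussian_kernel(sigma)
  y <- s$intensity
  for (i in seq_len(repeats)) {
    y <- convolve_edge_extend(y, kernel)
  }
  out <- set_intensity(s, y)
  append_step(out, "smooth", list(sigma = as.double(sigma), repeats = repeats))
}

#' Constant background subtraction
#'
#' Subtracts a fixed intensity from every point, clamping at zero.
#'
#' @param s A spectrum.
#' @param value Intensity to subtract (>= 0, in the spectrum's intensity
#'   units; 0-100 after normalization).
#' @return The corrected `ms_spectrum`, with a `subtract_constant` step
#'   appended.
#' @export
subtract_constant <- function(s, value) {
  s <- as_ms_spectrum(s)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value < 0) {
    stop("`value` must be a single non-negative number", call. = FALSE)
  }
  out <- set_intensity(s, pmax(s$intensity - value, 0))
  append_step(out, "subtract_constant", list(value = as.double(value)))
}

#' Linear background subtraction
#'
#' The baseline is the straight line through the first and last spectrum
#' points, i.e. a linear interpolation between the intensities at the
#' smallest and largest m/z; it is subtracted with clamping at zero, so the
#' first and last intensities become exactly zero.
#'
#' @param s A spectrum of length >= 2.
#' @return The corrected `ms_spectrum`, with a `subtract_linear` step
#'   appended.
#' @export
subtract_linear <- function(s) {
  s <- as_ms_spectrum(s)
  n <- nrow(s)
  if (n < 2) {
    stop("linear background subtraction needs a spectrum of length >= 2", call. = FALSE)
  }
  slope <- (s$intensity[n] - s$intensity[1]) / (s$mz[n] - s$mz[1])
  baseline <- s$intensity[1] + slope * (s$mz - s$mz[1])
  y <- pmax(s$intensity - baseline, 0)
  y[c(1, n)] <- 0 # endpoints are on the baseline by construction
  out <- set_intensity(s, y)
  append_step(out, "subtract_linear")
}

#' Curved background subtraction
#'
#' Estimates a slowly varying baseline as the rolling minimum of the
#' intensity over a centered window of `window` data points, smoothed with a
#' Gaussian kernel of `sigma = window / 2` (same kernel contract as
#' [smooth_spectrum()]), and subtracts it with clamping at zero. Narrow peaks
#' (much narrower than the window) survive almost untouched because the
#' rolling minimum under them stays at the local background level; humps much
#' broader than the window are treated as background and removed.
#'
#' @param s A spectrum.
#' @param window Baseline window in data points (>= 3 and < spectrum length);
#'   the single tuning parameter of this mode.
#' @return The corrected `ms_spectrum`, with a `subtract_curved` step
#'   appended.
#' @export
subtract_curved <- function(s, window) {
  s <- as_ms_spectrum(s)
  window <- as.integer(window)
  if (is.na(window) || window < 3 || window >= nrow(s)) {
    stop("`window` must be an integer in [3, spectrum length)", call. = FALSE)
  }
  roll_min <- zoo::rollapply(
    s$intensity,
    width = window, FUN = min, align = "center", partial = TRUE
  )
  baseline <- convolve_edge_extend(as.double(roll_min), gaussian_kernel(window / 2))
  out <- set_intensity(s, pmax(s$intensity - baseline, 0))
  append_step(out, "subtract_curved", list(window = window))
}

#' Minimum-intensity filter
#'
#' Zeroes every point whose intensity is strictly below `threshold`; points
#' exactly at the threshold are kept. Points are zeroed rather than removed
#' so the m/z grid, array alignment and session replay are preserved.
#'
#' @param s A spectrum.
#' @param threshold Minimum intensity to keep (>= 0).
#' @return The filtered `ms_spectrum`, with a `min_intensity` step appended.
#' @export
filter_min_intensity <- function(s, threshold) {
  s <- as_ms_spectrum(s)
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold) ||
    threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  y <- s$intensity
  y[y < threshold] <- 0
  out <- set_intensity(s, y)
  append_step(out, "min_intensity", list(threshold = as.double(threshold)))
}
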
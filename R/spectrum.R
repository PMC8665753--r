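#' Construct a mass spectrum
#'
#' A spectrum is a tibble with columns `mz` (mass-to-charge ratio in Thomson)
#' and `intensity` (arbitrary units; after [normalize_spectrum()] the base
#' peak equals 100). The constructor sorts by `mz`, collapses duplicate `mz`
#' values by summing their intensities (centroided exports can repeat bins),
#' and validates the container invariants: equal nonzero column lengths,
#' strictly increasing `mz`, finite intensities.
#'
#' Every processing verb ([smooth_spectrum()], [subtract_constant()],
#' [subtract_linear()], [subtract_curved()], [filter_min_intensity()],
#' [normalize_spectrum()]) appends a processing step to the spectrum so that a
#' session can replay the full pipeline on the raw data; see
#' [spectrum_processing()] and [replay_processing()].
#'
#' @param mz Numeric vector of m/z values (Th).
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param processing List of processing-step records carried along with the
#'   data (normally left at its default and populated by the processing verbs).
#' @return A tibble of class `ms_spectrum` with columns `mz` and `intensity`.
#' @examples
#' s <- ms_spectrum(c(1000, 1001, 1002), c(2, 4, 8))
#' s
#' @export
ms_spectrum <- function(mz, intensity, processing = list()) {
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have identical length", call. = FALSE)
  }
  if (length(mz) == 0) {
    stop("a spectrum must contain at least one point", call. = FALSE)
  }
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (anyNA(mz) || anyNA(intensity) || any(!is.finite(intensity)) || any(!is.finite(mz))) {
    stop("`mz` and `intensity` must be finite and non-missing", call. = FALSE)
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- as.double(rowsum(intensity, group = mz, reorder = TRUE))
    mz <- sort(unique(mz))
  }
  new_ms_spectrum(mz, intensity, processing)
}

# internal fast path: inputs already sorted, unique, validated
new_ms_spectrum <- function(mz, intensity, processing = list()) {
  tibble::new_tibble(
    list(mz = mz, intensity = intensity),
    nrow = length(mz),
    class = "ms_spectrum",
    processing = processing
  )
}

#' Coerce a data frame to a spectrum
#'
#' @param x A data frame with numeric columns `mz` and `intensity` (an
#'   existing `ms_spectrum` is returned unchanged).
#' @return An `ms_spectrum` tibble.
#' @export
as_ms_spectrum <- function(x) {
  if (inherits(x, "ms_spectrum")) {
    return(x)
  }
  if (!is.data.frame(x) || !all(c("mz", "intensity") %in% names(x))) {
    stop("`x` must be a data frame with columns `mz` and `intensity`", call. = FALSE)
  }
  ms_spectrum(x$mz, x$intensity, processing = attr(x, "processing") %||% list())
}

#' Processing history of a spectrum
#'
#' Each step is a list with elements `name` (one of `smooth`,
#' `subtract_constant`, `subtract_linear`, `subtract_curved`, `min_intensity`,
#' `normalize`) and `params`, a named list of exactly that operation's
#' parameters.
#'
#' @param s An `ms_spectrum`.
#' @return A list of processing-step records (empty for a raw spectrum).
#' @export
spectrum_processing <- function(s) {
  attr(s, "processing") %||% list()
}

.step_names <- c(
  "smooth", "subtract_constant", "subtract_linear",
  "subtract_curved", "min_intensity", "normalize"
)

.step_params <- list(
  smooth = c("sigma", "repeats"),
  subtract_constant = "value",
  subtract_linear = character(),
  subtract_curved = "window",
  min_intensity = "threshold",
  normalize = character()
)

.param_integer <- c("repeats", "window")

processing_step <- function(name, params = list()) {
  name <- match.arg(name, .step_names)
  wanted <- .step_params[[name]]
  if (!setequal(names(params), wanted)) {
    stop(sprintf(
      "step '%s' requires exactly the parameters: %s",
      name, if (length(wanted)) paste(wanted, collapse = ", ") else "(none)"
    ), call. = FALSE)
  }
  params <- params[wanted]
  # fix param storage types so a JSON round trip is the identity
  for (p in names(params)) {
    params[[p]] <- if (p %in% .param_integer) {
      as.integer(params[[p]])
    } else {
      as.double(params[[p]])
    }
  }
  list(name = name, params = params)
}

append_step <- function(s, name, params = list()) {
  attr(s, "processing") <- c(spectrum_processing(s), list(processing_step(name, params)))
  s
}

# replace intensities, keeping grid and history; used by every processing verb
set_intensity <- function(s, intensity) {
  new_ms_spectrum(s$mz, as.double(intensity), spectrum_processing(s))
}

#' Normalize a spectrum to its base peak
#'
#' Rescales intensities so the most intense point (the base peak) equals 100,
#' the conventional relative-abundance scale of vendor software. A spectrum of
#' all-zero intensities is returned unchanged.
#'
#' @param s A spectrum (data frame with `mz`, `intensity`).
#' @return The normalized `ms_spectrum`, with a `normalize` step appended to
#'   its processing history.
#' @examples
#' normalize_spectrum(ms_spectrum(1:3, c(2, 4, 8)))
#' @export
normalize_spectrum <- function(s) {
  s <- as_ms_spectrum(s)
  top <- max(s$intensity)
  out <- if (top > 0) set_intensity(s, s$intensity / top * 100) else s
  append_step(out, "normalize")
}

#' Replay a processing history on a raw spectrum
#'
#' Applies a list of recorded processing steps in order. Because every step is
#' deterministic, replaying the history stored in a session on its raw
#' spectrum reproduces the working spectrum bit for bit.
#'
#' @param s The raw spectrum.
#' @param steps A list of processing steps as returned by
#'   [spectrum_processing()].
#' @return The processed `ms_spectrum`.
#' @export
replay_processing <- function(s, steps) {
  s <- as_ms_spectrum(s)
  for (st in steps) {
    p <- st$params
    s <- switch(st$name,
      smooth = smooth_spectrum(s, sigma = p$sigma, repeats = p$repeats),
      subtract_constant = subtract_constant(s, value = p$value),
      subtract_linear = subtract_linear(s),
      subtract_curved = subtract_curved(s, window = p$window),
      min_intensity = filter_min_intensity(s, threshold = p$threshold),
      normalize = normalize_spectrum(s),
      stop(sprintf("unknown processing step '%s'", st$name), call. = FALSE)
    )
  }
  s
}

#' @export
print.ms_spectrum <- function(x, ...) {
  n_steps <- length(spectrum_processing(x))
  cat(sprintf(
    "# Mass spectrum: %d points, m/z %.6g-%.6g, %d processing step%s\n",
    nrow(x), min(x$mz), max(x$mz), n_steps, if (n_steps == 1) "" else "s"
  ))
  NextMethod()
}

#' Plot a spectrum
#'
#' Draws the spectrum as a line trace, optionally annotating the peaks of one
#' or more assigned charge series with their charge labels.
#'
#' @param object An `ms_spectrum`.
#' @param series Optional `charge_series` (or list of them) whose peaks are
#'   marked on the trace.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ms_spectrum <- function(object, series = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Th)", y = "Intensity", title = NULL)
  if (!is.null(series)) {
    if (inherits(series, "charge_series")) series <- list(series)
    marks <- purrr::map_dfr(series, function(cs) {
      dplyr::mutate(tidy(cs), series = cs$name)
    })
    p <- p +
      ggplot2::geom_point(
        data = marks,
        ggplot2::aes(x = .data$mz, y = .data$intensity, colour = .data$series)
      ) +
      ggplot2::geom_text(
        data = marks,
        ggplot2::aes(
          x = .data$mz, y = .data$intensity,
          label = paste0(.data$charge, "+"), colour = .data$series
        ),
        vjust = -0.6, size = 3, show.legend = FALSE
      )
  }
  p
}
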
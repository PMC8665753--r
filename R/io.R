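#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Read a two-column m/z-intensity CSV
#'
#' Reads a spectrum exported by vendor software (e.g. MassLynx, Xcalibur) as
#' a comma-separated file of two numeric columns, m/z (Th) and intensity. An
#' optional single header row is tolerated: the first row is skipped iff
#' either of its cells fails numeric parsing. Rows are sorted ascending by
#' m/z and duplicate m/z bins are collapsed by summing their intensities.
#'
#' @param source Path to a CSV file, or a connection.
#' @param normalize If `TRUE` (default), scale intensities so the base peak
#'   equals 100 immediately after loading.
#' @return An `ms_spectrum` tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("m/z,intensity", "1000,2", "1001,4", "1002,8"), f)
#' read_spectrum_csv(f)
#' @export
read_spectrum_csv <- function(source, normalize = TRUE) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("spectrum file is empty", call. = FALSE)
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  bad_shape <- which(lengths(cells) != 2L)
  if (length(bad_shape) > 0) {
    stop(sprintf(
      "line %d: expected exactly 2 comma-separated columns, found %d",
      bad_shape[1], lengths(cells)[bad_shape[1]]
    ), call. = FALSE)
  }
  parse_row <- function(x) suppressWarnings(as.numeric(trimws(x)))
  parsed <- lapply(cells, parse_row)
  first_line <- 1L
  if (anyNA(parsed[[1]])) {
    # header row: skipped iff either cell is non-numeric
    parsed <- parsed[-1]
    first_line <- 2L
  }
  if (length(parsed) < 2) {
    stop("spectrum file must contain at least 2 data rows", call. = FALSE)
  }
  bad <- which(vapply(parsed, anyNA, logical(1)))
  if (length(bad) > 0) {
    stop(sprintf(
      "line %d: non-numeric value in data row", bad[1] + first_line - 1L
    ), call. = FALSE)
  }
  m <- do.call(rbind, parsed)
  s <- ms_spectrum(m[, 1], m[, 2])
  if (normalize) s <- normalize_spectrum(s)
  s
}

#' Write a spectrum to two-column CSV
#'
#' Values are written with enough precision (15 significant digits) that a
#' write/read round trip reproduces the spectrum well beyond the 6
#' significant digits typical of vendor exports.
#'
#' @param s A spectrum.
#' @param path Output file path.
#' @param header Write a `m/z,intensity` header row (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_spectrum_csv <- function(s, path, header = TRUE) {
  s <- as_ms_spectrum(s)
  rows <- sprintf("%.15g,%.15g", s$mz, s$intensity)
  if (header) rows <- c("m/z,intensity", rows)
  writeLines(rows, path)
  invisible(path)
}

#' Bundle a spectrum analysis into a session
#'
#' A session is the self-contained record of an analysis: the raw spectrum as
#' loaded (post-normalization), the ordered processing history that turns it
#' into the working spectrum, the assigned charge series, and free-text
#' annotations. Sessions round-trip through JSON via [save_session()] /
#' [load_session()] so that a spectrum can be shared together with its
#' interpretation and replayed exactly.
#'
#' @param raw_spectrum The raw `ms_spectrum` (as loaded).
#' @param processing Ordered list of processing steps (normally
#'   `spectrum_processing(working_spectrum)`).
#' @param series List of `charge_series` objects; their names must be unique.
#' @param annotations Named list/character of free-text annotations.
#' @return An object of class `ms_session`.
#' @export
ms_session <- function(raw_spectrum, processing = list(), series = list(),
                       annotations = list()) {
  raw_spectrum <- as_ms_spectrum(raw_spectrum)
  if (length(series) > 0) {
    ok <- vapply(series, inherits, logical(1), what = "charge_series")
    if (!all(ok)) {
      stop("`series` must be a list of charge_series objects", call. = FALSE)
    }
    nm <- vapply(series, function(x) x$name, character(1))
    if (anyDuplicated(nm)) {
      stop("series names must be unique", call. = FALSE)
    }
    names(series) <- nm
  }
  annotations <- lapply(annotations, as.character)
  structure(
    list(
      format_version = "1.0",
      raw_spectrum = raw_spectrum,
      processing = processing,
      series = series,
      annotations = annotations
    ),
    class = "ms_session"
  )
}

#' Working spectrum of a session
#'
#' Replays the recorded processing history on the session's raw spectrum.
#'
#' @param session An `ms_session`.
#' @return The working `ms_spectrum`.
#' @export
session_spectrum <- function(session) {
  replay_processing(session$raw_spectrum, session$processing)
}

#' @export
print.ms_session <- function(x, ...) {
  cat(sprintf(
    "# MS analysis session (format %s)\n#   raw spectrum: %d points\n#   processing steps: %d\n#   series: %s\n#   annotations: %d\n",
    x$format_version, nrow(x$raw_spectrum), length(x$processing),
    if (length(x$series)) paste(names(x$series), collapse = ", ") else "(none)",
    length(x$annotations)
  ))
  invisible(x)
}

.session_required_keys <- c("format_version", "raw_spectrum", "processing", "series", "annotations")

session_to_list <- function(session) {
  out <- list(
    format_version = jsonlite::unbox(session$format_version),
    raw_spectrum = list(
      mz = session$raw_spectrum$mz,
      intensity = session$raw_spectrum$intensity
    ),
    processing = lapply(session$processing, function(st) {
      list(
        name = jsonlite::unbox(st$name),
        params = lapply(st$params, jsonlite::unbox)
      )
    }),
    series = lapply(unname(session$series), function(cs) {
      list(
        name = jsonlite::unbox(cs$name),
        peaks = list(
          mz = cs$peaks$mz,
          intensity = cs$peaks$intensity,
          window_lo = cs$peaks$window_lo,
          window_hi = cs$peaks$window_hi
        ),
        charges = cs$charges,
        mass = jsonlite::unbox(cs$mass),
        uncertainty = jsonlite::unbox(cs$uncertainty),
        adduct_mass = jsonlite::unbox(cs$adduct_mass)
      )
    }),
    annotations = lapply(session$annotations, jsonlite::unbox)
  )
  extra <- attr(session, "extra_fields")
  if (!is.null(extra)) out <- c(out, extra)
  out
}

#' Save / load a session as JSON
#'
#' `save_session()` serializes a session to a UTF-8 JSON file with top-level
#' keys `format_version`, `raw_spectrum`, `processing`, `series` and
#' `annotations`; numeric arrays are written at full double precision so that
#' `load_session(save_session(s))` reconstructs `s` exactly. Unknown
#' top-level keys found in a loaded file are preserved and written back on
#' re-save (forward compatibility). `load_session()` validates the presence
#' of all required keys and the major format version.
#'
#' @param session An `ms_session`.
#' @param path File path for the JSON session.
#' @return `save_session()` invisibly returns `path`; `load_session()`
#'   returns the reconstructed `ms_session`.
#' @export
save_session <- function(session, path) {
  if (!inherits(session, "ms_session")) {
    stop("`session` must be an ms_session", call. = FALSE)
  }
  json <- jsonlite::toJSON(
    session_to_list(session),
    digits = I(17), null = "null", na = "null", auto_unbox = FALSE
  )
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  missing <- setdiff(.session_required_keys, names(raw))
  if (length(missing) > 0) {
    stop(sprintf(
      "session file is missing required keys: %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  ver <- as.character(raw$format_version)
  major <- sub("\\..*$", "", ver)
  if (!identical(major, "1")) {
    stop(sprintf("unsupported session format_version '%s' (expected major 1)", ver),
      call. = FALSE
    )
  }
  spec <- new_ms_spectrum(
    as.double(raw$raw_spectrum$mz),
    as.double(raw$raw_spectrum$intensity)
  )
  processing <- lapply(raw$processing, function(st) {
    processing_step(st$name, as.list(st$params))
  })
  series <- lapply(raw$series, function(cs) {
    new_charge_series(
      name = cs$name,
      peaks = tibble::tibble(
        mz = as.double(cs$peaks$mz),
        intensity = as.double(cs$peaks$intensity),
        window_lo = as.double(cs$peaks$window_lo),
        window_hi = as.double(cs$peaks$window_hi)
      ),
      charges = as.integer(cs$charges),
      mass = as.double(cs$mass),
      uncertainty = as.double(cs$uncertainty),
      adduct_mass = as.double(cs$adduct_mass)
    )
  })
  out <- ms_session(
    raw_spectrum = spec,
    processing = processing,
    series = series,
    annotations = as.list(raw$annotations)
  )
  out$format_version <- ver
  extra <- raw[setdiff(names(raw), .session_required_keys)]
  if (length(extra) > 0) attr(out, "extra_fields") <- extra
  out
}

#' Export a tab-separated summary of assigned series
#'
#' Writes one row per charge series with its name, number of peaks, charge
#' range, deconvolved mass and uncertainty (both in Da), in insertion order.
#'
#' @param session An `ms_session`.
#' @param path Output TSV path.
#' @return Invisibly, a tibble of the exported table.
#' @export
export_series_table <- function(session, path) {
  if (!inherits(session, "ms_session")) {
    stop("`session` must be an ms_session", call. = FALSE)
  }
  tab <- purrr::map_dfr(session$series, glance)
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(
      name = character(), n_peaks = integer(),
      charge_min = integer(), charge_max = integer(),
      mass_Da = double(), uncertainty_Da = double()
    )
  } else {
    tab <- dplyr::rename(tab, mass_Da = "mass", uncertainty_Da = "uncertainty")
  }
  readr::write_tsv(tab, path)
  invisible(tab)
}
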
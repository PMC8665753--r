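#' Build a subunit table
#'
#' @param name Character vector of unique subunit names.
#' @param mass Numeric vector of average subunit masses in Da (> 0); average
#'   rather than monoisotopic masses, as is standard for native MS of large
#'   complexes.
#' @param max_copies Integer vector of per-subunit copy-number bounds
#'   (>= 1); explicit bounds keep the enumeration exact and finite.
#' @return A tibble with columns `name`, `mass`, `max_copies`.
#' @examples
#' subunit_table(c("alpha", "beta"), c(20000, 5000), c(10, 10))
#' @export
subunit_table <- function(name, mass, max_copies) {
  tab <- tibble::tibble(
    name = as.character(name),
    mass = as.double(mass),
    max_copies = as.integer(max_copies)
  )
  validate_subunit_table(tab)
}

validate_subunit_table <- function(tab) {
  if (!is.data.frame(tab) || !all(c("name", "mass", "max_copies") %in% names(tab))) {
    stop("a subunit table needs columns name, mass, max_copies", call. = FALSE)
  }
  if (nrow(tab) == 0) {
    stop("the subunit table is empty", call. = FALSE)
  }
  if (anyDuplicated(tab$name)) {
    stop("subunit names must be unique", call. = FALSE)
  }
  if (any(tab$mass <= 0) || any(tab$max_copies < 1)) {
    stop("subunit masses must be > 0 and max_copies >= 1", call. = FALSE)
  }
  tibble::as_tibble(tab[c("name", "mass", "max_copies")])
}

#' Enumerate subunit stoichiometries matching a complex mass
#'
#' Finds every integer copy-number combination of the given subunits (each
#' bounded by its `max_copies`, with at least one copy in total) whose summed
#' mass lies within `tolerance` of `target`. The search is an exact
#' depth-first enumeration with branch-and-bound pruning: a partial sum
#' already above `target + tolerance` cannot recover (masses are positive)
#' and is cut, as is a branch whose maximal remaining mass cannot reach
#' `target - tolerance`. Pruning never changes the solution set relative to
#' full enumeration.
#'
#' @param subunits A subunit table (see [subunit_table()]): columns `name`,
#'   `mass`, `max_copies`.
#' @param target Measured complex mass in Da (> 0).
#' @param tolerance Maximum absolute deviation in Da (>= 0). Set
#'   `ppm = TRUE` to interpret `tolerance` as parts-per-million of `target`
#'   instead.
#' @param ppm If `TRUE`, `tolerance` is in ppm of `target` (default `FALSE`,
#'   i.e. Da).
#' @return A tibble with one row per solution: one count column per subunit
#'   (named after it), `total_mass` (Da) and `deviation`
#'   (`total_mass - target`, Da, signed). Rows are sorted by `|deviation|`
#'   ascending, ties broken lexicographically on the count vector, so output
#'   order is deterministic.
#' @examples
#' tab <- subunit_table(c("alpha", "beta"), c(20000, 5000), c(10, 10))
#' enumerate_stoichiometries(tab, target = 45000, tolerance = 5)
#' @export
enumerate_stoichiometries <- function(subunits, target, tolerance, ppm = FALSE) {
  subunits <- validate_subunit_table(subunits)
  if (!is.numeric(target) || length(target) != 1 || target <= 0) {
    stop("`target` must be a single positive mass in Da", call. = FALSE)
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0) {
    stop("`tolerance` must be a single non-negative number", call. = FALSE)
  }
  if (isTRUE(ppm)) tolerance <- tolerance * 1e-6 * target
  if (prod(subunits$max_copies + 1) > 1e8) {
    stop(paste(
      "search space exceeds 1e8 combinations;",
      "tighten `max_copies` to keep the enumeration tractable"
    ), call. = FALSE)
  }

  m <- subunits$mass
  cap <- subunits$max_copies
  p <- length(m)
  lo <- target - tolerance
  hi <- target + tolerance
  # max mass still addable from subunit i onward, for lower-bound pruning
  tail_max <- rev(cumsum(rev(m * cap)))

  counts_acc <- list()
  counts <- integer(p)
  recurse <- function(i, partial) {
    if (partial > hi) {
      return(invisible(NULL)) # masses positive: no branch can recover
    }
    if (i > p) {
      if (partial >= lo && any(counts > 0)) {
        counts_acc[[length(counts_acc) + 1L]] <<- counts
      }
      return(invisible(NULL))
    }
    if (partial + tail_max[i] < lo) {
      return(invisible(NULL)) # even maxing out the rest cannot reach target
    }
    for (c_i in 0:cap[i]) {
      counts[i] <<- c_i
      recurse(i + 1L, partial + c_i * m[i])
      if (partial + c_i * m[i] > hi) break
    }
    counts[i] <<- 0L
  }
  recurse(1L, 0)

  if (length(counts_acc) == 0) {
    empty <- tibble::as_tibble(stats::setNames(
      rep(list(integer()), p), subunits$name
    ))
    return(dplyr::mutate(empty, total_mass = double(), deviation = double()))
  }
  cmat <- do.call(rbind, counts_acc)
  total <- as.double(cmat %*% m)
  out <- tibble::as_tibble(stats::setNames(
    lapply(seq_len(p), function(j) cmat[, j]), subunits$name
  ))
  out$total_mass <- total
  out$deviation <- total - target
  ord <- do.call(order, c(
    list(abs(out$deviation)),
    lapply(seq_len(p), function(j) cmat[, j])
  ))
  out[ord, ]
}

#' Match an assigned charge series against known subunits
#'
#' Convenience wrapper wiring a deconvolved series into the stoichiometry
#' search: the target is the series' mass and the effective tolerance is
#' `max(tolerance, 3 * series$uncertainty)`, so an uncertain mass
#' automatically widens the window to +/- 3 standard deviations.
#'
#' @param series A `charge_series`.
#' @param subunits A subunit table.
#' @param tolerance Minimum tolerance in Da (>= 0).
#' @return As [enumerate_stoichiometries()].
#' @export
score_series_against_subunits <- function(series, subunits, tolerance) {
  if (!inherits(series, "charge_series")) {
    stop("`series` must be a charge_series", call. = FALSE)
  }
  eff <- max(tolerance, 3 * series$uncertainty)
  enumerate_stoichiometries(subunits, target = series$mass, tolerance = eff)
}
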
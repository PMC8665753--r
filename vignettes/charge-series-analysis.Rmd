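---
title: "Deconvolving native mass spectra by charge-series variance minimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving native mass spectra by charge-series variance minimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativems)
library(dplyr)
```

## The problem

In native mass spectrometry (nMS), intact protein complexes are electrosprayed
gently enough to survive into the gas phase, where each species appears not as
one peak but as a *charge-state series*: a set of peaks at

$$ m/z = \frac{M + z\,m_\mathrm{H^+}}{z}, \qquad z = z_0, z_0+1, \dots $$

where $M$ is the neutral mass and $m_\mathrm{H^+} = 1.007276$ Da is the proton
mass. Neither $M$ nor the charges are observed directly; the spacing of the
series encodes both. Spectra of complex mixtures — for example membrane
vesicles sprayed directly into the instrument — contain many interleaved
series, which defeats fully automated deconvolution and makes purely manual
assignment slow. This package supports the middle ground: the analyst chooses
which peaks belong together (by m/z windows), and the machinery does the
arithmetic, bookkeeping and consistency checking.

## Charge assignment by variance minimisation

Given $k$ picked peaks sorted descending by m/z, assume the series has *no
missing charge states*: the peak with the highest m/z carries the lowest
charge. For every candidate base charge $z_0$, assign charges
$z_0, z_0+1, \dots, z_0+k-1$ and deconvolve each peak to a mass

$$ M_i = (m/z)_i \,(z_0+i) - (z_0+i)\, m_\mathrm{H^+}. $$

If the candidate is right, all $k$ masses agree; if it is wrong, they fan out.
The algorithm therefore selects the $z_0$ whose mass vector has minimal
variance, reports the mean as the mass and the sample standard deviation
($k-1$ denominator) as the uncertainty:

```{r}
peaks <- tibble::tibble(mz = mz_from_mass(10000, 9:11))
cs <- macsed_assign(peaks, name = "demo")
glance(cs)
```

Design choices the data do not dictate, fixed as follows:

* **Charge carrier.** The proton, positive-ion mode. The adduct mass is a
  parameter (`adduct_mass`) for negative mode or non-protonated adducts; the
  electron mass is not subtracted.
* **Tie-breaking.** If two candidates tie exactly, the smaller $z_0$ wins —
  deterministic, and it favours the lower-charge (wider-spacing)
  interpretation.
* **Variance scale.** The variance is computed on the mass vector in Da²,
  unweighted by intensity; sample (not population) statistics throughout.
* **Search bound.** `z_max = 500` comfortably covers MDa assemblies. The
  variance objective grows rapidly at implausibly high charges, so the cap
  bounds runtime rather than changing answers; the tests confirm the selected
  $z_0$ equals an exhaustive scan's argmin on every tested input.
* **Peak centroid.** The apex *sample* within the selection window, not an
  intensity-weighted centroid. This is grid-exact and easy to reason about;
  with a reasonably fine m/z grid the quantisation error (half a grid step,
  multiplied by the charge when propagated to mass) is negligible against
  peak widths in native spectra. A weighted centroid would interpolate below
  the grid but couples the answer to baseline quality.

With two peaks the variance surface has many near-degenerate minima, and with
noiseless input from *any* consecutive pair the minimum at the true charges is
exactly zero — but so, nearly, are aliases at multiples. The tests treat the
two-peak case explicitly: the implementation must return the global argmin of
the exhaustive scan, whatever it is. In practice analysts should pick three or
more peaks.

## Spectrum processing

Processing operates on a two-column spectrum (m/z in Thomson, intensity
normalised so the base peak is 100 — the conventional relative-abundance
scale; normalisation is applied once, on load). Four operations are provided,
each recording itself in the spectrum's processing history:

* **Gaussian smoothing** (`smooth_spectrum`): convolution with a unit-area
  Gaussian kernel of standard deviation `sigma` *data points*, truncated at
  4σ, nearest-value edge extension, optionally repeated. Units are data
  points rather than Thomson because exported CSVs need not be uniformly
  gridded. The unit-area kernel conserves total intensity away from edges.
  Truncation at 4σ discards ~6×10⁻⁵ of kernel mass; consequently repeated
  smoothing matches a single wider pass (the Gaussian semigroup property)
  only to about 10⁻⁵ of peak height, which the test suite checks at 10⁻⁴.
* **Constant subtraction**: `max(I - c, 0)`.
* **Linear subtraction**: subtracts the straight line through the first and
  last points (the intensities at the smallest and largest m/z), clamped at
  zero; both endpoints become exactly zero.
* **Curved subtraction** (`subtract_curved`): the baseline is the rolling
  minimum of intensity over a centred window of `window` data points,
  smoothed with a Gaussian of σ = `window`/2, then subtracted with clamping.
  This rolling-minimum construction is our concrete realisation of the
  "curved background" idea found in deconvolution software; the window is
  its single tuning parameter. Peaks much narrower than the window survive
  (the rolling minimum under them stays at background level); humps much
  broader than the window are treated as background.
* **Minimum-intensity filter**: intensities strictly below the threshold are
  set to zero — points are zeroed, never deleted, so the m/z grid and array
  alignment survive and a session replays exactly. Points exactly at the
  threshold are kept.

All operations preserve the m/z grid and clamp at zero, so downstream code
can rely on non-negative intensities of unchanged length.

## Sessions

A session bundles the raw spectrum (as loaded, post-normalisation), the
ordered processing history, the assigned series and free-text annotations
into one JSON file (`format_version` 1.0; the schema is this package's own).
Because every processing operation is deterministic, replaying the history on
the raw spectrum reproduces the working spectrum *bit for bit* — floats are
serialised with 17 significant digits, which round-trips IEEE doubles
exactly. Unknown top-level keys in a loaded file are kept and written back,
so files from future minor versions survive a round trip here.

```{r}
sim <- simulate_spectrum(
  species_spec("demo", 10000, charge_center = 10, charge_spread = 1),
  mz_range = c(700, 1800), n_points = 20000, noise_sigma = 0.01, seed = 42
)
work <- sim$spectrum |>
  smooth_spectrum(sigma = 2) |>
  filter_min_intensity(0.05)
wins <- mass_finder(10000, 9, 11) |>
  transmute(mz_lo = mz - 4, mz_hi = mz + 4)
series <- macsed_assign(pick_peaks(work, wins), name = "demo")
ses <- ms_session(sim$spectrum,
  processing = spectrum_processing(work),
  series = list(series)
)
path <- tempfile(fileext = ".json")
save_session(ses, path)
identical(session_spectrum(load_session(path))$intensity, work$intensity)
```

## Stoichiometry matching

Native MS is often used to ask: *which combination of known subunits adds up
to this measured complex mass?* `enumerate_stoichiometries()` answers it
exactly: a depth-first enumeration over integer copy numbers, bounded per
subunit by an explicit `max_copies`, returning every combination within a
mass tolerance, ranked by absolute deviation (ties broken lexicographically
so output order is reproducible). Branch-and-bound pruning (partial sums
above `target + tolerance` cut, branches that cannot reach
`target - tolerance` cut) makes desk-scale problems instant without ever
changing the solution set — the tests verify pruned results against full
enumeration on random instances. Requiring explicit per-subunit bounds is
deliberate: an unbounded knapsack over real-valued masses can explode, and a
guard rejects search spaces beyond 10⁸ combinations. At least one copy in
total is required; zero-copy subunits are allowed within a solution.
Tolerance is absolute (Da) by default, with a `ppm` convenience flag; masses
are average masses, as appropriate for native MS of large complexes.

```{r}
subs <- subunit_table(c("alpha", "beta"), c(20000, 5000), c(10, 10))
enumerate_stoichiometries(subs, target = 45000, tolerance = 5)
```

`score_series_against_subunits()` wires an assigned series straight in, with
effective tolerance `max(tolerance, 3 * uncertainty)` so an uncertain mass
automatically widens the window.

## The simulator, and what passing its tests does (not) show

`simulate_spectrum()` is a first-order generative model of a native ESI
spectrum: a Gaussian charge-state envelope (centre and spread in charges;
weights below 10⁻⁴ dropped), one Gaussian peak per charge state centred
exactly on the electrospray relation, optional linear or broad-Gaussian
baseline, additive Gaussian intensity noise under an explicit seed, on a
uniform m/z grid, normalised to base peak 100. Every peak position in the
emitted truth table is exact, which is what makes end-to-end recovery
testable: across seeded scenarios from 20 kDa to 1 MDa the full
simulate → smooth → pick → assign pipeline recovers masses to better than
0.1%, and a tetradecamer-scale fixture (14 × 57 197 Da over charges 60–75,
on a curved baseline) to within 0.02%.

The simulator deliberately omits isotope structure, adduct heterogeneity,
peak asymmetry, detector saturation and correlated (chemical) noise, and its
grid is uniform although the readers accept non-uniform grids. Passing these
tests therefore demonstrates that the *algorithms* are implemented correctly
and are robust to position jitter and smooth baselines — not that real
instrument data will always be as well-behaved. In particular, apex picking
inherits any peak asymmetry of real data directly into the mass estimate.

Problem sizes in the shipped test-suite and acceptance script — 200 random
series for exactness, 100 for oracle agreement, 100 random stoichiometry
instances, 20 end-to-end scenarios at 20 000 grid points, 200 noise
replicates — were chosen to estimate the reported rates with reasonable
confidence while keeping a full run on a laptop in well under a minute.

## Numerical notes and limitations

* Duplicate m/z rows on input are collapsed by summing (centroided exports
  can repeat bins); rows are sorted ascending.
* A CSV header row is detected as "first row, either cell non-numeric"; any
  later non-numeric row is an error naming the line.
* Deconvolved masses are means of $(m/z)\cdot z - z\,m_\mathrm{H^+}$; with
  noiseless input the relative error is at machine precision, and the
  uncertainty is reported as 0 only up to floating-point cancellation
  (< 10⁻⁶ Da in tests).
* The noise-robustness tests show exact charge recovery in ≥ 95% of
  replicates at 0.1 Th jitter for an 11-peak, 100 kDa series, with median
  mass error growing monotonically with jitter — but robustness degrades for
  short series and low charges, where variance minima are shallower.
* Whether upstream implementations zero or delete sub-threshold points, and
  how exactly their curved background is constructed, varies; both behaviours
  here are documented interpretations chosen for replayability.
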
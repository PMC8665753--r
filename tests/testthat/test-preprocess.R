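flat <- function(n, value = 0) ms_spectrum(seq_len(n), rep(value, n))

test_that("a unit impulse reproduces the truncated, unit-area Gaussian kernel", {
  n <- 101
  y <- rep(0, n)
  y[51] <- 1
  s <- smooth_spectrum(ms_spectrum(seq_len(n), y), sigma = 2)
  r <- ceiling(4 * 2)
  expected <- exp(-(seq(-r, r)^2) / (2 * 4))
  expected <- expected / sum(expected)
  expect_equal(s$intensity[(51 - r):(51 + r)], expected, tolerance = 1e-14)
  expect_equal(sum(s$intensity), 1, tolerance = 1e-12)
  expect_true(all(s$intensity[c(1:(51 - r - 1), (51 + r + 1):n)] == 0))
})

test_that("smoothing leaves a constant spectrum unchanged and conserves intensity", {
  s <- smooth_spectrum(flat(80, 5), sigma = 3, repeats = 2)
  expect_lt(max(abs(s$intensity - 5)), 1e-12)

  # unit-area kernel conserves total intensity for interior signal
  n <- 400
  y <- rep(0, n)
  y[150:250] <- exp(-(seq(150, 250) - 200)^2 / 200)
  sm <- smooth_spectrum(ms_spectrum(seq_len(n), y), sigma = 4)
  expect_lt(abs(sum(sm$intensity) - sum(y)) / sum(y), 1e-9)
})

test_that("repeated smoothing approximates a single wider pass (semigroup)", {
  # two sigma passes ~ one sigma*sqrt(2) pass; agreement is limited by the
  # 4-sigma kernel truncation, which caps it near 1e-5 of peak height
  x <- seq_len(1001)
  y <- exp(-(x - 500)^2 / (2 * 25))
  s <- ms_spectrum(x, y)
  twice <- smooth_spectrum(s, sigma = 2, repeats = 2)$intensity
  once <- smooth_spectrum(s, sigma = 2 * sqrt(2), repeats = 1)$intensity
  expect_lt(max(abs(twice - once)) / max(y), 1e-4)
})

test_that("smoothing rejects invalid parameters", {
  s <- flat(10, 1)
  expect_error(smooth_spectrum(s, sigma = 0), "sigma")
  expect_error(smooth_spectrum(s, sigma = -1), "sigma")
  expect_error(smooth_spectrum(s, sigma = 2, repeats = 0), "repeats")
})

test_that("constant subtraction shifts and clamps at zero", {
  s <- ms_spectrum(1:3, c(10, 50, 100))
  expect_equal(subtract_constant(s, 10)$intensity, c(0, 40, 90))
  expect_equal(subtract_constant(s, 0)$intensity, c(10, 50, 100))
  expect_equal(subtract_constant(s, 200)$intensity, c(0, 0, 0))
  expect_error(subtract_constant(s, -1), "non-negative")
})

test_that("linear subtraction removes the endpoint-anchored line exactly", {
  s <- ms_spectrum(c(1000, 1500, 2000), c(10, 100, 20))
  out <- subtract_linear(s)
  expect_equal(out$intensity, c(0, 85, 0))

  expect_equal(subtract_linear(flat(3, 5))$intensity, c(0, 0, 0))
  expect_error(subtract_linear(ms_spectrum(1, 1)), "length >= 2")

  # adding a known ramp to a signal that is zero at both ends, then
  # subtracting, recovers the original
  sim <- suppressWarnings(simulate_spectrum(
    species_spec("A", 10000, 10, 1),
    mz_range = c(820, 1300), n_points = 5000, seed = 2
  ))
  clean <- sim$spectrum
  ramp <- 0.01 * (clean$mz - clean$mz[1]) + 3
  ramped <- ms_spectrum(clean$mz, clean$intensity + ramp)
  recovered <- subtract_linear(ramped)
  expect_lt(max(abs(recovered$intensity - clean$intensity)), 1e-9)
})

test_that("curved subtraction flattens backgrounds but preserves narrow peaks", {
  expect_equal(subtract_curved(flat(200, 5), window = 25)$intensity, rep(0, 200))

  # narrow peak on zero baseline: apex preserved within 1%
  n <- 1001
  x <- seq_len(n)
  peak <- 80 * exp(-(x - 500)^2 / (2 * 3^2))
  out <- subtract_curved(ms_spectrum(x, peak), window = 101)
  expect_gt(max(out$intensity), 0.99 * 80)

  # broad hump (much wider than the window) is background: mostly removed
  hump <- 40 * exp(-(x - 500)^2 / (2 * 300^2))
  out <- subtract_curved(ms_spectrum(x, hump), window = 51)
  expect_lt(max(out$intensity), 0.2 * 40)

  expect_error(subtract_curved(flat(10, 1), window = 2), "window")
  expect_error(subtract_curved(flat(10, 1), window = 10), "window")
})

test_that("minimum-intensity filter zeroes below threshold, keeps grid and boundary", {
  s <- ms_spectrum(1:3, c(10, 50, 100))
  expect_equal(filter_min_intensity(s, 50)$intensity, c(0, 50, 100))
  expect_equal(filter_min_intensity(s, 0)$intensity, c(10, 50, 100))
  expect_equal(filter_min_intensity(s, 101)$intensity, c(0, 0, 0))
  expect_error(filter_min_intensity(s, -5), "non-negative")
})

test_that("all processing operations preserve the m/z grid and never go negative", {
  set.seed(31)
  mz <- sort(runif(300, 1000, 3000))
  s <- ms_spectrum(mz, runif(300, 0, 100))
  ops <- list(
    function(x) smooth_spectrum(x, sigma = 2.5, repeats = 2),
    function(x) subtract_constant(x, 20),
    subtract_linear,
    function(x) subtract_curved(x, window = 31),
    function(x) filter_min_intensity(x, 10),
    normalize_spectrum
  )
  for (op in ops) {
    out <- op(s)
    expect_identical(out$mz, s$mz)
    expect_identical(nrow(out), nrow(s))
    expect_true(all(out$intensity >= 0))
  }
})

test_that("a recorded pipeline replays to a bitwise-identical working spectrum", {
  set.seed(13)
  raw <- ms_spectrum(sort(runif(500, 800, 4000)), runif(500, 0, 60))
  work <- raw |>
    normalize_spectrum() |>
    smooth_spectrum(sigma = 1.7, repeats = 3) |>
    subtract_curved(window = 41) |>
    subtract_constant(0.2) |>
    filter_min_intensity(0.5)
  steps <- spectrum_processing(work)
  expect_length(steps, 5)
  expect_identical(
    vapply(steps, `[[`, character(1), "name"),
    c("normalize", "smooth", "subtract_curved", "subtract_constant", "min_intensity")
  )
  replayed <- replay_processing(raw, steps)
  expect_identical(replayed$intensity, work$intensity)
  expect_identical(replayed$mz, work$mz)
})
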
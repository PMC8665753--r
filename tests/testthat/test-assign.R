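test_that("mz_from_mass implements the electrospray relation", {
  expect_equal(mz_from_mass(10000, 10), 1001.007276)
  expect_equal(mz_from_mass(10000, 1), 10001.007276)
  expect_equal(mz_from_mass(10000, 10, adduct_mass = 0), 1000)
  expect_error(mz_from_mass(0, 5), "positive")
  expect_error(mz_from_mass(-10, 5), "positive")
  expect_error(mz_from_mass(10000, 0), "positive integer")
})

test_that("pick_peaks returns the apex sample per window, lowest m/z on ties", {
  sim <- suppressWarnings(simulate_spectrum(
    species_spec("A", 10000, 10, 1, peak_fwhm = 1.5),
    mz_range = c(820, 1300), n_points = 10000, seed = 1
  ))
  pk <- pick_peaks(sim$spectrum, list(c(990, 1010)))
  expect_equal(nrow(pk), 1)
  grid_step <- diff(sim$spectrum$mz[1:2])
  expect_lt(abs(pk$mz - 1001.007276), grid_step)
  expect_equal(pk$window_lo, 990)
  expect_equal(pk$window_hi, 1010)

  expect_error(pick_peaks(sim$spectrum, list(c(2000, 2100))), "outside the spectrum range")

  # three windows around the three dominant simulated charge states hit the
  # truth apexes on the grid
  truth <- sim$truth$peak_table
  dominant <- dplyr::slice_max(truth, height, n = 3)
  wins <- tibble::tibble(mz_lo = dominant$mz - 5, mz_hi = dominant$mz + 5)
  pk3 <- pick_peaks(sim$spectrum, wins)
  expect_equal(nrow(pk3), 3)
  expect_true(all(abs(pk3$mz - dominant$mz) <= grid_step))

  # tie on a flat plateau resolves to the lowest m/z
  s <- ms_spectrum(1:5, c(0, 3, 3, 3, 0))
  expect_equal(pick_peaks(s, list(c(1, 5)))$mz, 2)

  # all-zero windows are skipped with a warning
  s <- ms_spectrum(1:10, c(rep(0, 5), 1, rep(0, 4)))
  expect_warning(pk0 <- pick_peaks(s, list(c(1, 4), c(5, 7))), "no nonzero")
  expect_equal(nrow(pk0), 1)
})

test_that("exact consecutive-charge peaks deconvolve to the true mass with ~zero variance", {
  cs <- macsed_assign(tibble::tibble(mz = c(1112.118387, 1001.007276, 910.098185)))
  expect_identical(cs$charges, 9:11)
  expect_equal(cs$mass, 10000, tolerance = 1e-7)
  expect_lt(cs$uncertainty, 1e-6)
})

test_that("rounded m/z inputs still select the oracle's charges and statistics", {
  mz <- c(1112.12, 1001.01, 910.10)
  cs <- macsed_assign(tibble::tibble(mz = mz))
  oracle <- macsed_oracle(mz)
  expect_identical(cs$charges, as.integer(oracle$charges))
  expect_identical(cs$charges, 9:11)
  expect_lt(abs(cs$mass - 10000), 0.05)
  expect_gt(cs$uncertainty, 0)
  expect_equal(cs$mass, oracle$mass)
  expect_equal(cs$uncertainty, oracle$uncertainty)
})

test_that("a two-peak series equals the global variance argmin from exhaustive search", {
  mz <- c(1001.007276, 910.098185)
  cs <- macsed_assign(tibble::tibble(mz = mz))
  oracle <- macsed_oracle(mz)
  expect_identical(cs$charges, as.integer(oracle$charges))
  expect_equal(cs$mass, oracle$mass)
  expect_equal(cs$uncertainty, oracle$uncertainty)
})

test_that("assignment rejects degenerate inputs", {
  expect_error(macsed_assign(tibble::tibble(mz = 1000)), "at least 2")
  expect_error(macsed_assign(tibble::tibble(mz = c(1000, 1000))), "distinct")
  expect_error(macsed_assign(peaks_at(10000, 9:11), z_max = 2), "z_max")
})

test_that("noiseless series over a wide mass/charge range are recovered exactly", {
  set.seed(101)
  for (rep in 1:50) {
    mass <- 10^runif(1, log10(5e3), log10(5e6))
    k <- sample(2:40, 1)
    z_lo <- sample(1:(500 - k), 1)
    charges <- z_lo:(z_lo + k - 1)
    cs <- macsed_assign(peaks_at(mass, charges))
    expect_identical(cs$charges, as.integer(charges))
    expect_lt(abs(cs$mass - mass) / mass, 1e-9)
    expect_lt(cs$uncertainty, 1e-6)
  }
})

test_that("the selected base charge always equals the brute-force variance argmin", {
  set.seed(202)
  for (rep in 1:25) {
    mass <- runif(1, 8e3, 9e5)
    k <- sample(3:12, 1)
    z_lo <- sample(5:80, 1)
    jitter <- rnorm(k, 0, 0.05)
    mz <- mz_from_mass(mass, z_lo:(z_lo + k - 1)) + jitter
    cs <- macsed_assign(tibble::tibble(mz = mz), z_max = 200)
    oracle <- macsed_oracle(mz, z_max = 200)
    expect_identical(min(cs$charges), as.integer(oracle$z0))
    expect_equal(cs$mass, oracle$mass)
    expect_equal(cs$uncertainty, oracle$uncertainty)
  }
})

test_that("moderate m/z jitter rarely breaks charge assignment and errors grow with noise", {
  set.seed(303)
  mass <- 1e5
  charges <- 40:50
  n_rep <- 60
  med_err <- c()
  for (sigma in c(0.01, 0.1, 0.5)) {
    ok <- 0
    errs <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      mz <- mz_from_mass(mass, charges) + rnorm(length(charges), 0, sigma)
      cs <- macsed_assign(tibble::tibble(mz = mz))
      if (identical(cs$charges, as.integer(charges))) ok <- ok + 1
      errs[i] <- abs(cs$mass - mass)
    }
    if (sigma == 0.1) expect_gte(ok / n_rep, 0.95)
    med_err <- c(med_err, stats::median(errs))
  }
  expect_true(all(diff(med_err) > 0))
})

test_that("mass finder lists descending m/z per ascending charge", {
  tab <- mass_finder(100000, 10, 12)
  expect_equal(tab$charge, 10:12)
  expect_equal(tab$mz, c(10001.007276, 9091.916367, 8334.340609), tolerance = 1e-9)

  expect_equal(nrow(mass_finder(50000, 7, 7)), 1)
  expect_error(mass_finder(50000, 0, 5), "positive integers")
  expect_error(mass_finder(50000, 8, 5), "z_lo <= z_hi")

  # peaks placed exactly at mass-finder positions deconvolve back to the mass
  M <- 123456.78
  tab <- mass_finder(M, 20, 25)
  cs <- macsed_assign(tibble::tibble(mz = tab$mz))
  expect_identical(cs$charges, 20:25)
  expect_lt(abs(cs$mass - M) / M, 1e-9)
})

test_that("adjacent-peak prediction extends a series consistently with the mass finder", {
  cs <- macsed_assign(peaks_at(10000, 9:11))
  pred <- predict_adjacent(cs)
  expect_equal(pred$charge, c(8L, 12L))
  expect_equal(pred$mz, c(1251.007276, 834.340609), tolerance = 1e-6)

  pred3 <- predict_adjacent(cs, n = 3)
  expect_equal(pred3$charge, c(6:8, 12:14))
  # consistency: every prediction lies exactly on the mass finder line
  for (i in seq_len(nrow(pred3))) {
    expect_identical(
      pred3$mz[i],
      mass_finder(cs$mass, pred3$charge[i], pred3$charge[i])$mz
    )
  }

  # charges below 1 are dropped
  low <- macsed_assign(peaks_at(5000, 1:3))
  pred_low <- predict_adjacent(low, n = 1)
  expect_equal(pred_low$charge, 4L)
})
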
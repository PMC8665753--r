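# Independent oracles and fixture builders. These deliberately re-derive
# results by brute force / direct arithmetic, never by calling the package
# code paths they are used to check.

# exact peak positions for a species of given mass over consecutive charges
peaks_at <- function(mass, charges, adduct = 1.007276, intensity = 1) {
  tibble::tibble(
    mz = (mass + charges * adduct) / charges,
    intensity = intensity
  )
}

# brute-force variance scan over every candidate base charge, plain loops
macsed_oracle <- function(mz, z_max = 500, adduct = 1.007276) {
  mz <- sort(mz, decreasing = TRUE)
  k <- length(mz)
  best_z0 <- NA_integer_
  best_var <- Inf
  for (z0 in 1:(z_max - k + 1)) {
    masses <- numeric(k)
    for (i in seq_len(k)) {
      z <- z0 + i - 1
      masses[i] <- mz[i] * z - z * adduct
    }
    v <- stats::var(masses)
    if (v < best_var) { # strict <: first (smallest) z0 wins ties
      best_var <- v
      best_z0 <- z0
    }
  }
  masses <- numeric(k)
  for (i in seq_len(k)) {
    z <- best_z0 + i - 1
    masses[i] <- mz[i] * z - z * adduct
  }
  list(
    z0 = best_z0,
    charges = best_z0:(best_z0 + k - 1),
    mass = mean(masses),
    uncertainty = stats::sd(masses)
  )
}

# exhaustive nested enumeration over the full count grid
stoich_oracle <- function(masses, caps, target, tolerance) {
  grid <- do.call(expand.grid, lapply(caps, function(m) 0:m))
  total <- as.matrix(grid) %*% masses
  keep <- abs(total - target) <= tolerance & rowSums(grid) > 0
  counts <- as.matrix(grid[keep, , drop = FALSE])
  dimnames(counts) <- NULL
  counts
}

# canonical string form of a solution set, order-independent comparison
stoich_key <- function(counts) {
  sort(apply(counts, 1, paste, collapse = "/"))
}
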
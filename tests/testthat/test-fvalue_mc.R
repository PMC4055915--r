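test_that("pair energy: quadratic vertex, unit z-score, symbolic oracle", {
  expect_equal(pair_energy(6, 6, 1.5), 0)
  vals <- pair_energy(c(5.9, 6.1), 6, 1.5)
  expect_true(all(vals > 0))
  # (r - rbar) = sigma adds kT/2 above the minimum
  expect_equal(pair_energy(7.5, 6, 1.5, kT = 2) - pair_energy(6, 6, 1.5, kT = 2),
               2 / 2)
  set.seed(3)
  for (k in 1:20) {
    r <- runif(1, 2, 20); rb <- runif(1, 4, 15); sg <- runif(1, 0.2, 4)
    kt <- runif(1, 0.5, 5)
    expect_equal(pair_energy(r, rb, sg, kt), kt * (r - rb)^2 / (2 * sg^2))
  }
  expect_error(pair_energy(5, 5, 0), "sigma")
  # the dropped constant is conformation-independent: energy differences
  # with and without it are identical, so Metropolis decisions coincide
  dE_drop <- pair_energy(8, 6, 1.5) - pair_energy(5, 6, 1.5)
  dE_full <- pair_energy(8, 6, 1.5, include_constant = TRUE) -
    pair_energy(5, 6, 1.5, include_constant = TRUE)
  expect_equal(dE_drop, dE_full)
})

test_that("potential building floors sigma and covers all |i-j| >= 2 pairs", {
  pot <- potential_from_stats(test_sequence_50(), small_stats())
  n <- pot$n
  for (k in 1:20) {
    i <- sample(1:(n - 2), 1); j <- sample((i + 2):n, 1)
    expect_false(is.na(pot$rbar[i, j]))
    expect_gte(pot$sigma[i, j], 0.1)
  }
  expect_true(all(is.na(diag(pot$rbar))))
  expect_error(potential_from_stats("AAAA", small_stats()), "shorter than 10")
})

test_that("sweeps preserve bond lengths and obey Metropolis limits", {
  pot <- potential_from_stats(test_sequence_50(), small_stats())
  set.seed(1)
  x0 <- random_chain(50)
  expect_equal(sqrt(rowSums(diff(x0)^2)), rep(3.8, 49), tolerance = 1e-9)

  # kT -> infinity: acceptance -> 1
  set.seed(2)
  hot <- mc_sweep(x0, pot, kT = 1e12, n_sweeps = 5)
  expect_gte(hot$acceptance, 0.999)

  # zero amplitude: dU = 0, everything accepted, coordinates unchanged
  set.seed(3)
  frozen <- mc_sweep(x0, pot, kT = 1, n_sweeps = 2, max_angle = 0)
  expect_equal(frozen$acceptance, 1)
  expect_equal(frozen$coords, x0, tolerance = 1e-12)

  # bond-length conservation over 1000 sweeps
  set.seed(4)
  long <- mc_sweep(x0, pot, kT = 50, n_sweeps = 1000)
  bonds <- sqrt(rowSums(diff(long$coords)^2))
  expect_lt(max(abs(bonds - 3.8)), 1e-6)

  # energy decreases in expectation from a random start at low kT
  set.seed(5)
  drops <- replicate(3, {
    x <- random_chain(50)
    e0 <- chain_energy(x, pot)
    e1 <- chain_energy(mc_sweep(x, pot, kT = 5, n_sweeps = 100)$coords, pot)
    e1 - e0
  })
  expect_lt(mean(drops), 0)
})

test_that("kT calibration reaches the target and is monotone in the target", {
  pot <- potential_from_stats(test_sequence_50(), small_stats())
  set.seed(10)
  kt50 <- calibrate_kT(pot, target = 0.5, pilot_runs = 4, pilot_sweeps = 150,
                       tol = 0.02)
  expect_true(abs(attr(kt50, "acceptance") - 0.5) <= 0.02)
  set.seed(10)
  kt99 <- calibrate_kT(pot, target = 0.99, pilot_runs = 2, pilot_sweeps = 100,
                       tol = 0.02)
  expect_gt(as.numeric(kt99), as.numeric(kt50))
  # impossible target inside a clamped bracket errors with diagnostics
  set.seed(10)
  expect_error(calibrate_kT(pot, target = 0.95, pilot_runs = 1,
                            pilot_sweeps = 60, kT_bracket = c(1e-4, 1e-3)),
               "failed to bracket")
})

test_that("run_simulation is reproducible and contact frequencies are sane", {
  stats <- small_stats()
  seqr <- substr(test_sequence_50(), 1, 30)
  cf1 <- run_simulation(seqr, stats, n_steps = 200, n_runs = 2, seed = 7,
                        calibrate = FALSE, kT = 20)
  cf2 <- run_simulation(seqr, stats, n_steps = 200, n_runs = 2, seed = 7,
                        calibrate = FALSE, kT = 20)
  expect_identical(cf1$g, cf2$g)
  offd <- cf1$g[abs(row(cf1$g) - col(cf1$g)) >= 2]
  expect_true(all(offd >= 0 & offd <= 1))
  expect_true(all(is.na(cf1$g[abs(row(cf1$g) - col(cf1$g)) < 2])))
  expect_error(run_simulation("AAAAA", stats, n_steps = 10, n_runs = 1,
                              seed = 1), "shorter than 10")
})

test_that("homopolymer contact frequencies depend on |i-j| band-wise", {
  cf <- run_simulation(strrep("A", 30), small_stats(), n_steps = 800,
                       n_runs = 20, seed = 3, calibrate = FALSE, kT = 20)
  for (k in c(3, 5, 8)) {
    v <- sapply(1:(30 - k), function(i) cf$g[i, i + k])
    third <- floor(length(v) / 3)
    expect_lt(abs(mean(v[1:third]) - mean(v[(length(v) - third + 1):length(v)])),
              0.1)
  }
})

test_that("Q normalization matches brute-force z-scoring; centering identities", {
  set.seed(8)
  n <- 20
  g <- matrix(0, n, n)
  for (i in 1:(n - 2)) for (j in (i + 2):n) g[i, j] <- g[j, i] <- runif(1)
  Q <- normalize_contacts(g)
  # brute-force oracle
  sep <- abs(row(g) - col(g))
  for (m in unique(range_of_separation(2:(n - 1)))) {
    idx <- which(sep >= 2 & upper.tri(g) &
                   range_of_separation(pmax(sep, 1)) == m, arr.ind = TRUE)
    v <- g[idx]
    mu <- mean(v); dm <- sqrt(mean((v - mu)^2))
    for (r in seq_len(nrow(idx)))
      expect_equal(Q[idx[r, 1], idx[r, 2]], (g[idx[r, 1], idx[r, 2]] - mu) / dm)
    expect_lt(abs(sum(Q[idx])), 1e-9 * max(1, sum(abs(Q[idx]))))
  }
  # constant g within a range: Q = 0 there
  gc <- matrix(0, 15, 15)
  for (i in 1:13) for (j in (i + 2):15) gc[i, j] <- gc[j, i] <- 0.4
  Qc <- normalize_contacts(gc)
  expect_true(all(Qc[abs(row(Qc) - col(Qc)) >= 2] == 0))
  # F = rowSums(Q) sums to zero globally
  fp <- f_profile(Q)
  expect_lt(abs(sum(fp$F)), 1e-6 * sum(abs(fp$F)))
})

test_that("F-profile peaks: planted column, terminal exclusion, null case", {
  n <- 25
  Q0 <- matrix(0, n, n); diag(Q0) <- NA
  fp0 <- f_profile(Q0)
  expect_true(all(fp0$F == 0, na.rm = TRUE))
  expect_length(fp0$peaks, 0)

  plant <- function(m) {
    Q <- matrix(0, n, n)
    Q[m, ] <- Q[, m] <- 3; Q[m, m] <- 0
    f_profile(Q)
  }
  expect_equal(plant(12)$peaks, 12)   # unique interior peak
  expect_length(plant(2)$peaks, 0)    # terminal exclusion drops residue 2
})

test_that("peak matching is greedy-nearest with a hard tolerance boundary", {
  same <- match_peaks(c(5, 15, 25), c(5, 15, 25))
  expect_equal(same$matched$distance, c(0, 0, 0))
  off3 <- match_peaks(c(5, 15, 25), c(8, 18, 28), tolerance = 3)
  expect_equal(nrow(off3$matched), 3)
  off4 <- match_peaks(c(5, 15, 25), c(9, 19, 29), tolerance = 3)
  expect_equal(nrow(off4$matched), 0)
  expect_equal(off4$unmatched_a, c(5, 15, 25))
  # each peak used once
  m <- match_peaks(c(10), c(9, 11), tolerance = 3)
  expect_equal(nrow(m$matched), 1)
  expect_length(m$unmatched_b, 1)
})
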
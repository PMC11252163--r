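test_that("polarization is translation invariant and additive over molecules", {
  sys <- random_system(3, 15, seed = 9)
  P <- polarization(sys)
  sys2 <- sys
  sys2$positions <- sys$positions + matrix(c(3.2, -1.1, 7.9),
                                           nrow(sys$positions), 3, byrow = TRUE)
  expect_equal(polarization(sys2), P, tolerance = 1e-12)

  parts <- Reduce(`+`, lapply(1:3, function(m) {
    sub <- water_system(sys$positions[molecule_atoms(m), ], sys$box_side)
    polarization(sub)
  }))
  expect_equal(parts, P, tolerance = 1e-12)
})

test_that("the single-molecule dipole matches the hand-computed geometry value", {
  sys <- one_molecule()
  p <- spcfw_parameters()
  # |p| = 2 qH l0 cos(theta0 / 2), computed from the charges and geometry
  expected <- 2 * p$charge_H * p$bond_equilibrium_length *
    cos(p$bend_equilibrium_angle / 2)
  expect_equal(sqrt(sum(polarization(sys)^2)), expected, tolerance = 1e-12)
  expect_equal(spcfw_equilibrium_dipole(), expected, tolerance = 1e-12)
})

test_that("autocorrelation is exactly normalized and vanishes for white noise", {
  set.seed(2)
  P <- matrix(rnorm(3 * 20000), ncol = 3)
  phi <- autocorrelation(P, 0:30)
  expect_identical(phi[1], 1)
  se <- 1 / sqrt(nrow(P))
  expect_lt(max(abs(phi[-1])), 4 * se)
  expect_error(autocorrelation(P, c(0, 20000)), "lags")
})

test_that("AR(1) decay is recovered by the autocorrelation/fit pipeline", {
  set.seed(8)
  tau_true <- 12
  rho <- exp(-1 / tau_true)
  nrep <- 8
  n <- 30000
  lags <- 0:60
  acfs <- sapply(seq_len(nrep), function(r) {
    P <- matrix(0, n, 3)
    for (i in 2:n) P[i, ] <- rho * P[i - 1, ] + rnorm(3)
    autocorrelation(P, lags)
  })
  # direct check on a single estimate
  expect_lt(abs(-1 / log(mean(acfs[2, ])) - tau_true), 0.05 * tau_true * 4)
  set.seed(77)  # bootstrap weights must match between the two fits
  fit <- fit_decay(acfs, lags)
  expect_lt(abs(fit$tau - tau_true) / tau_true, 0.05)
  expect_gt(fit$se, 0)

  # unit covariance: doubling the lag times doubles tau
  set.seed(77)
  fit2 <- fit_decay(acfs, 2 * lags)
  expect_equal(fit2$tau, 2 * fit$tau, tolerance = 1e-9)
})

test_that("an exact exponential is fitted to high accuracy", {
  set.seed(3)
  lags <- 0:50
  acfs <- sapply(1:5, function(r) exp(-lags / 5) * exp(rnorm(51, 0, 1e-3)))
  fit <- fit_decay(acfs, lags)
  expect_lt(abs(fit$tau - 5) / 5, 0.01)
  expect_error(fit_decay(acfs[, 1, drop = FALSE], lags), "two replicates")
})

test_that("characteristic distances apply the per-sampler conversions", {
  # ECMC: unit mean active speed gives d = tau
  expect_equal(characteristic_distance("ecmc_newtonian", 7,
                                       list(mean_active_speed = 1)), 7)
  # Metropolis at zero acceptance never moves
  expect_equal(characteristic_distance("metropolis", 100,
                                       list(acceptance = 0, halfwidth_H = 0.1,
                                            halfwidth_O = 0.1)), 0)
  # homogeneity of degree one in tau, all tags
  for (tag in c("ecmc_straight", "md_external", "metropolis")) {
    pars <- list(mean_active_speed = 0.9, n_molecules = 64,
                 mean_speed_H = 14, mean_speed_O = 3.5,
                 acceptance = 0.37, halfwidth_H = 0.09, halfwidth_O = 0.05)
    expect_equal(characteristic_distance(tag, 6, pars),
                 3 * characteristic_distance(tag, 2, pars), tolerance = 1e-12)
  }
  # MD branch equals the Maxwell-speed formula spelled out
  v_H <- maxwell_mean_speed(300, 1.0079)
  v_O <- maxwell_mean_speed(300, 15.9994001)
  expect_equal(
    characteristic_distance("md_external", 2,
                            list(n_molecules = 10, mean_speed_H = v_H,
                                 mean_speed_O = v_O)),
    10 * (2 * v_H + v_O) * 2, tolerance = 1e-12)
  expect_error(characteristic_distance("metropolis", 1, list()), "missing")
})

test_that("Maxwell mean speed has the closed form and scalings", {
  expect_equal(maxwell_mean_speed(300, 4), maxwell_mean_speed(300, 1) / 2,
               tolerance = 1e-12)
  expect_equal(maxwell_mean_speed(1200, 1), 2 * maxwell_mean_speed(300, 1),
               tolerance = 1e-12)
  # against numerical integration of the Maxwell-Boltzmann speed density
  kB <- 0.0019872041
  m <- 15.9994001; T <- 300
  dens <- function(v) 4 * pi * v^2 *
    (m / (2 * pi * kB * T))^(3 / 2) * exp(-m * v^2 / (2 * kB * T))
  num <- integrate(function(v) v * dens(v), 0, Inf, rel.tol = 1e-12)$value
  expect_equal(maxwell_mean_speed(T, m), num, tolerance = 1e-8)
})

test_that("the mean cube displacement equals 0.961 delta and scales linearly", {
  r <- mean_cube_displacement(1)
  expect_equal(round(r, 3), 0.961)
  expect_equal(mean_cube_displacement(2.5), 2.5 * r, tolerance = 1e-12)
  # Monte Carlo cross-check
  set.seed(5)
  n <- 2e6
  mc <- mean(sqrt(rowSums(matrix(runif(3 * n, -1, 1), ncol = 3)^2)))
  se <- sd(sqrt(rowSums(matrix(runif(3 * 1e4, -1, 1), ncol = 3)^2))) / sqrt(n)
  expect_lt(abs(mc - r), 4 * se)
})

test_that("polarization series validate their invariants", {
  expect_error(polarization_series(c(1, 1, 2), matrix(0, 3, 3)),
               "strictly increasing")
  s <- polarization_series(1:5, matrix(rnorm(15), 5, 3), "metropolis")
  expect_s3_class(s, "polarization_series")
})
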
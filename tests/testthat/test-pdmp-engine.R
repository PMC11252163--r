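test_that("the force kick is an involution and conserves v^T M v", {
  set.seed(6)
  for (rep in 1:2000) {
    na <- 6
    v <- matrix(rnorm(3 * na), na, 3)
    mass <- if (rep %% 3 == 0) runif(na, 0.5, 16) else rep(1, na)
    g <- matrix(0, na, 3)
    idx <- sample(na, sample(2:3, 1))
    g[idx, ] <- rnorm(3 * length(idx))
    v1 <- newtonian_kick(v, g, mass)
    v2 <- newtonian_kick(v1, g, mass)
    expect_equal(v2, v, tolerance = 1e-12)
    expect_equal(sum(mass * rowSums(v1^2)), sum(mass * rowSums(v^2)),
                 tolerance = 1e-12)
    # only atoms carrying gradient change velocity
    expect_equal(v1[-idx, ], v[-idx, ])
  }
  expect_error(newtonian_kick(matrix(0, 2, 3), matrix(0, 2, 3)),
               "zero gradient")
})

test_that("the equal-mass head-on kick exchanges the velocities", {
  # pair factor, gradient along the line of motion: elastic exchange
  v <- rbind(c(1, 0, 0), c(0, 0, 0))
  g <- rbind(c(1, 0, 0), c(-1, 0, 0))
  v1 <- newtonian_kick(v, g)
  expect_equal(v1, rbind(c(0, 0, 0), c(1, 0, 0)), tolerance = 1e-14)
})

test_that("pair lifting transfers activity and conserves total velocity", {
  set.seed(8)
  sys <- random_system(2, 12)
  lj <- Filter(function(f) f$kind == "lennard_jones", factor_list(sys))[[1]]
  for (rep in 1:50) {
    lift <- lifted_state(sys)
    lift$active_atom <- lj$atoms[sample(2, 1)]
    res <- lift_pair(lj, sys, lift)
    expect_identical(res$next_active,
                     setdiff(lj$atoms, lift$active_atom))
    dv <- res$velocity - lift$velocity
    # the two velocity changes are exactly opposite
    expect_equal(dv[lj$atoms[1], ], -dv[lj$atoms[2], ], tolerance = 1e-12)
    expect_equal(colSums(dv), c(0, 0, 0), tolerance = 1e-12)
  }
  expect_error(lift_pair(factor_list(sys)[[3]], sys, lifted_state(sys)),
               "two-atom")
})

test_that("general lifting reproduces its outcome weights", {
  # fixed bend-factor event: enumerate the six outcome weights directly and
  # compare empirical frequencies over many draws
  set.seed(12)
  sys <- one_molecule()
  sys$positions[2, ] <- sys$positions[2, ] + c(0.02, -0.05, 0.04)
  sys$positions[3, ] <- sys$positions[3, ] + c(-0.03, 0.01, 0.02)
  bend <- Filter(function(f) f$kind == "bend", factor_list(sys))[[1]]
  lift <- lifted_state(sys)
  # make the event admissible: active atom moving uphill for the bend
  g2 <- factor_gradient(bend, sys, 2)
  lift$active_atom <- 2L
  lift$velocity[2, ] <- g2 / sqrt(sum(g2^2)) + c(0.1, 0.2, -0.1)

  g <- matrix(0, nrow(lift$velocity), 3)
  for (a in bend$atoms) g[a, ] <- factor_gradient(bend, sys, a)
  vk <- newtonian_kick(lift$velocity, g, lift$mass)
  w_kick <- vapply(bend$atoms, function(a) max(0, -sum(g[a, ] * vk[a, ])), 0)
  w_keep <- vapply(bend$atoms, function(a)
    max(0, -sum(g[a, ] * lift$velocity[a, ])), 0)
  w <- c(w_kick, w_keep) / sum(w_kick + w_keep)

  n <- 40000
  counts <- matrix(0, 2, 3)
  for (i in 1:n) {
    res <- lift_general(bend, sys, lift)
    kicked <- !identical(res$velocity, lift$velocity)
    counts[if (kicked) 1 else 2, match(res$next_active, bend$atoms)] <-
      counts[if (kicked) 1 else 2, match(res$next_active, bend$atoms)] + 1
  }
  emp <- c(counts[1, ], counts[2, ]) / n
  for (k in seq_along(w)) {
    se <- sqrt(max(w[k] * (1 - w[k]), 1e-12) / n)
    expect_lt(abs(emp[k] - w[k]), 4 * se + 1e-12)
  }
  # whenever the velocity is kept, the active atom must change
  expect_equal(counts[2, match(2L, bend$atoms)], 0)
})

test_that("single-atom factors always take the kick branch", {
  # a pair factor restricted to one contributing atom cannot occur in this
  # model; emulate with a bend whose other gradients vanish numerically by
  # checking the weight formula instead: if only the active atom carries
  # gradient, the keep weight is zero and the kick flips the velocity sign
  v <- rbind(c(0.4, -0.2, 0.1))
  g <- rbind(c(1, 2, -1))
  vk <- newtonian_kick(v, g)
  # kick reflects v in g: keep-branch weight max(0, -g.v) relates by sign
  expect_equal(sum(g * vk), -sum(g * v), tolerance = 1e-12)
})

test_that("straight ratio lifting matches its weights and never self-selects", {
  set.seed(14)
  sys <- one_molecule()
  sys$positions[2, ] <- sys$positions[2, ] + c(0.03, -0.02, 0.05)
  bend <- Filter(function(f) f$kind == "bend", factor_list(sys))[[1]]
  lift <- lifted_state(sys)
  lift$active_atom <- 2L
  g2 <- factor_gradient(bend, sys, 2)
  lift$velocity[2, ] <- g2 / sqrt(sum(g2^2))  # uphill, unit speed
  v <- lift$velocity[2, ]
  w <- vapply(bend$atoms, function(a)
    max(0, -sum(factor_gradient(bend, sys, a) * v)), 0)
  w <- w / sum(w)
  expect_equal(w[match(2L, bend$atoms)], 0)  # own weight vanishes uphill

  n <- 40000
  draws <- replicate(n, straight_lift(bend, sys, lift))
  emp <- vapply(bend$atoms, function(a) mean(draws == a), 0)
  for (k in seq_along(w)) {
    se <- sqrt(max(w[k] * (1 - w[k]), 1e-12) / n)
    expect_lt(abs(emp[k] - w[k]), 4 * se + 1e-12)
  }

  # pair factors transfer deterministically
  bondf <- factor_list(sys)[[1]]
  lift$active_atom <- bondf$atoms[1]
  expect_identical(straight_lift(bondf, sys, lift), bondf$atoms[2])
})

test_that("lifting resampling satisfies its stationary-law corrections", {
  set.seed(19)
  sys <- random_system(2, 12)
  lift <- lifted_state(sys)
  na <- 6
  actives <- integer(20000)
  for (i in seq_len(20000)) {
    lift <- resample_lifting(lift)
    actives[i] <- lift$active_atom
    if (i <= 200) {
      expect_equal(colSums(lift$velocity), c(0, 0, 0), tolerance = 1e-12)
      expect_equal(sum(lift$mass * rowSums(lift$velocity^2)),
                   2 * lift$kinetic_energy, tolerance = 1e-12)
    }
  }
  # uniform active-atom label
  expect_gt(chisq.test(tabulate(actives, na))$p.value, 1e-3)

  # isotropy with identity masses: first-moment components vanish
  vs <- t(replicate(4000, {
    l <- resample_lifting(lift)
    l$velocity[l$active_atom, ] / sqrt(sum(l$velocity[l$active_atom, ]^2))
  }))
  se <- 1 / sqrt(3 * nrow(vs))
  expect_lt(max(abs(colMeans(vs))), 4 * se * sqrt(3))
})

test_that("factor event rate clamps downhill and orthogonal motion to zero", {
  sys <- random_system(2, 12, seed = 44, jitter = 0.4)
  f <- factor_list(sys)[[1]]
  g <- factor_gradient(f, sys, f$atoms[1])
  # orthogonal velocity
  v_perp <- c(-g[2], g[1], 0)
  expect_equal(factor_event_rate(f, sys, f$atoms[1], v_perp, beta300), 0)
  # downhill
  expect_equal(factor_event_rate(f, sys, f$atoms[1], -g, beta300), 0)
  # uphill equals beta * g.v and matches the potential's time derivative
  v <- g / sqrt(sum(g^2)) * 0.7
  r <- factor_event_rate(f, sys, f$atoms[1], v, beta300)
  h <- 1e-6
  sp <- sys; sp$positions[f$atoms[1], ] <- sp$positions[f$atoms[1], ] + v * h
  sm <- sys; sm$positions[f$atoms[1], ] <- sm$positions[f$atoms[1], ] - v * h
  dudt <- (factor_potential(f, sp) - factor_potential(f, sm)) / (2 * h)
  expect_equal(r, beta300 * max(0, dudt), tolerance = 1e-5)
  # inactive atoms have zero rate by definition
  expect_equal(factor_event_rate(f, sys, 6L, v, beta300), 0)
})

test_that("the compiled engine conserves kinetic energy and stamps samples exactly", {
  box <- generate_water_box(2, box_side = 20, seed = 31, equilibrate = FALSE)
  run <- run_ecmc(box, simulation_parameters(seed = 7, sampling_interval = 0.25,
                                             tau_chain = 50),
                  duration = 150)
  expect_lt(run$kinetic_energy_drift, 1e-9)
  expect_lt(max(abs(run$velocity_sum)), 1e-10)
  expect_equal(run$bound_violations, 0)
  expect_equal(run$stamps, seq(0, 150, 0.25))
  expect_gt(sum(run$events), 500)
})

test_that("the dimer sampled by the exact bond solver follows the radial Boltzmann law", {
  set.seed(99)
  sys <- one_molecule(box_side = 30)
  res <- mini_ecmc(sys, list(ecmc_factor("bond", c(1, 2))),
                   duration = 1500, sampling_interval = 0.5, tau_chain = 5)
  r <- vapply(res$configs, function(x) sqrt(sum((x[2, ] - x[1, ])^2)), 0)
  r <- r[-(1:200)]
  p <- spcfw_parameters()
  expect_gt(suppressWarnings(
    ks.test(r, dimer_marginal_cdf(p$bond_stiffness,
                                  p$bond_equilibrium_length))$p.value),
    1e-3)
})
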
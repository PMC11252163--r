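test_that("Fibonacci vectors follow the golden-ratio equal-area construction", {
  fib <- fibonacci_sphere(10, 0.36)
  expect_equal(unname(sqrt(rowSums(fib^2))), rep(1, 10), tolerance = 1e-12)
  expect_equal(attr(fib, "azimuth")[1], 0)
  expect_equal(attr(fib, "polar")[1], acos(1 - 0.72 / 9.72), tolerance = 1e-14)
  # golden-angle increments
  golden <- (1 + sqrt(5)) / 2
  expect_equal(diff(attr(fib, "azimuth")), rep(2 * pi / golden, 9))
  expect_error(fibonacci_sphere(0), "at least 1")
  expect_error(fibonacci_sphere(10, 1.2), "eps")
})

test_that("nearest-Fibonacci lookup is exact, scale-free and matches Euclidean argmin", {
  set.seed(3)
  fib <- fibonacci_sphere(10, 0.36)
  for (d in 1:10) expect_identical(nearest_fibonacci(fib[d, ], fib), d)
  for (rep in 1:2000) {
    v <- rnorm(3)
    i1 <- nearest_fibonacci(v, fib)
    expect_identical(nearest_fibonacci(runif(1, 0.1, 9) * v, fib), i1)
    vn <- v / sqrt(sum(v^2))
    eu <- which.min(colSums((t(fib) - vn)^2))
    expect_identical(i1, as.integer(eu))
  }
  expect_error(nearest_fibonacci(c(0, 0, 0), fib), "zero velocity")
})

test_that("Walker tables sample proportionally to their bounds", {
  set.seed(41)
  # uniform bounds
  wt <- build_walker_table(rep(2, 8))
  f <- tabulate(walker_sample(wt, 40000), 8) / 40000
  expect_lt(max(abs(f - 1 / 8)), 4 * sqrt(0.125 * 0.875 / 40000))
  # 2:1:1
  wt <- build_walker_table(c(2, 1, 1))
  expect_equal(wt$total, 4)
  f <- tabulate(walker_sample(wt, 40000), 3) / 40000
  expect_lt(abs(f[1] - 0.5), 4 * sqrt(0.25 / 40000))
  expect_lt(abs(f[2] - 0.25), 4 * sqrt(0.1875 / 40000))
  # degenerate cases
  expect_identical(unique(walker_sample(build_walker_table(5), 100)), 1L)
  expect_error(build_walker_table(c(0, 0)), "all bounds are zero")
  expect_error(build_walker_table(c(-1, 2)), "nonnegative")
  # alias sampling is exact in expectation for irregular weights
  b <- c(0.3, 1.7, 0.05, 2.2, 0.75)
  wt <- build_walker_table(b)
  f <- tabulate(walker_sample(wt, 60000), 5) / 60000
  p <- b / sum(b)
  expect_lt(max(abs(f - p) / sqrt(p * (1 - p) / 60000)), 4.5)
})

test_that("cell grids track occupancy with a one-occupant policy and surplus list", {
  sys <- generate_water_box(8, box_side = 25, seed = 2, equilibrate = FALSE)
  g <- cell_grid(sys, excluded_layers = 2)
  expect_gte(g$n_cells, 6)
  # every molecule registered exactly once
  reg <- sum(!is.na(g$cell_of)) + length(g$surplus)
  expect_equal(reg, 8)
  expect_true(all(tabulate(g$occupant[!is.na(g$occupant)]) <= 1))

  # moving a molecule across a boundary updates exactly one pair of cells
  m <- which(!is.na(g$cell_of))[1]
  sys2 <- sys
  sys2$positions[molecule_atoms(m), ] <-
    sys2$positions[molecule_atoms(m), ] + g$cell_side * 1.01
  g2 <- update_occupancy(g, sys2, m)
  changed <- which(!(is.na(g$occupant) == is.na(g2$occupant)) |
                     (!is.na(g$occupant) & !is.na(g2$occupant) &
                        g$occupant != g2$occupant))
  expect_lte(length(changed), 2)
  expect_gte(length(changed), 1)

  # two barycenters forced into one cell: exactly one goes to surplus
  sys3 <- sys
  other <- which(!is.na(g$cell_of))[2]
  mo <- which(!is.na(g$cell_of))[1]
  shift <- molecule_barycenters(sys)[mo, ] - molecule_barycenters(sys)[other, ]
  sys3$positions[molecule_atoms(other), ] <-
    sys3$positions[molecule_atoms(other), ] +
    matrix(shift, 3, 3, byrow = TRUE) + 0.05
  g3 <- update_occupancy(g, sys3, other)
  expect_true(other %in% g3$surplus || mo %in% g3$surplus)
})

test_that("cell bounds rescale linearly and dominate the true event rate", {
  set.seed(77)
  sys <- generate_water_box(8, box_side = 25, seed = 5, equilibrate = FALSE)
  grid <- cell_grid(sys, excluded_layers = 2)
  sphere <- fibonacci_sphere(10, 0.36)
  offs <- grid_offsets(grid$n_cells, 2)
  # the nearest allowed offset is the hardest case for bound validity
  o_near <- offs[which.min(rowSums(offs^2)), ]
  b1 <- estimate_cell_bound("coulomb", o_near, 1, grid, sys, sphere, beta300,
                            prefactor = 1)
  b2 <- estimate_cell_bound("coulomb", o_near, 1, grid, sys, sphere, beta300,
                            prefactor = 2)
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
  expect_error(estimate_cell_bound("coulomb", c(0, 1, 0), 1, grid, sys,
                                   sphere, beta300), "excluded layers")

  # validity sweep: random molecule placements with barycenters inside the
  # two cells never exceed the stored bound (unit charge and speed)
  ew <- ewald_settings(sys$box_side)
  L <- sys$box_side
  cs <- grid$cell_side
  geom <- spcfw_equilibrium_geometry()
  viol <- 0
  n_sweep <- 800
  for (d in c(1, 6)) {
    vhat <- sphere[d, ]
    bd <- estimate_cell_bound("coulomb", o_near, d, grid, sys, sphere,
                              beta300, prefactor = 2)
    for (rep in seq_len(n_sweep)) {
      place <- function(cell_origin) {
        q <- rnorm(4); q <- q / sqrt(sum(q^2))
        R <- matrix(c(
          1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
          2 * (q[2] * q[4] + q[1] * q[3]),
          2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
          2 * (q[3] * q[4] - q[1] * q[2]),
          2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
          1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
        mol <- geom %*% t(R)
        bary <- colMeans(mol)
        target <- cell_origin + runif(3, 0, cs)
        mol + matrix(target - bary, 3, 3, byrow = TRUE)
      }
      pos <- rbind(place(c(0, 0, 0)), place(o_near * cs))
      s2 <- water_system(pos, L)
      res <- ewald_pair_interaction(s2, 1, 2, ew)
      for (a in 1:3) {
        rate <- beta300 * max(0, sum(res$grad_i[a, ] * vhat)) /
          abs(s2$charge[a])  # unit charge, unit speed
        if (rate > bd) viol <- viol + 1
      }
    }
  }
  expect_equal(viol, 0)
})

test_that("bundled cell-veto candidates are exponential and rescale with speed", {
  set.seed(50)
  sys <- generate_water_box(8, box_side = 25, seed = 5, equilibrate = FALSE)
  grid <- cell_grid(sys, excluded_layers = 2)
  sphere <- fibonacci_sphere(10, 0.36)
  offs <- grid_offsets(grid$n_cells, 2)
  bounds <- runif(nrow(offs), 0, 0.02)
  wt <- build_walker_table(bounds)
  lift <- lifted_state(sys)
  i <- lift$active_atom
  sp <- sqrt(sum(lift$velocity[i, ]^2))
  qa <- abs(sys$charge[i])
  draws <- replicate(20000, cell_veto_candidate(lift, wt, offs,
                                                charge = qa)$candidate_time)
  expect_gt(ks.test(draws, "pexp", wt$total * sp * qa)$p.value, 1e-3)

  # target offsets never lie within the excluded layers
  ent <- replicate(2000, cell_veto_candidate(lift, wt, offs, qa)$offset)
  expect_true(all(apply(abs(ent), 2, max) > 2))

  # doubling the speed halves the mean waiting time
  lift2 <- lift
  lift2$velocity <- 2 * lift$velocity
  d2 <- replicate(20000, cell_veto_candidate(lift2, wt, offs,
                                             charge = qa)$candidate_time)
  expect_lt(abs(mean(d2) / mean(draws) - 0.5), 0.03)
})

test_that("cell-veto confirmation computes the true Ewald rate", {
  sys <- generate_water_box(8, box_side = 25, seed = 6, equilibrate = FALSE)
  lift <- lifted_state(sys)
  lift$active_atom <- 1L
  ew <- ewald_settings(sys$box_side)
  f <- ecmc_factor("coulomb_molecular", c(molecule_atoms(1), molecule_atoms(3)))
  rate <- factor_event_rate(f, sys, 1L, lift$velocity[1, ], beta300, ewald = ew)
  # a huge bound: confirmation probability equals rate / bound
  set.seed(1)
  n <- 20000
  bound <- max(rate, 1e-12) * 4
  acc <- mean(replicate(n, confirm_cell_event(sys, lift, 3, bound,
                                              beta = beta300, ewald = ew)))
  expect_lt(abs(acc - rate / bound), 4 * sqrt(0.25 / n) + 1e-9)
  # downhill factor never confirms
  lift$velocity[1, ] <- -factor_gradient(f, sys, 1, ewald = ew)
  expect_false(confirm_cell_event(sys, lift, 3, 1, beta = beta300, ewald = ew))
})

test_that("the number of candidate sources stays bounded as N grows", {
  counts <- vapply(c(64, 216), function(n) {
    sys <- generate_water_box(n, seed = n, equilibrate = FALSE)
    run <- run_ecmc(sys, simulation_parameters(seed = 1, tau_chain = 10,
                                               sampling_interval = 0.5),
                    duration = 1.5)
    run$max_handlers
  }, 0)
  # handler count is set by the excluded-layer volume, not by N
  expect_true(all(counts <= 300))
  expect_lt(abs(counts[2] - counts[1]), 150)
})
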
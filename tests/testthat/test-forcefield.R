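test_that("factor potentials vanish at their minima and partition the total", {
  sys <- one_molecule()
  facs <- factor_list(sys)
  kinds <- vapply(facs, `[[`, "", "kind")
  expect_equal(factor_potential(facs[[which(kinds == "bond")[1]]], sys), 0)
  expect_equal(factor_potential(facs[[which(kinds == "bend")[1]]], sys), 0)

  # LJ vanishes at r = sigma
  p <- spcfw_parameters()
  pos <- rbind(spcfw_equilibrium_geometry() + 3,
               spcfw_equilibrium_geometry() +
                 matrix(c(3 + p$lj_sigma, 3, 3), 3, 3, byrow = TRUE))
  sys2 <- water_system(pos, 40)
  lj <- Filter(function(f) f$kind == "lennard_jones", factor_list(sys2))[[1]]
  expect_equal(factor_potential(lj, sys2), 0, tolerance = 1e-12)

  # Eq-partition: total equals the factor sum exactly, for several N
  for (n in c(2, 4)) {
    s <- random_system(n, 14, seed = n)
    ew <- ewald_settings(s$box_side)
    tot <- total_potential(s, ewald = ew)
    parts <- sum(vapply(factor_list(s), factor_potential, numeric(1),
                        system = s, ewald = ew))
    expect_equal(tot, parts, tolerance = 1e-13)
  }
})

test_that("total potential is invariant under lattice-commensurate translation", {
  s <- random_system(2, 12, seed = 3)
  ew <- ewald_settings(s$box_side)
  e0 <- total_potential(s, ewald = ew)
  s2 <- s
  s2$positions <- s$positions + matrix(s$box_side * c(1, -2, 3),
                                       nrow(s$positions), 3, byrow = TRUE)
  expect_equal(total_potential(s2, ewald = ew), e0, tolerance = 1e-9)

  # intramolecular part of a single equilibrium molecule is zero
  m1 <- one_molecule()
  expect_equal(total_potential(m1), 0, tolerance = 1e-12)
})

test_that("analytic factor gradients match finite differences", {
  set.seed(11)
  ew <- ewald_settings(12)
  for (rep in 1:25) {
    s <- random_system(2, 12, jitter = 0.6)
    facs <- factor_list(s)
    for (f in facs) {
      for (atom in f$atoms) {
        g <- factor_gradient(f, s, atom, ewald = ew)
        gn <- fd_gradient(f, s, atom, ewald = ew)
        expect_equal(g, gn, tolerance = 1e-5,
                     label = sprintf("%s grad atom %d rep %d", f$kind, atom, rep))
      }
    }
  }
})

test_that("pair factors obey translational antisymmetry and bends sum to zero", {
  set.seed(4)
  ew <- ewald_settings(12)
  for (rep in 1:10) {
    s <- random_system(2, 12, jitter = 0.5)
    for (f in factor_list(s)) {
      if (f$kind %in% c("bond", "lennard_jones")) {
        ga <- factor_gradient(f, s, f$atoms[1], ewald = ew)
        gb <- factor_gradient(f, s, f$atoms[2], ewald = ew)
        expect_equal(ga, -gb, tolerance = 1e-10)
      } else if (f$kind == "bend") {
        gsum <- Reduce(`+`, lapply(f$atoms, factor_gradient, factor = f,
                                   system = s, ewald = ew))
        expect_equal(gsum, c(0, 0, 0), tolerance = 1e-10)
      }
    }
  }
})

test_that("factor constructors enforce their contracts", {
  sys <- random_system(2, 12, seed = 1)
  expect_error(ecmc_factor("bond", 1:3), "2 atom")
  expect_error(factor_gradient(factor_list(sys)[[1]], sys, atom = 6),
               "does not contribute")
  expect_error(check_factor(ecmc_factor("lennard_jones", c(2, 4)), sys),
               "oxygen")
  expect_error(check_factor(ecmc_factor("bond", c(1, 4)), sys),
               "one molecule")
})

test_that("Ewald energy is splitting-independent and gradients are exact", {
  s <- random_system(2, 12, seed = 21)
  e <- lapply(c(0.8, 1, 1.2), function(f)
    ewald_settings(s$box_side, splitting_length = f * s$box_side / 4))
  en <- vapply(e, function(ew)
    ewald_pair_interaction(s, 1, 2, ew, gradients = FALSE)$energy, 0)
  expect_lt(max(abs(en - en[2])), 1e-9)
  expect_lt(e[[2]]$achieved_relative_precision, 1e-12)

  # gradient vs central finite differences of the pair energy
  ew <- e[[2]]
  res <- ewald_pair_interaction(s, 1, 2, ew)
  h <- 1e-6
  for (atom in c(1, 2, 4)) {
    num <- vapply(1:3, function(k) {
      sp <- s; sp$positions[atom, k] <- sp$positions[atom, k] + h
      sm <- s; sm$positions[atom, k] <- sm$positions[atom, k] - h
      (ewald_pair_interaction(sp, 1, 2, ew, gradients = FALSE)$energy -
         ewald_pair_interaction(sm, 1, 2, ew, gradients = FALSE)$energy) / (2 * h)
    }, numeric(1))
    g <- if (atom <= 3) res$grad_i[atom, ] else res$grad_j[atom - 3, ]
    expect_equal(g, num, tolerance = 1e-6)
  }
})

test_that("Ewald pair interaction respects inversion symmetry", {
  # two molecules related by inversion through the box centre: the gradient
  # sets map onto each other under the same inversion
  L <- 16
  geom <- spcfw_equilibrium_geometry()
  a <- geom + matrix(c(4, 5, 6), 3, 3, byrow = TRUE)
  b <- -sweep(a, 2, c(L, L, L))  # inversion through (L/2, L/2, L/2)
  s <- water_system(rbind(a, b), L)
  res <- ewald_pair_interaction(s, 1, 2)
  expect_equal(res$grad_i, -res$grad_j, tolerance = 1e-9)
})

test_that("non-neutral molecules are rejected by the Ewald front end", {
  s <- random_system(2, 12, seed = 2)
  s$charge[1] <- -0.5
  expect_error(ewald_pair_interaction(s, 1, 2), "neutral")
})
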
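# shared fixtures and oracles, all built in code

kB <- 0.0019872041
beta300 <- 1 / (kB * 300)

# one molecule at equilibrium geometry, shifted into the box
one_molecule <- function(box_side = 20, shift = c(5, 5, 5),
                         params = spcfw_parameters()) {
  water_system(spcfw_equilibrium_geometry(params) +
                 matrix(shift, 3, 3, byrow = TRUE), box_side, params)
}

# n molecules on a jittered lattice with random orientations (no overlap
# removal: intended for derivative checks, not for sampling)
random_system <- function(n, box_side, seed = NULL, jitter = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  geom <- spcfw_equilibrium_geometry()
  nside <- ceiling(n^(1 / 3))
  spacing <- box_side / nside
  sites <- as.matrix(expand.grid(1:nside, 1:nside, 1:nside))[1:n, , drop = FALSE]
  pos <- matrix(0, 3 * n, 3)
  for (m in 1:n) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    origin <- (sites[m, ] - 0.5) * spacing + runif(3, -jitter, jitter)
    pos[3 * (m - 1) + 1:3, ] <- geom %*% t(R) +
      matrix(origin, 3, 3, byrow = TRUE)
  }
  water_system(pos, box_side)
}

# central finite difference of a factor potential wrt one atom
fd_gradient <- function(factor, system, atom, h = 1e-6, ewald = NULL) {
  vapply(1:3, function(k) {
    sp <- system; sp$positions[atom, k] <- sp$positions[atom, k] + h
    sm <- system; sm$positions[atom, k] <- sm$positions[atom, k] - h
    (factor_potential(factor, sp, ewald = ewald) -
       factor_potential(factor, sm, ewald = ewald)) / (2 * h)
  }, numeric(1))
}

# closed-form stationary marginals of the internal coordinates
bond_marginal_cdf <- function(params = spcfw_parameters(), beta = beta300) {
  r <- seq(0.85, 1.2, 5e-5)
  d <- r^2 * exp(-beta * params$bond_stiffness *
                   (r - params$bond_equilibrium_length)^2 / 2)
  cdf <- cumsum(d) / sum(d)
  function(q) approx(r, cdf, q, rule = 2)$y
}

bend_marginal_cdf <- function(params = spcfw_parameters(), beta = beta300) {
  th <- seq(1.4, 2.6, 5e-5)
  d <- sin(th) * exp(-beta * params$bend_stiffness *
                       (th - params$bend_equilibrium_angle)^2 / 2)
  cdf <- cumsum(d) / sum(d)
  function(q) approx(th, cdf, q, rule = 2)$y
}

# radial Boltzmann law of an isolated harmonic dimer
dimer_marginal_cdf <- function(k, r0, beta = beta300) {
  r <- seq(max(r0 - 8 / sqrt(beta * k), 1e-3), r0 + 8 / sqrt(beta * k), 5e-5)
  d <- r^2 * exp(-beta * k * (r - r0)^2 / 2)
  cdf <- cumsum(d) / sum(d)
  function(q) approx(r, cdf, q, rule = 2)$y
}

# R-surface mini engine: event-chain sampling over an explicit factor list,
# built from the exported solver and lifting operations. Used to validate
# the solvers independently of the compiled engine.
mini_ecmc <- function(system, factors, duration, sampling_interval,
                      beta = beta300, tau_chain = 5, variant = "newtonian",
                      slice_length = 0.1, safety_factor = 1.2) {
  lift <- lifted_state(system)
  t <- 0
  next_samp <- sampling_interval
  next_res <- tau_chain
  configs <- list()
  n_events <- 0
  while (t < duration) {
    i <- lift$active_atom
    v <- lift$velocity[i, ]
    horizon <- min(next_samp, next_res) - t
    best <- horizon; bestf <- 0; bestb <- NA
    for (fi in seq_along(factors)) {
      f <- factors[[fi]]
      if (!(i %in% f$atoms)) next
      if (f$kind == "bond") {
        tc <- bond_event_time(f, system, lift, rexp(1), beta, horizon = best)
        if (tc < best) { best <- tc; bestf <- fi; bestb <- NA }
      } else {
        rate_fn <- function(tt) {
          s2 <- system
          s2$positions[i, ] <- s2$positions[i, ] + v * tt
          factor_event_rate(f, s2, i, v, beta)
        }
        bc <- bounded_event_time(rate_fn, slice_length / sqrt(sum(v^2)),
                                 safety_factor, rexp(1), horizon = best)
        if (bc$time < best) { best <- bc$time; bestf <- fi; bestb <- bc$bound }
      }
    }
    system$positions[i, ] <- system$positions[i, ] + v * best
    t <- t + best
    lift$system <- system
    if (bestf == 0) {
      if (next_samp <= next_res) {
        configs[[length(configs) + 1L]] <- system$positions
        next_samp <- next_samp + sampling_interval
      } else {
        lift <- resample_lifting(lift)
        next_res <- next_res + tau_chain
      }
      next
    }
    f <- factors[[bestf]]
    confirmed <- TRUE
    if (!is.na(bestb)) {
      confirmed <- confirm_event(factor_event_rate(f, system, i, v, beta),
                                 bestb)
    }
    if (confirmed) {
      n_events <- n_events + 1
      if (variant == "straight") {
        nxt <- straight_lift(f, system, lift)
        lift$velocity[nxt, ] <- lift$velocity[i, ]
        if (nxt != i) lift$velocity[i, ] <- 0
        lift$active_atom <- nxt
      } else if (length(f$atoms) == 2) {
        res <- lift_pair(f, system, lift)
        lift$velocity <- res$velocity
        lift$active_atom <- res$next_active
      } else {
        res <- lift_general(f, system, lift)
        lift$velocity <- res$velocity
        lift$active_atom <- res$next_active
      }
    }
  }
  list(configs = configs, n_events = n_events)
}
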
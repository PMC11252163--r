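#' Fibonacci-sphere velocity discretization
#'
#' Maps a generalized Fibonacci lattice onto the unit sphere by the Lambert
#' cylindrical equal-area projection: azimuths advance by the golden angle
#' `2 pi d / phi` with `phi = (1 + sqrt(5))/2`, and the polar angles are
#' `arccos(1 - 2 (d + eps) / (D - 1 + 2 eps))` for `d = 0, ..., D-1`. The
#' resulting near-uniform direction set discretizes the continuous velocity
#' space of the Newtonian variant for cell-bound precomputation.
#'
#' @param D number of vectors (default 10).
#' @param eps offset parameter in (0, 1); the default 0.36 is the empirical
#'   choice that spreads nearest-neighbor distances well.
#' @return object of class `fibonacci_sphere`: a `D x 3` matrix of unit
#'   vectors with attributes `azimuth`, `polar`, `D`, `eps`.
#' @export
fibonacci_sphere <- function(D = 10, eps = 0.36) {
  if (!(D >= 1)) stop("D must be at least 1")
  if (!(eps > 0 && eps < 1)) stop("eps must lie in (0, 1)")
  d <- seq_len(D) - 1
  golden <- (1 + sqrt(5)) / 2
  phi_d <- 2 * pi * d / golden
  theta_d <- acos(1 - 2 * (d + eps) / (D - 1 + 2 * eps))
  v <- cbind(cos(phi_d) * sin(theta_d), sin(phi_d) * sin(theta_d),
             cos(theta_d))
  structure(v, azimuth = phi_d, polar = theta_d, D = D, eps = eps,
            class = c("fibonacci_sphere", "matrix", "array"))
}

#' Nearest Fibonacci vector under the cosine distance
#'
#' Brute-force scan (D is small): the index whose unit vector has the
#' largest normalized dot product with the query velocity. Invariant under
#' positive rescaling of the velocity.
#'
#' @param velocity nonzero 3-vector.
#' @param sphere a [fibonacci_sphere()].
#' @return index in `1..D`.
#' @export
nearest_fibonacci <- function(velocity, sphere) {
  n <- sqrt(sum(velocity^2))
  if (n == 0) stop("zero velocity has no direction")
  which.max(as.matrix(sphere) %*% (velocity / n))
}

# covering radius of the direction set: max over the sphere of the angle to
# the nearest Fibonacci vector, estimated on a dense deterministic probe set
# and inflated; used to extend cell bounds from a vector to its whole
# Voronoi cell (a cap of this half-angle contains every Voronoi cell)
fibonacci_covering_angle <- function(sphere, n_probe = 20000) {
  probe <- fibonacci_sphere(n_probe, eps = 0.5)
  dots <- as.matrix(probe) %*% t(as.matrix(sphere))
  dots[dots > 1] <- 1
  delta <- max(acos(apply(dots, 1, max)))
  min(delta * 1.10 + 0.02, pi)
}

#' Cell grid with occupancy tracking
#'
#' Cubic grid of cells used by the cell-veto algorithm. The tuner picks the
#' largest cells (fewest per edge) whose expected occupancy stays below one
#' while still leaving room outside the excluded layers; tracked points
#' (molecular barycenters for Coulomb, oxygens for Lennard-Jones) register
#' in exactly one cell, overflow beyond one occupant per cell goes to the
#' surplus list.
#'
#' @param system a [water_system()] (or `NULL` when `n_molecules` and
#'   `box_side` are given).
#' @param excluded_layers depth of the excluded near-field layers (>= 1,
#'   default 2).
#' @param kind `"coulomb"` (barycenters) or `"lennard_jones"` (oxygens).
#' @param n_cells override the tuned number of cells per edge.
#' @return object of class `cell_grid`.
#' @export
cell_grid <- function(system, excluded_layers = 2, kind = "coulomb",
                      n_cells = NULL) {
  kind <- match.arg(kind, c("coulomb", "lennard_jones"))
  N <- system$n_molecules
  L <- system$box_side
  if (is.null(n_cells))
    n_cells <- max(2L * excluded_layers + 2L, ceiling((N / 0.55)^(1 / 3)))
  g <- structure(list(
    n_cells = as.integer(n_cells),
    cell_side = L / n_cells,
    box_side = L,
    excluded_layers = as.integer(excluded_layers),
    occupant = rep(NA_integer_, n_cells^3),
    cell_of = rep(NA_integer_, N),
    surplus = integer(0),
    kind = kind
  ), class = "cell_grid")
  pts <- tracked_points(system, kind)
  for (m in seq_len(N)) g <- grid_insert(g, m, bin_point(g, pts[m, ]))
  g
}

tracked_points <- function(system, kind) {
  if (kind == "coulomb") molecule_barycenters(system)
  else system$positions[seq(1, 3 * system$n_molecules, 3), , drop = FALSE]
}

bin_point <- function(grid, p) {
  L <- grid$box_side
  ix <- pmin(pmax(floor((p %% L) / grid$cell_side), 0), grid$n_cells - 1)
  as.integer((ix[3] * grid$n_cells + ix[2]) * grid$n_cells + ix[1] + 1)
}

grid_insert <- function(grid, m, cell) {
  if (is.na(grid$occupant[cell])) {
    grid$occupant[cell] <- m
    grid$cell_of[m] <- cell
  } else {
    grid$surplus <- c(grid$surplus, m)
    grid$cell_of[m] <- NA_integer_
  }
  grid
}

#' Re-bin a tracked point after its molecule moved
#'
#' Removes the molecule from its cell (or the surplus list), inserts it at
#' its new position, and promotes a surplus molecule into any vacated cell
#' it occupies. Surplus molecules contribute no Walker-table events; their
#' factors are served by the direct bounded solver.
#'
#' @param grid a [cell_grid()].
#' @param system the (moved) [water_system()].
#' @param molecule molecule index to re-bin.
#' @return the updated grid.
#' @export
update_occupancy <- function(grid, system, molecule) {
  pts <- tracked_points(system, grid$kind)
  cnew <- bin_point(grid, pts[molecule, ])
  cold <- grid$cell_of[molecule]
  if (!is.na(cold) && cold == cnew) return(grid)
  if (!is.na(cold)) grid$occupant[cold] <- NA_integer_
  else grid$surplus <- setdiff(grid$surplus, molecule)
  grid <- grid_insert(grid, molecule, cnew)
  if (!is.na(cold) && is.na(grid$occupant[cold])) {
    for (s in grid$surplus) {
      if (bin_point(grid, pts[s, ]) == cold) {
        grid$surplus <- setdiff(grid$surplus, s)
        grid$occupant[cold] <- s
        grid$cell_of[s] <- cold
        break
      }
    }
  }
  grid
}

# minimum-image relative cell offsets outside the excluded layers
grid_offsets <- function(n_cells, excluded_layers) {
  half <- floor(n_cells / 2)
  vals <- ((seq_len(n_cells) - 1 + half) %% n_cells) - half
  off <- as.matrix(expand.grid(x = vals, y = vals, z = vals))
  keep <- apply(abs(off), 1, max) > excluded_layers
  unname(off[keep, , drop = FALSE])
}

#' Precomputed cell bound for one relative cell offset
#'
#' The factor event rate is maximized over position grids in the active and
#' target cells with the velocity direction allowed to range over a cap
#' covering the Voronoi cell of the given Fibonacci vector, then multiplied
#' by an empirical prefactor. Coulomb bounds vary a point charge against a
#' molecular dipole distribution (first-moment bound with the dipole
#' aligned along the worst-case field gradient, padded cells, and a
#' residual-field constant covering all periodic-image and screening
#' corrections); Lennard-Jones bounds vary the two oxygens directly.
#' Bounds are stored for unit speed and unit charge and rescaled at use
#' time.
#'
#' @param kind `"coulomb"` or `"lennard_jones"`.
#' @param offset integer 3-vector of cell offsets (outside the excluded
#'   layers).
#' @param fib_index index into the Fibonacci sphere.
#' @param grid a [cell_grid()].
#' @param system a [water_system()].
#' @param sphere a [fibonacci_sphere()].
#' @param beta inverse temperature.
#' @param prefactor empirical safety prefactor (default 2).
#' @param grid_n positions per cell axis in the maximization (default 5).
#' @return bound rate (per unit Monte Carlo time, unit speed and charge).
#' @export
estimate_cell_bound <- function(kind, offset, fib_index, grid, system, sphere,
                                beta, prefactor = 2, grid_n = 5) {
  kind <- match.arg(kind, c("coulomb", "lennard_jones"))
  if (max(abs(offset)) <= grid$excluded_layers)
    stop("offset lies inside the excluded layers")
  b <- cell_bounds_matrix(system, grid, sphere, beta,
                          offsets = matrix(as.integer(offset), 1, 3),
                          prefactor = prefactor, grid_n = grid_n)
  if (kind == "coulomb") b$bounds_coulomb[1, fib_index]
  else b$bounds_lj[1, fib_index]
}

cell_bounds_matrix <- function(system, grid, sphere, beta, offsets,
                               prefactor = 2, grid_n = 5, pad = 1.3) {
  ew <- ewald_settings(system$box_side)
  rest <- ewald_rest_constants(system$box_side, ew)
  # neutrality-aware first-moment constant: the field of a neutral molecule
  # whose sites lie within the padded cell is bounded by
  # M1 * max_ball |Hess psi_E|, with the bare Hessian direction factor
  # sqrt(1 + 3 cos^2) evaluated on the position grid
  m1 <- spcfw_m1_moment(system$params)
  delta <- fibonacci_covering_angle(sphere)
  .estimate_cell_bounds_cpp(offsets, as.matrix(sphere), system$box_side,
                            grid$n_cells, pad, grid_n, beta,
                            unclass(system$params), m1, delta,
                            0, rest$hess_rest, prefactor)
}

#' Walker alias table
#'
#' Standard alias construction over nonnegative bounds: sampling an entry
#' proportional to its bound takes constant time regardless of the number
#' of entries.
#'
#' @param bounds nonnegative weights, at least one positive.
#' @return object of class `walker_table` with `cut`, `alias` and the
#'   `total` bounded rate Q.
#' @export
build_walker_table <- function(bounds) {
  if (any(bounds < 0)) stop("bounds must be nonnegative")
  total <- sum(bounds)
  if (total <= 0) stop("all bounds are zero")
  n <- length(bounds)
  scaled <- bounds / total * n
  cut <- scaled
  alias <- seq_len(n)
  small <- which(scaled < 1)
  large <- which(scaled >= 1)
  while (length(small) && length(large)) {
    s <- small[1]; small <- small[-1]
    l <- large[1]
    alias[s] <- l
    scaled[l] <- scaled[l] - (1 - cut[s])
    if (scaled[l] < 1) {
      cut[l] <- scaled[l]
      large <- large[-1]
      small <- c(small, l)
    } else cut[l] <- 1
  }
  cut[c(small, large)] <- 1
  structure(list(cut = pmin(cut, 1), alias = alias, total = total,
                 n = n, bounds = bounds), class = "walker_table")
}

#' Constant-time draw from a Walker table
#' @param table a [build_walker_table()] result.
#' @param n number of draws.
#' @return integer indices sampled proportionally to the bounds.
#' @export
walker_sample <- function(table, n = 1) {
  i <- sample.int(table$n, n, replace = TRUE)
  u <- runif(n)
  ifelse(u < table$cut[i], i, table$alias[i])
}

#' Bundled candidate event from the cell-veto tables
#'
#' One exponential waiting time with the total bounded rate Q (rescaled to
#' the actual speed and charge of the active atom) covers the entire set of
#' bundled far-field factors; a single alias draw then selects the target
#' cell.
#'
#' @param lifted a [lifted_state()].
#' @param table a [build_walker_table()] over the cell bounds for the
#'   active atom's Fibonacci direction.
#' @param offsets matrix of the relative cell offsets indexed by the table.
#' @param charge absolute charge of the active atom (1 for Lennard-Jones
#'   bundling).
#' @return list with `candidate_time` (waiting time), `entry` (table row)
#'   and `offset` (the sampled relative cell offset).
#' @export
cell_veto_candidate <- function(lifted, table, offsets, charge = 1) {
  s <- sqrt(sum(lifted$velocity[lifted$active_atom, ]^2))
  rate <- table$total * s * abs(charge)
  entry <- walker_sample(table, 1)
  list(candidate_time = rexp(1) / rate, entry = entry,
       offset = offsets[entry, ], rate = rate)
}

#' Thinning confirmation of a cell-veto candidate
#'
#' Computes the actual factor event rate with the actual atom positions and
#' the actual velocity of the moving atom (Coulomb factors through the
#' machine-precision Ewald summation) and confirms against the sampled cell
#' bound.
#'
#' @param system a [water_system()].
#' @param lifted a [lifted_state()].
#' @param target_molecule molecule resolved from the occupancy map.
#' @param bound the sampled cell bound, already rescaled to actual speed
#'   and charge.
#' @param kind `"coulomb"` or `"lennard_jones"`.
#' @param beta inverse temperature.
#' @param ewald settings for the Coulomb rate.
#' @param strict abort on bound violation?
#' @return logical: event confirmed?
#' @export
confirm_cell_event <- function(system, lifted, target_molecule, bound,
                               kind = "coulomb", beta, ewald = NULL,
                               strict = TRUE) {
  i <- lifted$active_atom
  mi <- system$molecule_of[i]
  fac <- if (kind == "coulomb") {
    ecmc_factor("coulomb_molecular",
                c(molecule_atoms(mi), molecule_atoms(target_molecule)))
  } else {
    ecmc_factor("lennard_jones",
                c(molecule_atoms(mi)[1], molecule_atoms(target_molecule)[1]))
  }
  rate <- factor_event_rate(fac, system, i, lifted$velocity[i, ], beta,
                            ewald = ewald)
  confirm_event(rate, bound, strict = strict)
}

# full cell-veto table set for the compiled engine, memoized on the
# geometry/parameter signature
build_cell_veto_tables <- function(system, beta, excluded_layers = 2,
                                   D = 10, eps = 0.36, prefactor = 2,
                                   grid_n = 5) {
  key <- sprintf("%.10g|%d|%.10g|%d|%d|%.3g|%.3g|%d",
                 system$box_side, system$n_molecules, beta, excluded_layers,
                 D, eps, prefactor, grid_n)
  hit <- .waterecmc_cache$tables[[key]]
  if (!is.null(hit)) return(hit)
  grid <- cell_grid(system, excluded_layers, kind = "coulomb")
  offsets <- grid_offsets(grid$n_cells, excluded_layers)
  if (nrow(offsets) == 0) return(NULL)
  sphere <- fibonacci_sphere(D, eps)
  b <- cell_bounds_matrix(system, grid, sphere, beta, offsets,
                          prefactor = prefactor, grid_n = grid_n)
  mk <- function(bm) {
    cut <- matrix(0, nrow(offsets), D)
    ali <- matrix(0L, nrow(offsets), D)
    for (d in seq_len(D)) {
      wt <- build_walker_table(bm[, d])
      cut[, d] <- wt$cut
      ali[, d] <- wt$alias - 1L  # zero-based for the engine
    }
    list(cut = cut, alias = ali)
  }
  wc <- mk(b$bounds_coulomb)
  wl <- mk(b$bounds_lj)
  out <- list(
    n_cells = grid$n_cells, excluded_layers = as.integer(excluded_layers),
    offsets = offsets, fib_vectors = unclass(as.matrix(sphere)),
    bounds_coulomb = b$bounds_coulomb, bounds_lj = b$bounds_lj,
    alias_cut_coulomb = wc$cut, alias_index_coulomb = wc$alias,
    alias_cut_lj = wl$cut, alias_index_lj = wl$alias
  )
  .waterecmc_cache$tables[[key]] <- out
  out
}
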
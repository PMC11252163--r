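#' Lifted state of the piecewise-deterministic Markov process
#'
#' The lifting variables that extend the physical configuration: an
#' all-atom velocity (mere labels except for the active atom), the active
#' atom, and a diagonal mass matrix with conserved kinetic energy
#' `v^T M v = 2 E_kin`. By default all masses are equal (identity matrix)
#' and `E_kin` is fixed so that the expected active-atom speed is about one
#' -- a pure convention, since the velocity has no kinematic meaning.
#'
#' @param system a [water_system()].
#' @param mass per-atom masses (diagonal mass matrix); default all ones.
#' @param kinetic_energy conserved `E_kin`; default `3 N_a pi / 16`, which
#'   for identity masses makes the mean atom speed about 1.
#' @param velocity optional `N_a x 3` matrix; drawn by [resample_lifting()]
#'   when `NULL`.
#' @param active_atom optional index; drawn uniformly when `NULL`.
#' @return object of class `lifted_state`.
#' @export
lifted_state <- function(system, mass = NULL, kinetic_energy = NULL,
                         velocity = NULL, active_atom = NULL) {
  na <- 3 * system$n_molecules
  if (is.null(mass)) mass <- rep(1, na)
  stopifnot(length(mass) == na, all(mass > 0))
  if (is.null(kinetic_energy)) kinetic_energy <- 3 * na * pi / 16
  st <- structure(list(
    system = system,
    velocity = velocity,
    active_atom = active_atom,
    mass = mass,
    kinetic_energy = kinetic_energy,
    clock = 0
  ), class = "lifted_state")
  if (is.null(velocity) || is.null(active_atom)) st <- resample_lifting(st)
  st
}

#' Resample the lifting variables from their stationary laws
#'
#' The all-atom velocity is drawn from a multivariate Gaussian with
#' covariance `M^-1`, then corrected so the componentwise velocity sum is
#' zero and rescaled onto the kinetic-energy shell `v^T M v = 2 E_kin`.
#' The active atom is drawn uniformly.
#'
#' @param lifted a [lifted_state()].
#' @return the updated state.
#' @export
resample_lifting <- function(lifted) {
  na <- length(lifted$mass)
  repeat {
    v <- matrix(rnorm(3 * na), na, 3) / sqrt(lifted$mass)
    v <- sweep(v, 2, colMeans(v))
    vmv <- sum(lifted$mass * rowSums(v^2))
    if (vmv > 0) break
  }
  lifted$velocity <- v * sqrt(2 * lifted$kinetic_energy / vmv)
  lifted$active_atom <- sample.int(na, 1)
  lifted
}

#' Factor event rate of the active atom
#'
#' The instantaneous hazard `beta * max(0, grad_i U_M . v_i)` for the factor
#' to interrupt the straight-line motion of the active atom; zero when the
#' active atom does not contribute to the factor.
#'
#' @param factor an [ecmc_factor()].
#' @param system a [water_system()].
#' @param active active atom index.
#' @param velocity_of_active its velocity (3-vector).
#' @param beta inverse temperature (mol/kcal).
#' @param ewald settings for Coulomb factors.
#' @return nonnegative rate per unit Monte Carlo time.
#' @export
factor_event_rate <- function(factor, system, active, velocity_of_active,
                              beta, ewald = NULL) {
  if (!(active %in% factor$atoms)) return(0)
  g <- factor_gradient(factor, system, active, ewald = ewald)
  beta * max(0, sum(g * velocity_of_active))
}

#' Newtonian force kick
#'
#' Reflects the all-atom velocity in the gradient of the event-factor
#' potential, for a general diagonal mass matrix. The kick conserves
#' `v^T M v`, is an involution, and only changes the velocities of atoms on
#' which the gradient is nonzero.
#'
#' @param velocity `N_a x 3` all-atom velocity.
#' @param grad_U `N_a x 3` gradient of the event-factor potential (zero rows
#'   for non-contributing atoms).
#' @param mass per-atom masses (diagonal mass matrix), default identity.
#' @return the kicked velocity matrix.
#' @export
newtonian_kick <- function(velocity, grad_U, mass = rep(1, nrow(velocity))) {
  gg <- sum(grad_U^2 / mass)
  if (gg == 0) stop("zero gradient: kick direction undefined")
  phi <- 2 * sum(velocity * grad_U) / gg
  velocity - phi * grad_U / mass
}

#' Newtonian-general lifting at a confirmed event
#'
#' Samples the next active atom and whether the force kick is applied, with
#' probability proportional to `max(0, -grad_k U_M . v'_k)` for the kicked
#' outcome and `max(0, -grad_k U_M . v_k)` for the unkicked one, over the
#' contributing atoms k. A single-atom factor always kicks; an unkicked
#' outcome always changes the active atom.
#'
#' @inheritParams factor_event_rate
#' @param lifted a [lifted_state()], positioned at the confirmed event.
#' @return list with `next_active` and `velocity`.
#' @export
lift_general <- function(factor, system, lifted, ewald = NULL) {
  atoms <- factor$atoms
  na <- nrow(lifted$velocity)
  g <- matrix(0, na, 3)
  for (a in atoms) g[a, ] <- factor_gradient(factor, system, a, ewald = ewald)
  vk <- newtonian_kick(lifted$velocity, g, lifted$mass)
  w_kick <- vapply(atoms, function(a) max(0, -sum(g[a, ] * vk[a, ])), 0)
  w_keep <- vapply(atoms, function(a) max(0, -sum(g[a, ] * lifted$velocity[a, ])), 0)
  C <- sum(w_kick) + sum(w_keep)
  if (C <= 0) stop("all lifting outcome weights vanish at a confirmed event")
  pick <- sample.int(2 * length(atoms), 1, prob = c(w_kick, w_keep))
  if (pick <= length(atoms)) {
    list(next_active = atoms[pick], velocity = vk)
  } else {
    list(next_active = atoms[pick - length(atoms)], velocity = lifted$velocity)
  }
}

#' Newtonian-pair lifting for distance-dependent pair factors
#'
#' Deterministic scheme for two-atom factors with identity masses: the
#' force kick is always applied to both atoms (an equal-mass elastic
#' collision along the gradient) and the activity always transfers to the
#' other atom of the pair.
#'
#' @inheritParams lift_general
#' @return list with `next_active` and `velocity`.
#' @export
lift_pair <- function(factor, system, lifted, ewald = NULL) {
  if (length(factor$atoms) != 2)
    stop("pair scheme requires a two-atom factor")
  if (any(lifted$mass != lifted$mass[1]))
    stop("pair scheme requires an identity mass matrix")
  a <- factor$atoms[1]; b <- factor$atoms[2]
  na <- nrow(lifted$velocity)
  g <- matrix(0, na, 3)
  g[a, ] <- factor_gradient(factor, system, a, ewald = ewald)
  g[b, ] <- -g[a, ]
  v <- newtonian_kick(lifted$velocity, g, lifted$mass)
  nxt <- if (lifted$active_atom == a) b else a
  list(next_active = nxt, velocity = v)
}

#' Ratio lifting of the straight variant
#'
#' The velocity vector is transferred unchanged; the next active atom is
#' sampled among the contributing atoms with probability proportional to
#' `max(0, -grad_k U_M . v)`. For pair factors the transfer is
#' deterministic.
#'
#' @inheritParams lift_general
#' @return index of the next active atom.
#' @export
straight_lift <- function(factor, system, lifted, ewald = NULL) {
  atoms <- factor$atoms
  v <- lifted$velocity[lifted$active_atom, ]
  if (length(atoms) == 2)
    return(setdiff(atoms, lifted$active_atom))
  w <- vapply(atoms, function(a)
    max(0, -sum(factor_gradient(factor, system, a, ewald = ewald) * v)), 0)
  if (sum(w) <= 0) stop("all ratio-lifting weights vanish at a confirmed event")
  atoms[sample.int(length(atoms), 1, prob = w)]
}
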
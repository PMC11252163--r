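#' One reversible Metropolis trial
#'
#' Proposes a new position for a single uniformly chosen atom inside a cube
#' of per-species half-width and accepts with the Metropolis criterion
#' `min(1, exp(-beta dU))`. The energy difference is computed from the
#' affected factors only, which by the factor partition equals the
#' total-potential difference exactly.
#'
#' @param system a [water_system()].
#' @param halfwidths named numeric vector `c(H = ..., O = ...)` of proposal
#'   cube half-widths in Angstrom.
#' @param beta inverse temperature (mol/kcal).
#' @param ewald settings for Coulomb factors.
#' @return list with the (possibly updated) `system`, `accepted`, the moved
#'   `atom` and its `species`.
#' @export
metropolis_step <- function(system, halfwidths, beta, ewald = NULL) {
  stopifnot(all(halfwidths > 0), all(c("H", "O") %in% names(halfwidths)))
  if (is.null(ewald) && system$n_molecules >= 2)
    ewald <- ewald_settings(system$box_side)
  na <- 3 * system$n_molecules
  i <- sample.int(na, 1)
  species <- system$element[i]
  delta <- halfwidths[[species]]
  m <- system$molecule_of[i]

  affected <- Filter(function(f) i %in% f$atoms, factor_list(system))
  e0 <- sum(vapply(affected, factor_potential, numeric(1),
                   system = system, ewald = ewald))
  trial <- system
  trial$positions[i, ] <- system$positions[i, ] + runif(3, -delta, delta)
  e1 <- sum(vapply(affected, factor_potential, numeric(1),
                   system = trial, ewald = ewald))
  dU <- e1 - e0
  accepted <- dU <= 0 || runif(1) < exp(-beta * dU)
  list(system = if (accepted) trial else system, accepted = accepted,
       atom = i, species = species, delta_U = dU)
}

#' Adapt the proposal half-widths toward a target acceptance rate
#'
#' Multiplicative update `delta <- delta * (measured / target)^exponent`,
#' applied independently per species during a dedicated burn-in phase; the
#' half-widths are frozen afterwards so the production chain is strictly
#' reversible.
#'
#' @param halfwidths named vector `c(H = , O = )`.
#' @param acceptance named vector of measured per-species acceptance rates.
#' @param target target acceptance rate (default 0.37).
#' @param exponent update exponent (default 0.5).
#' @return updated half-widths.
#' @export
adapt_proposal <- function(halfwidths, acceptance, target = 0.37,
                           exponent = 0.5) {
  for (sp in names(acceptance)) {
    halfwidths[[sp]] <- halfwidths[[sp]] *
      (max(acceptance[[sp]], 0.02) / target)^exponent
  }
  halfwidths
}

#' Production Metropolis run (compiled)
#'
#' Runs the single-atom Metropolis sampler with per-species proposal-cube
#' adaptation during burn-in, frozen half-widths in production, and
#' polarization sampling. This is the reversible reference against which
#' the event-chain variants are cross-validated.
#'
#' @param system a [water_system()].
#' @param temperature temperature in K.
#' @param n_production production trials (measured acceptance, sampling).
#' @param n_adapt_batches,batch_size adaptation schedule: the half-widths
#'   are updated after every batch during burn-in only.
#' @param target_acceptance target acceptance rate (default 0.37).
#' @param halfwidths initial `c(H = , O = )` half-widths.
#' @param sample_every record the polarization every this many production
#'   trials (0 disables sampling).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param adapt run the adaptation phase?
#' @return object of class `metropolis_run` with the final system,
#'   acceptance rates, frozen half-widths, adaptation history and the
#'   polarization series.
#' @export
run_metropolis <- function(system, temperature = 300, n_production = 1e5,
                           n_adapt_batches = 25, batch_size = 1000,
                           target_acceptance = 0.37,
                           halfwidths = c(H = 0.2, O = 0.2),
                           sample_every = 10, seed = NULL, adapt = TRUE) {
  validate_water_system(system)
  if (!is.null(seed)) set.seed(seed)
  beta <- 1 / (.kB * temperature)
  # full-system Ewald: short-ranged real space (minimum image only), the
  # reciprocal part through incremental structure factors. Truncations are
  # chosen so the residual is orders of magnitude below kT; the
  # machine-precision per-pair summation of the ECMC engine is unaffected.
  L <- system$box_side
  alpha <- 8 / L
  kmax <- 12L
  res <- .run_metropolis_cpp(
    t(system$positions), system$charge, L, beta, unclass(system$params),
    list(alpha = alpha, kmax = kmax, nreal = 0L),
    list(delta_H = halfwidths[["H"]], delta_O = halfwidths[["O"]],
         adapt = adapt, n_adapt_batches = as.integer(n_adapt_batches),
         batch_size = as.integer(batch_size),
         target_acceptance = target_acceptance,
         n_production = as.double(n_production),
         sample_every = as.integer(sample_every)))
  final <- system
  final$positions <- t(res$final_positions)
  structure(list(
    final_system = final,
    acceptance = res$acceptance,
    acceptance_H = res$acceptance_H,
    acceptance_O = res$acceptance_O,
    halfwidths = c(H = res$delta_H, O = res$delta_O),
    history = list(delta_H = res$delta_H_history,
                   delta_O = res$delta_O_history,
                   acceptance_H = res$acceptance_H_history,
                   acceptance_O = res$acceptance_O_history),
    stamps = res$stamps,
    polarization = res$polarization,
    series = if (length(res$stamps))
      polarization_series(res$stamps, res$polarization,
                          sampler = "metropolis") else NULL
  ), class = "metropolis_run")
}

#' @export
print.metropolis_run <- function(x, ...) {
  cat(sprintf(
    "metropolis_run: acceptance %.3f (H %.3f, O %.3f), halfwidths H %.3f A, O %.3f A\n",
    x$acceptance, x$acceptance_H, x$acceptance_O,
    x$halfwidths[["H"]], x$halfwidths[["O"]]))
  invisible(x)
}
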
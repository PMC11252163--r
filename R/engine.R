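#' Simulation parameters for the event-chain sampler
#'
#' Collects the run conditions of the piecewise-deterministic Markov
#' process. The chain time between full resamplings of the lifting
#' variables defaults to `0.2 N` for the straight variant and `10000 N`
#' for the Newtonian variant (resampling is only needed for
#' irreducibility, and the Newtonian variant rotates dipoles best with
#' rare resampling).
#'
#' @param temperature temperature in K.
#' @param variant `"newtonian"` or `"straight"`.
#' @param tau_chain chain time in Monte Carlo time units; `NULL` picks the
#'   variant default at run time.
#' @param sampling_interval spacing of configuration samples (Monte Carlo
#'   time).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param cell_veto `"auto"`, `"on"` or `"off"`. `"auto"` enables the
#'   cell-veto bundling when the box supports a grid with non-excluded
#'   cells.
#' @param excluded_layers excluded near-field layer depth (cells).
#' @param slice_length travel distance per bounding slice (A).
#' @param safety_factor safety multiplier of evaluation-based slice bounds.
#' @param cell_veto_prefactor empirical prefactor of the cell bounds.
#' @param strict abort on any bounding-rate violation (exactness guard)?
#' @return object of class `simulation_parameters`.
#' @export
simulation_parameters <- function(temperature = 300,
                                  variant = c("newtonian", "straight"),
                                  tau_chain = NULL,
                                  sampling_interval = 1,
                                  seed = NULL,
                                  cell_veto = c("auto", "on", "off"),
                                  excluded_layers = 2,
                                  slice_length = 0.1,
                                  safety_factor = 1.2,
                                  cell_veto_prefactor = 2,
                                  strict = TRUE) {
  variant <- match.arg(variant)
  cell_veto <- match.arg(cell_veto)
  stopifnot(temperature > 0, sampling_interval > 0, slice_length > 0)
  if (!is.null(tau_chain)) stopifnot(tau_chain > 0)
  structure(list(
    temperature = temperature,
    beta = 1 / (.kB * temperature),
    variant = variant,
    tau_chain = tau_chain,
    sampling_interval = sampling_interval,
    seed = seed,
    cell_veto = cell_veto,
    excluded_layers = excluded_layers,
    slice_length = slice_length,
    safety_factor = safety_factor,
    cell_veto_prefactor = cell_veto_prefactor,
    strict = strict
  ), class = "simulation_parameters")
}

#' Run the event-chain Monte Carlo sampler
#'
#' Realizes the piecewise-deterministic Markov process: a single active
#' atom moves on a straight line until the earliest candidate event
#' (exact bond times; bounding-rate thinning for bend, near-field Coulomb
#' and Lennard-Jones factors; bundled cell-veto candidates for the far
#' field), the lifting scheme of the chosen variant transfers the motion,
#' and configurations are sampled at exact multiples of the sampling
#' interval. The total potential is never evaluated.
#'
#' @param system a [water_system()].
#' @param params a [simulation_parameters()].
#' @param duration total Monte Carlo time to simulate.
#' @param store_configs keep full configurations at every sample (memory
#'   permitting)?
#' @return object of class `ecmc_run`: the polarization series, final
#'   system, event statistics and diagnostics.
#' @export
#' @examples
#' \donttest{
#' box <- generate_water_box(2, box_side = 20, seed = 1)
#' run <- run_ecmc(box, simulation_parameters(seed = 1), duration = 50)
#' head(run$polarization)
#' }
run_ecmc <- function(system, params = simulation_parameters(),
                     duration, store_configs = FALSE) {
  validate_water_system(system)
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- system$n_molecules
  tau <- params$tau_chain
  if (is.null(tau))
    tau <- if (params$variant == "straight") 0.2 * N else 10000 * N

  ew <- ewald_settings(system$box_side)
  rest <- ewald_rest_constants(system$box_side, ew)

  tables <- NULL
  if (params$cell_veto != "off" && N >= 2) {
    feasible <- system$box_side / (2 * params$excluded_layers + 2) >= 2.0 &&
      N >= 8
    if (params$cell_veto == "on" || (params$cell_veto == "auto" && feasible)) {
      tables <- build_cell_veto_tables(system, params$beta,
                                       params$excluded_layers,
                                       prefactor = params$cell_veto_prefactor)
      if (is.null(tables) && params$cell_veto == "on")
        stop("cell-veto requested but the grid leaves no non-excluded cells")
    }
  }

  control <- list(
    variant = params$variant,
    tau_chain = tau,
    sampling_interval = params$sampling_interval,
    duration = duration,
    slice_length = params$slice_length,
    strict = params$strict,
    store_configs = store_configs,
    c1_rest = rest$grad_rest,
    c2_rest = rest$hess_rest,
    m1_mol = spcfw_m1_moment(system$params),
    rho_mol = 1.3
  )
  res <- .run_ecmc_cpp(t(system$positions), system$charge, system$box_side,
                       params$beta, unclass(system$params),
                       list(alpha = ew$alpha, kmax = ew$reciprocal_cutoff,
                            nreal = ew$real_space_image_cutoff),
                       control, tables)
  final <- system
  final$positions <- t(res$final_positions)
  out <- list(
    stamps = res$stamps,
    polarization = res$polarization,
    series = polarization_series(res$stamps, res$polarization,
                                 sampler = paste0("ecmc_", params$variant)),
    final_system = final,
    events = res$events,
    candidates = res$candidates,
    bound_violations = res$bound_violations,
    max_handlers = res$max_handlers,
    mean_active_speed = res$mean_active_speed,
    kinetic_energy_drift = res$kinetic_energy_drift,
    velocity_sum = res$velocity_sum,
    params = params,
    duration = duration,
    cell_veto_used = !is.null(tables)
  )
  if (store_configs) out$configs <- res$configs
  class(out) <- "ecmc_run"
  out
}

#' @export
print.ecmc_run <- function(x, ...) {
  cat(sprintf(
    "ecmc_run: %s variant, duration %.6g, %d samples, events: %s\n",
    x$params$variant, x$duration, length(x$stamps),
    paste(names(x$events), round(x$events), sep = "=", collapse = " ")))
  if (x$bound_violations > 0)
    cat(sprintf("  WARNING: %d bound violations\n", x$bound_violations))
  invisible(x)
}
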
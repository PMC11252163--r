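#' Generate a synthetic water box
#'
#' Replaces an external packing/equilibration pipeline: molecules are
#' placed on a simple-cubic lattice with uniformly random orientations at
#' equilibrium internal geometry, and a short Metropolis pre-equilibration
#' removes lattice artifacts and overlaps. The box side follows from the
#' molecule count and mass density (0.97 g/cm^3 by default) unless given
#' explicitly.
#'
#' @param n_molecules number of water molecules.
#' @param density mass density in g/cm^3 (ignored when `box_side` is
#'   given).
#' @param box_side optional box side in Angstrom.
#' @param temperature temperature of the pre-equilibration in K.
#' @param seed integer seed for reproducible boxes.
#' @param equilibrate run the Metropolis pre-equilibration?
#' @param n_equil pre-equilibration trials (default `400 * n_molecules`).
#' @return a [water_system()].
#' @export
generate_water_box <- function(n_molecules, density = 0.97, box_side = NULL,
                               temperature = 300, seed = NULL,
                               equilibrate = TRUE, n_equil = NULL) {
  stopifnot(n_molecules >= 1, density > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(box_side)) {
    # 1 g/cm^3 corresponds to 0.602214076/M molecules per A^3
    vol <- n_molecules * .mass_water / (density * 0.602214076)
    box_side <- vol^(1 / 3)
  }
  nside <- ceiling(n_molecules^(1 / 3))
  spacing <- box_side / nside
  if (spacing < 2.4 && n_molecules > 1)
    stop("density too high: lattice sites closer than 2.4 A")
  geom <- spcfw_equilibrium_geometry()
  center <- colMeans(geom)
  sites <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                                 z = seq_len(nside)))[seq_len(n_molecules), ,
                                                      drop = FALSE]
  pos <- matrix(0, 3 * n_molecules, 3)
  for (m in seq_len(n_molecules)) {
    R <- random_rotation()
    origin <- (sites[m, ] - 0.5) * spacing
    pos[molecule_atoms(m), ] <-
      sweep(geom, 2, center) %*% t(R) + matrix(origin, 3, 3, byrow = TRUE)
  }
  sys <- water_system(pos, box_side)
  if (equilibrate && n_molecules >= 2) {
    if (is.null(n_equil)) n_equil <- 400 * n_molecules
    eq <- run_metropolis(sys, temperature = temperature,
                         n_production = n_equil,
                         n_adapt_batches = 10,
                         batch_size = max(200, 2 * n_molecules),
                         sample_every = 0)
    sys <- eq$final_system
  }
  sys
}

# uniform random rotation from a random quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Write a water system as extended XYZ
#'
#' Plain-text format: atom count, a comment line carrying
#' `box_side=<value>`, then one `element x y z` line per atom (O, H, H per
#' molecule), at full double precision for a lossless round trip.
#'
#' @param system a [water_system()].
#' @param path output file.
#' @export
write_xyz <- function(system, path) {
  n <- 3 * system$n_molecules
  lines <- c(
    as.character(n),
    sprintf("box_side=%.17g", system$box_side),
    sprintf("%s %.17g %.17g %.17g", system$element,
            system$positions[, 1], system$positions[, 2],
            system$positions[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a water system from extended XYZ
#'
#' @param path input file written by [write_xyz()] (or any XYZ with the box
#'   side in the comment line and atoms grouped O, H, H).
#' @return a [water_system()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ: missing header")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  box <- regmatches(lines[2], regexec("box_side=([-0-9.eE+]+)", lines[2]))[[1]]
  if (length(box) < 2)
    stop("missing box record: comment line must contain box_side=<value>")
  L <- as.numeric(box[2])
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop(sprintf("atom count mismatch: header says %d, found %d atom lines",
                 n, length(body)))
  parts <- strsplit(trimws(body), "\\s+")
  el <- vapply(parts, `[[`, "", 1)
  bad <- which(!el %in% c("O", "H"))
  if (length(bad))
    stop(sprintf("unsupported element '%s' on atom line %d", el[bad[1]],
                 bad[1]))
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  sys <- water_system(pos, L)
  if (!identical(sys$element, el))
    stop("atoms must be grouped O, H, H per molecule")
  sys
}

#' Load a run configuration
#'
#' Flat sectioned key-value file (YAML): sections `system`, `engine`,
#' `cell_veto`, `metropolis` and `analysis`. Unknown keys are rejected;
#' missing keys take documented defaults. The resolved configuration is
#' suitable for [save_config()] and round-trips exactly.
#'
#' @param path configuration file.
#' @return object of class `sim_config`: the fully resolved configuration.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  resolve_config(raw)
}

config_defaults <- function() {
  list(
    system = list(n_molecules = 2, density = 0.97, box_side = NULL,
                  temperature = 300, seed = 1),
    engine = list(variant = "newtonian", tau_chain = NULL,
                  sampling_interval = 1, duration = 100,
                  slice_length = 0.1, safety_factor = 1.2, strict = TRUE),
    cell_veto = list(mode = "auto", excluded_layers = 2, prefactor = 2,
                     fibonacci_D = 10, fibonacci_eps = 0.36),
    metropolis = list(n_production = 1e5, n_adapt_batches = 25,
                      batch_size = 1000, target_acceptance = 0.37,
                      sample_every = 10),
    analysis = list(burn_in_fraction = 0.2, fit_window = c(0.05, 0.8),
                    n_bootstrap = 200, n_replicates = 20)
  )
}

resolve_config <- function(raw) {
  def <- config_defaults()
  bad_sec <- setdiff(names(raw), names(def))
  if (length(bad_sec))
    stop("unknown configuration sections: ", paste(bad_sec, collapse = ", "))
  cfg <- def
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop(sprintf("unknown keys in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    # single-bracket assignment so explicit nulls survive the round trip
    for (k in names(raw[[sec]])) cfg[[sec]][k] <- list(raw[[sec]][[k]])
  }
  with(cfg$system, {
    if (temperature <= 0) stop("temperature must be positive")
    if (n_molecules < 1) stop("n_molecules must be at least 1")
  })
  if (!cfg$engine$variant %in% c("newtonian", "straight"))
    stop("engine variant must be 'newtonian' or 'straight'")
  if (cfg$engine$sampling_interval <= 0)
    stop("sampling_interval must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Save a resolved configuration
#' @param config a `sim_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
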
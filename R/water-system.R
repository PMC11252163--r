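#' Periodic box of SPC/Fw water molecules
#'
#' The central container of the package: `N` water molecules (atom order
#' O, H, H per molecule) in a periodic cubic box. Bonded atoms are stored
#' unwrapped relative to each other; only intermolecular distances are
#' subject to the minimum-image convention.
#'
#' @param positions numeric `3N x 3` matrix of atom positions in Angstrom,
#'   grouped O, H, H per molecule.
#' @param box_side box edge length in Angstrom.
#' @param params SPC/Fw parameters supplying the site charges.
#' @return An object of class `water_system` with fields `box_side`,
#'   `n_molecules`, `positions`, `element`, `charge`, `mass`, `molecule_of`.
#' @export
#' @examples
#' geom <- spcfw_equilibrium_geometry()
#' sys <- water_system(geom + 5, box_side = 20)
#' sys$n_molecules
water_system <- function(positions, box_side, params = spcfw_parameters()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have three columns")
  na <- nrow(positions)
  if (na %% 3 != 0) stop("number of atoms must be a multiple of three")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  if (!is.numeric(box_side) || length(box_side) != 1 || box_side <= 0)
    stop("box_side must be a positive scalar")
  n <- na / 3L
  element <- rep(c("O", "H", "H"), n)
  charge <- rep(c(params$charge_O, params$charge_H, params$charge_H), n)
  mass <- rep(c(.mass_O, .mass_H, .mass_H), n)
  sys <- structure(list(
    box_side = box_side,
    n_molecules = n,
    positions = unname(positions),
    element = element,
    charge = charge,
    mass = mass,
    molecule_of = rep(seq_len(n), each = 3L),
    params = params
  ), class = "water_system")
  validate_water_system(sys)
  sys
}

#' @export
print.water_system <- function(x, ...) {
  cat(sprintf("water_system: %d SPC/Fw molecules (%d atoms), box side %.4f A\n",
              x$n_molecules, 3 * x$n_molecules, x$box_side))
  invisible(x)
}

validate_water_system <- function(sys) {
  stopifnot(inherits(sys, "water_system"))
  n <- sys$n_molecules
  if (nrow(sys$positions) != 3 * n) stop("N_a must equal 3 N")
  if (!identical(sys$element, rep(c("O", "H", "H"), n)))
    stop("each molecule must consist of one O followed by two H")
  qs <- colSums(matrix(sys$charge, nrow = 3))
  if (any(abs(qs) > 1e-12)) stop("each molecule must be charge neutral")
  invisible(sys)
}

# atom indices of one molecule (O, H, H)
molecule_atoms <- function(m) 3L * (m - 1L) + 1:3

# minimum-image displacement
min_image <- function(d, L) d - L * round(d / L)

#' Molecular barycenters (geometric centers) of all molecules
#' @param system a `water_system`.
#' @return `N x 3` matrix.
#' @export
molecule_barycenters <- function(system) {
  x <- system$positions
  n <- system$n_molecules
  (x[seq(1, 3 * n, 3), , drop = FALSE] +
    x[seq(2, 3 * n, 3), , drop = FALSE] +
    x[seq(3, 3 * n, 3), , drop = FALSE]) / 3
}
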
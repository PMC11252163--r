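#' @useDynLib waterecmc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp runif rnorm integrate uniroot median quantile sd
#'   ks.test chisq.test lm coef
#' @importFrom utils modifyList
NULL

# Boltzmann constant in kcal mol^-1 K^-1
.kB <- 0.0019872041

# Coulomb prefactor 1/(4 pi eps0) in kcal A mol^-1 e^-2, the conventional
# value of the force-field literature the SPC/Fw parameters come from
.kC <- 332.06371

#' SPC/Fw force-field parameters
#'
#' Empirical parameters of the flexible simple-point-charge (SPC/Fw) water
#' model of Wu, Tepper and Voth (2006): harmonic O--H bonds, a harmonic
#' H--O--H bend, a 12-6 Lennard-Jones interaction between oxygens and partial
#' charges on all three sites. Potentials use the `k/2 x^2` convention.
#'
#' Units are Angstrom, kcal/mol, radian and elementary charge.
#'
#' @param ... named overrides of individual parameters.
#' @return A list of class `spcfw_parameters` with elements
#'   `bond_equilibrium_length`, `bond_stiffness`, `bend_equilibrium_angle`,
#'   `bend_stiffness`, `lj_epsilon`, `lj_sigma`, `charge_O`, `charge_H` and
#'   `coulomb_prefactor`.
#' @export
#' @examples
#' p <- spcfw_parameters()
#' p$bond_equilibrium_length
spcfw_parameters <- function(...) {
  p <- list(
    bond_equilibrium_length = 1.012,
    bond_stiffness = 1059.162,
    bend_equilibrium_angle = 113.24 * pi / 180,
    bend_stiffness = 75.90,
    lj_epsilon = 0.1554253,
    lj_sigma = 3.165492,
    charge_O = -0.82,
    charge_H = 0.41,
    coulomb_prefactor = .kC
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown SPC/Fw parameters: ", paste(bad, collapse = ", "))
  p <- modifyList(p, over)
  stopifnot(p$bond_stiffness > 0, p$bend_stiffness > 0, p$lj_sigma > 0)
  if (abs(2 * p$charge_H + p$charge_O) > 1e-12)
    stop("molecule must be charge neutral: 2 qH + qO = 0")
  class(p) <- "spcfw_parameters"
  p
}

# atom masses in Da (used for box sizing and MD speed conversions only;
# ECMC runs with equal masses by default)
.mass_H <- 1.0079
.mass_O <- 15.9994001
.mass_water <- .mass_O + 2 * .mass_H

#' Equilibrium geometry of one SPC/Fw molecule
#'
#' Oxygen at the origin, hydrogens in the xz-plane, symmetric about z.
#'
#' @param params SPC/Fw parameter set.
#' @return 3 x 3 matrix, rows O, H, H.
#' @export
spcfw_equilibrium_geometry <- function(params = spcfw_parameters()) {
  l0 <- params$bond_equilibrium_length
  th <- params$bend_equilibrium_angle
  rbind(
    O = c(0, 0, 0),
    H = l0 * c(sin(th / 2), 0, cos(th / 2)),
    H = l0 * c(-sin(th / 2), 0, cos(th / 2))
  )
}

#' Dipole moment of the SPC/Fw molecule at equilibrium geometry (e A)
#' @param params SPC/Fw parameter set.
#' @export
spcfw_equilibrium_dipole <- function(params = spcfw_parameters()) {
  geom <- spcfw_equilibrium_geometry(params)
  p <- params$charge_O * geom[1, ] + params$charge_H * (geom[2, ] + geom[3, ])
  sqrt(sum(p^2))
}

# sum_j |q_j| |x_j - barycenter| at equilibrium geometry, inflated for
# thermal geometry fluctuations; the first-moment constant of the
# neutrality-aware Coulomb rate envelopes
spcfw_m1_moment <- function(params = spcfw_parameters(), margin = 1.15) {
  geom <- spcfw_equilibrium_geometry(params)
  cen <- colMeans(geom)
  d <- sqrt(rowSums(sweep(geom, 2, cen)^2))
  q <- abs(c(params$charge_O, params$charge_H, params$charge_H))
  sum(q * d) * margin
}
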
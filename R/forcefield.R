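#' Potential energy of a single factor
#'
#' Bond and bend factors are harmonic in the deviation of the O--H length
#' and the H--O--H angle from equilibrium (bonded atoms are never
#' minimum-imaged against each other). The Lennard-Jones factor is the 12-6
#' form between the closest periodic images of the two oxygens. The
#' molecular Coulomb factor is the full periodic lattice sum between the
#' nine charge pairs of the two molecules, via [ewald_pair_interaction()].
#'
#' @param factor an [ecmc_factor()].
#' @param system a [water_system()].
#' @param ewald Ewald settings for Coulomb factors; tuned automatically when
#'   `NULL`.
#' @return energy in kcal/mol.
#' @export
factor_potential <- function(factor, system, ewald = NULL) {
  check_factor(factor, system)
  p <- system$params
  x <- system$positions
  a <- factor$atoms
  switch(factor$kind,
    bond = {
      r <- sqrt(sum((x[a[1], ] - x[a[2], ])^2))
      0.5 * p$bond_stiffness * (r - p$bond_equilibrium_length)^2
    },
    bend = {
      u <- x[a[2], ] - x[a[1], ]
      w <- x[a[3], ] - x[a[1], ]
      cth <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
      th <- acos(pmin(1, pmax(-1, cth)))
      0.5 * p$bend_stiffness * (th - p$bend_equilibrium_angle)^2
    },
    lennard_jones = {
      d <- min_image(x[a[1], ] - x[a[2], ], system$box_side)
      sr6 <- (p$lj_sigma^2 / sum(d^2))^3
      4 * p$lj_epsilon * (sr6^2 - sr6)
    },
    coulomb_molecular = {
      mols <- unique(system$molecule_of[a])
      if (is.null(ewald)) ewald <- ewald_settings(system$box_side)
      ewald_pair_interaction(system, mols[1], mols[2], ewald,
                             gradients = FALSE)$energy
    }
  )
}

#' Analytic gradient of a factor potential with respect to one atom
#'
#' Same boundary conventions as [factor_potential()].
#'
#' @inheritParams factor_potential
#' @param atom atom index; must contribute to the factor.
#' @return gradient 3-vector in kcal/mol/A.
#' @export
factor_gradient <- function(factor, system, atom, ewald = NULL) {
  check_factor(factor, system)
  if (!(atom %in% factor$atoms))
    stop("atom does not contribute to this factor")
  p <- system$params
  x <- system$positions
  a <- factor$atoms
  switch(factor$kind,
    bond = {
      d <- x[a[1], ] - x[a[2], ]
      r <- sqrt(sum(d^2))
      g1 <- p$bond_stiffness * (r - p$bond_equilibrium_length) * d / r
      if (atom == a[1]) g1 else -g1
    },
    bend = {
      u <- x[a[2], ] - x[a[1], ]
      w <- x[a[3], ] - x[a[1], ]
      r1 <- sqrt(sum(u^2)); r2 <- sqrt(sum(w^2))
      u <- u / r1; w <- w / r2
      cth <- pmin(1, pmax(-1, sum(u * w)))
      sth <- max(sqrt(1 - cth^2), 1e-12)
      dU <- p$bend_stiffness * (acos(cth) - p$bend_equilibrium_angle)
      gH1 <- -dU * (w - cth * u) / (r1 * sth)
      gH2 <- -dU * (u - cth * w) / (r2 * sth)
      if (atom == a[2]) gH1 else if (atom == a[3]) gH2 else -(gH1 + gH2)
    },
    lennard_jones = {
      d <- min_image(x[a[1], ] - x[a[2], ], system$box_side)
      r2 <- sum(d^2)
      sr6 <- (p$lj_sigma^2 / r2)^3
      g1 <- 4 * p$lj_epsilon * (-12 * sr6^2 + 6 * sr6) / r2 * d
      if (atom == a[1]) g1 else -g1
    },
    coulomb_molecular = {
      mols <- unique(system$molecule_of[a])
      if (is.null(ewald)) ewald <- ewald_settings(system$box_side)
      res <- ewald_pair_interaction(system, mols[1], mols[2], ewald)
      g <- rbind(res$grad_i, res$grad_j)
      g[match(atom, a), ]
    }
  )
}

#' Total potential energy of the system
#'
#' Sum of all factor potentials. Used by the Metropolis reference sampler
#' and by tests; the event-chain engine itself never evaluates it.
#'
#' @inheritParams factor_potential
#' @export
total_potential <- function(system, ewald = NULL) {
  if (is.null(ewald) && system$n_molecules >= 2)
    ewald <- ewald_settings(system$box_side)
  sum(vapply(factor_list(system), factor_potential, numeric(1),
             system = system, ewald = ewald))
}
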
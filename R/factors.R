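#' Factor descriptors of the SPC/Fw potential
#'
#' The total potential is a sum of factor potentials, each depending on a
#' small atom subset: two harmonic O--H bonds and one harmonic bend per
#' molecule, and one Lennard-Jones (oxygen pair) plus one molecular Coulomb
#' factor (all six atoms) per molecule pair. The factors are the units that
#' independently generate candidate events in the event-chain sampler.
#'
#' @param kind one of `"bond"`, `"bend"`, `"lennard_jones"`,
#'   `"coulomb_molecular"`.
#' @param atoms integer vector of atom indices (length 2, 3, 2 and 6
#'   respectively).
#' @return An object of class `ecmc_factor`.
#' @export
ecmc_factor <- function(kind, atoms) {
  kind <- match.arg(kind, c("bond", "bend", "lennard_jones",
                            "coulomb_molecular"))
  need <- c(bond = 2L, bend = 3L, lennard_jones = 2L, coulomb_molecular = 6L)
  atoms <- as.integer(atoms)
  if (length(atoms) != need[[kind]])
    stop(sprintf("a %s factor needs %d atom indices", kind, need[[kind]]))
  structure(list(kind = kind, atoms = atoms), class = "ecmc_factor")
}

#' Complete factor list of a water system
#'
#' Enumerates the factors whose sum partitions the total potential exactly:
#' per molecule the two bonds (O--H1, O--H2) and the bend (O, H1, H2); per
#' molecule pair the oxygen--oxygen Lennard-Jones factor and the molecular
#' Coulomb factor over all six atoms.
#'
#' @param system a `water_system`.
#' @return list of `ecmc_factor` objects.
#' @export
factor_list <- function(system) {
  n <- system$n_molecules
  out <- list()
  for (m in seq_len(n)) {
    a <- molecule_atoms(m)
    out[[length(out) + 1L]] <- ecmc_factor("bond", a[c(1, 2)])
    out[[length(out) + 1L]] <- ecmc_factor("bond", a[c(1, 3)])
    out[[length(out) + 1L]] <- ecmc_factor("bend", a)
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ai <- molecule_atoms(i); aj <- molecule_atoms(j)
        out[[length(out) + 1L]] <- ecmc_factor("lennard_jones", c(ai[1], aj[1]))
        out[[length(out) + 1L]] <- ecmc_factor("coulomb_molecular", c(ai, aj))
      }
    }
  }
  out
}

check_factor <- function(factor, system) {
  if (!inherits(factor, "ecmc_factor")) stop("not an ecmc_factor")
  na <- 3 * system$n_molecules
  if (any(factor$atoms < 1 | factor$atoms > na))
    stop("factor atom indices out of range")
  mols <- unique(system$molecule_of[factor$atoms])
  switch(factor$kind,
    bond = , bend = if (length(mols) != 1)
      stop("bonded factor must lie within one molecule"),
    lennard_jones = {
      if (length(mols) != 2) stop("LJ factor needs two distinct molecules")
      if (any(system$element[factor$atoms] != "O"))
        stop("LJ factor atoms must be oxygens")
    },
    coulomb_molecular = if (length(mols) != 2)
      stop("molecular Coulomb factor needs two distinct molecules")
  )
  invisible(factor)
}
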
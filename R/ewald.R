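#' Machine-precision Ewald settings for molecular pair interactions
#'
#' Tunes the truncation shells of the classic Ewald summation so that the
#' periodic Coulomb interaction between two neutral molecules is converged
#' to a target relative precision, without any assumption on the global
#' charge distribution. The tuner increases the reciprocal and real-space
#' cutoffs on a probe configuration until successive energies agree, then
#' freezes. Conducting ("tinfoil") boundary conditions are used, so no
#' surface term appears; for neutral charge groups the splitting-dependent
#' background terms cancel identically.
#'
#' @param box_side box edge length in Angstrom.
#' @param splitting_length Ewald splitting length 1/alpha in Angstrom;
#'   defaults to `box_side / 4`, which balances the real and reciprocal
#'   sums for a per-pair evaluation.
#' @param target target relative precision (default 1e-12).
#' @param params SPC/Fw parameters (probe charges).
#' @return object of class `ewald_settings` with fields `splitting_length`,
#'   `real_space_image_cutoff`, `reciprocal_cutoff`,
#'   `achieved_relative_precision`, plus the box side and alpha.
#' @export
ewald_settings <- function(box_side, splitting_length = box_side / 4,
                           target = 1e-12, params = spcfw_parameters()) {
  key <- sprintf("%.12g|%.12g|%.3g", box_side, splitting_length, target)
  hit <- .waterecmc_cache$ewald[[key]]
  if (!is.null(hit)) return(hit)

  alpha <- 1 / splitting_length
  geom <- spcfw_equilibrium_geometry(params)
  q <- c(params$charge_O, params$charge_H, params$charge_H)
  posA <- t(geom + matrix(c(0.11, 0.23, 0.31), 3, 3, byrow = TRUE))
  posB <- t(geom %*% matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3) +
              matrix(box_side * c(0.41, 0.27, 0.36), 3, 3, byrow = TRUE))
  ener <- function(kmax, nreal) {
    .ewald_pair_cpp(posA, q, posB, q, box_side, alpha, kmax, nreal,
                    params$coulomb_prefactor, gradients = FALSE)$energy
  }
  # grow the reciprocal cutoff until converged at generous real cutoff
  nreal0 <- max(1L, ceiling(6 * splitting_length / box_side))
  kmax <- max(4L, ceiling(alpha * box_side))
  e_prev <- ener(kmax, nreal0)
  prec <- Inf
  repeat {
    kmax <- kmax + 2L
    e <- ener(kmax, nreal0)
    prec <- abs(e - e_prev) / max(abs(e), 1e-10)
    if (prec < target || kmax > 64L) break
    e_prev <- e
  }
  # then shrink/grow the real-space shells
  nreal <- nreal0
  while (nreal > 1L &&
         abs(ener(kmax, nreal - 1L) - ener(kmax, nreal)) /
           max(abs(ener(kmax, nreal)), 1e-10) < target) {
    nreal <- nreal - 1L
  }
  out <- structure(list(
    box_side = box_side,
    splitting_length = splitting_length,
    alpha = alpha,
    reciprocal_cutoff = kmax,
    real_space_image_cutoff = nreal,
    achieved_relative_precision = prec
  ), class = "ewald_settings")
  .waterecmc_cache$ewald[[key]] <- out
  out
}

#' @export
print.ewald_settings <- function(x, ...) {
  cat(sprintf(
    "ewald_settings: L = %.4f A, 1/alpha = %.4f A, kmax = %d, %d real shell(s), rel. precision %.2e\n",
    x$box_side, x$splitting_length, x$reciprocal_cutoff,
    x$real_space_image_cutoff, x$achieved_relative_precision))
  invisible(x)
}

#' Periodic Coulomb interaction between two water molecules
#'
#' Energy and per-atom gradients of the molecular Coulomb factor: the
#' interaction between the nine charge pairs of two distinct neutral
#' molecules, including all periodic images of both molecules, with the
#' self-image terms of each molecule excluded. Converged to the precision
#' of the supplied [ewald_settings()].
#'
#' @param system a [water_system()].
#' @param mol_i,mol_j distinct molecule indices.
#' @param settings an [ewald_settings()] object (tuned automatically when
#'   `NULL`).
#' @param gradients compute gradients as well as the energy?
#' @return list with `energy` (kcal/mol) and, if requested, `grad_i`,
#'   `grad_j` (3 x 3 matrices, rows O, H, H, kcal/mol/A).
#' @export
ewald_pair_interaction <- function(system, mol_i, mol_j, settings = NULL,
                                   gradients = TRUE) {
  if (mol_i == mol_j) stop("mol_i and mol_j must differ")
  if (is.null(settings)) settings <- ewald_settings(system$box_side)
  ai <- molecule_atoms(mol_i)
  aj <- molecule_atoms(mol_j)
  qi <- system$charge[ai]
  qj <- system$charge[aj]
  if (abs(sum(qi)) > 1e-12 || abs(sum(qj)) > 1e-12)
    stop("molecules must be charge neutral for the tuned Ewald summation")
  res <- .ewald_pair_cpp(t(system$positions[ai, , drop = FALSE]), qi,
                         t(system$positions[aj, , drop = FALSE]), qj,
                         system$box_side, settings$alpha,
                         settings$reciprocal_cutoff,
                         settings$real_space_image_cutoff,
                         system$params$coulomb_prefactor,
                         gradients = gradients)
  if (gradients) {
    res$grad_i <- t(res$grad_i)
    res$grad_j <- t(res$grad_j)
  }
  res
}

# residual-field constants of the periodic charge kernel relative to its
# bare nearest-image part, memoized per box (deterministic probe draws)
ewald_rest_constants <- function(box_side, settings = NULL) {
  key <- sprintf("rest|%.12g", box_side)
  hit <- .waterecmc_cache$rest[[key]]
  if (!is.null(hit)) return(hit)
  if (is.null(settings)) settings <- ewald_settings(box_side)
  # deterministic probe draws without disturbing the caller's RNG stream
  had_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", globalenv())
  set.seed(20011)
  out <- .ewald_rest_constants_cpp(box_side, settings$alpha,
                                   settings$reciprocal_cutoff,
                                   settings$real_space_image_cutoff,
                                   rmin = 1.5, ngrid = 9, nrandom = 400,
                                   margin = 1.5)
  if (had_seed) assign(".Random.seed", old_seed, globalenv())
  .waterecmc_cache$rest[[key]] <- out
  out
}

# package-level memo cache (ewald settings, rest constants, cell-veto tables)
.waterecmc_cache <- new.env(parent = emptyenv())
.waterecmc_cache$ewald <- list()
.waterecmc_cache$rest <- list()
.waterecmc_cache$tables <- list()
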
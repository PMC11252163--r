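#' Total electric polarization of the box
#'
#' Sum of the molecular dipole moments, each computed from the site charges
#' with the hydrogens minimum-imaged to their oxygen; molecular neutrality
#' makes every molecular dipole origin-independent.
#'
#' @param system a [water_system()].
#' @return 3-vector in e A.
#' @export
polarization <- function(system) {
  x <- system$positions
  L <- system$box_side
  P <- c(0, 0, 0)
  for (m in seq_len(system$n_molecules)) {
    a <- molecule_atoms(m)
    xo <- x[a[1], ]
    p <- system$charge[a[1]] * xo +
      system$charge[a[2]] * (xo + min_image(x[a[2], ] - xo, L)) +
      system$charge[a[3]] * (xo + min_image(x[a[3], ] - xo, L))
    P <- P + p
  }
  P
}

#' Polarization time series
#'
#' @param stamps strictly increasing clock stamps (sampler-native units).
#' @param P `n x 3` matrix of polarization vectors (e A).
#' @param sampler tag: `"ecmc_newtonian"`, `"ecmc_straight"`,
#'   `"metropolis"` or `"md_external"`.
#' @param replicate replicate id.
#' @return object of class `polarization_series`.
#' @export
polarization_series <- function(stamps, P, sampler = "ecmc_newtonian",
                                replicate = 1L) {
  P <- as.matrix(P)
  stopifnot(ncol(P) == 3, length(stamps) == nrow(P))
  if (any(diff(stamps) <= 0)) stop("clock stamps must be strictly increasing")
  sampler <- match.arg(sampler, c("ecmc_newtonian", "ecmc_straight",
                                  "metropolis", "md_external"))
  structure(list(stamps = stamps, P = unname(P), sampler = sampler,
                 replicate = replicate), class = "polarization_series")
}

#' Normalized polarization autocorrelation
#'
#' `Phi(tau) = <P(t).P(t+tau)>_t / <P(t).P(t)>_t` at integer lag indices of
#' an evenly sampled series, with the stationarity assumption `<P> = 0`
#' (no mean subtraction). `Phi(0) = 1` exactly.
#'
#' @param series a [polarization_series()] or an `n x 3` matrix.
#' @param lags integer lag indices (in sampling steps), starting at 0.
#' @return numeric vector of autocorrelations at the requested lags.
#' @export
autocorrelation <- function(series, lags) {
  P <- if (inherits(series, "polarization_series")) series$P else as.matrix(series)
  n <- nrow(P)
  lags <- as.integer(lags)
  if (any(lags < 0) || max(lags) >= n)
    stop("lags must lie in [0, n - 1]")
  denom <- mean(rowSums(P^2))
  vapply(lags, function(k) {
    if (k == 0) return(1)
    idx <- seq_len(n - k)
    mean(rowSums(P[idx, , drop = FALSE] * P[idx + k, , drop = FALSE])) / denom
  }, numeric(1))
}

#' Exponential decay fit of the median autocorrelation
#'
#' For replicate autocorrelation curves, computes the per-lag median across
#' replicates, estimates its error with the bootstrap, and fits
#' `exp(-tau / tau_phi)` by error-weighted least squares on the log scale
#' inside a fit window of autocorrelation values.
#'
#' @param acfs `n_lags x n_replicates` matrix of autocorrelation values.
#' @param lag_times numeric lag times (sampler-native units) matching the
#'   rows.
#' @param window autocorrelation range `c(lo, hi)` defining the fit window
#'   (default `c(0.05, 0.8)`).
#' @param n_boot bootstrap replicates for the per-lag errors (default 200).
#' @return object of class `decay_fit` with `tau`, `se`, the fit `window`
#'   and `n_boot`.
#' @export
fit_decay <- function(acfs, lag_times, window = c(0.05, 0.8), n_boot = 200) {
  acfs <- as.matrix(acfs)
  stopifnot(nrow(acfs) == length(lag_times))
  if (ncol(acfs) < 2) stop("need at least two replicates for the bootstrap")
  med <- apply(acfs, 1, median)
  nrep <- ncol(acfs)
  boot <- replicate(n_boot, apply(
    acfs[, sample.int(nrep, nrep, replace = TRUE), drop = FALSE], 1, median))
  se <- apply(boot, 1, sd)
  keep <- which(med >= window[1] & med <= window[2] & lag_times > 0)
  if (length(keep) < 2) stop("fit window is empty")
  y <- log(med[keep])
  w <- (med[keep] / pmax(se[keep], 1e-12))^2  # delta method on the log scale
  fit <- lm(y ~ lag_times[keep], weights = w)
  slope <- coef(fit)[[2]]
  if (slope >= 0) stop("fitted decay is non-positive")
  tau <- -1 / slope
  se_slope <- sqrt(diag(vcov_safe(fit))[2])
  structure(list(tau = tau, se = tau^2 * se_slope, window = window,
                 n_boot = n_boot, n_lags = length(keep)),
            class = "decay_fit")
}

vcov_safe <- function(fit) {
  v <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(v, "try-error")) matrix(NA_real_, 2, 2) else v
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: tau = %.5g +/- %.2g (%d lags in window [%g, %g])\n",
              x$tau, x$se, x$n_lags, x$window[1], x$window[2]))
  invisible(x)
}

#' Characteristic decorrelation distance
#'
#' Converts an autocorrelation time into the average cumulative distance
#' moved by the atoms of the sampler: for event-chain Monte Carlo the mean
#' active-atom speed times tau; for molecular dynamics
#' `N (2 <|v_H|> + <|v_O|>) tau` with Maxwell-Boltzmann mean speeds; for
#' the Metropolis sampler
#' `p (2 <|d_H|>/3 + <|d_O|>/3) tau` with the mean proposal-cube
#' displacement lengths, neglecting correlations between rejection
#' probability and displacement.
#'
#' @param tag one of `"ecmc_newtonian"`, `"ecmc_straight"`, `"metropolis"`,
#'   `"md_external"`.
#' @param tau autocorrelation time in the sampler's native units.
#' @param params named list of tag-specific parameters: ECMC needs
#'   `mean_active_speed`; MD needs `n_molecules`, `mean_speed_H`,
#'   `mean_speed_O` (per time unit of tau); Metropolis needs `acceptance`,
#'   `halfwidth_H`, `halfwidth_O` (tau in trials).
#' @return distance in Angstrom.
#' @export
characteristic_distance <- function(tag, tau, params) {
  tag <- match.arg(tag, c("ecmc_newtonian", "ecmc_straight", "metropolis",
                          "md_external"))
  need <- function(keys) {
    miss <- setdiff(keys, names(params))
    if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  }
  if (tag %in% c("ecmc_newtonian", "ecmc_straight")) {
    need("mean_active_speed")
    params$mean_active_speed * tau
  } else if (tag == "md_external") {
    need(c("n_molecules", "mean_speed_H", "mean_speed_O"))
    params$n_molecules * (2 * params$mean_speed_H + params$mean_speed_O) * tau
  } else {
    need(c("acceptance", "halfwidth_H", "halfwidth_O"))
    params$acceptance *
      (2 * mean_cube_displacement(params$halfwidth_H) / 3 +
         mean_cube_displacement(params$halfwidth_O) / 3) * tau
  }
}

#' Maxwell-Boltzmann mean speed
#'
#' `sqrt(8 kB T / (pi m))`. In the package's internal units (kcal/mol, Da)
#' the result carries `sqrt(kcal mol^-1 Da^-1)`; multiply by 0.646832 to
#' convert to Angstrom per picosecond.
#'
#' @param temperature temperature in K.
#' @param mass atomic mass in Da.
#' @param units `"internal"` or `"A_per_ps"`.
#' @export
maxwell_mean_speed <- function(temperature, mass,
                               units = c("internal", "A_per_ps")) {
  units <- match.arg(units)
  stopifnot(temperature > 0, mass > 0)
  v <- sqrt(8 * .kB * temperature / (pi * mass))
  if (units == "A_per_ps") v * 0.6468319 else v
}

#' Mean displacement length of the cube proposal
#'
#' Mean Euclidean norm of a vector uniform on the cube `[-delta, delta]^3`,
#' evaluated by high-order Gauss-Legendre product quadrature; the ratio to
#' `delta` is a universal constant (about 0.9606).
#'
#' @param delta cube half-width.
#' @param n_nodes quadrature nodes per axis.
#' @export
mean_cube_displacement <- function(delta, n_nodes = 48) {
  stopifnot(delta > 0)
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  x <- gl$x
  w <- gl$w
  g <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes),
                   k = seq_len(n_nodes))
  r <- sqrt(x[g$i]^2 + x[g$j]^2 + x[g$k]^2)
  delta * sum(w[g$i] * w[g$j] * w[g$k] * r) / 8
}
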
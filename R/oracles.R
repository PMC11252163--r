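#' Numerical inversion oracle for candidate event times
#'
#' Independent test oracle: accumulates the integrated event rate by
#' adaptive quadrature and inverts the exponential-threshold identity by
#' root bracketing, to high accuracy in time. Event rates carry a
#' `max(0, .)` clamp, so the integrand is only piecewise smooth; adaptive
#' quadrature across such kinks can silently lose accuracy. The oracle
#' therefore first locates the boundaries of the rate's zero-regions on a
#' fine scan (refined by bisection on the positivity indicator) and
#' integrates each smooth piece separately. Used to validate the
#' closed-form and thinning-based solvers; never used by the samplers
#' themselves.
#'
#' @param rate_fn nonnegative, piecewise-continuous rate function of time.
#' @param exp_threshold exponential threshold (mean 1).
#' @param horizon search horizon; `Inf` is reported if the integrated rate
#'   never reaches the threshold before it.
#' @param tol absolute tolerance of the returned time.
#' @param n_scan grid resolution of the kink scan.
#' @return event time, or `Inf` when beyond the horizon.
#' @export
numerical_event_time_oracle <- function(rate_fn, exp_threshold, horizon,
                                        tol = 1e-10, n_scan = 1024L) {
  stopifnot(is.finite(horizon), horizon > 0)
  grid <- seq(0, horizon, length.out = n_scan + 1L)
  pos <- vapply(grid, rate_fn, numeric(1)) > 0
  kinks <- numeric(0)
  for (i in which(diff(pos) != 0L)) {
    lo <- grid[i]; hi <- grid[i + 1L]
    target <- pos[i]  # rate positive at lo?
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if ((rate_fn(mid) > 0) == target) lo <- mid else hi <- mid
    }
    kinks <- c(kinks, (lo + hi) / 2)
  }
  bounds <- sort(unique(c(0, kinks, horizon)))

  piece <- function(a, b) {
    if (b - a < 1e-14) return(0)
    integrate(function(u) vapply(u, rate_fn, numeric(1)), a, b,
              rel.tol = 1e-12, abs.tol = 1e-13, subdivisions = 400L)$value
  }
  cum_at_bounds <- c(0, cumsum(vapply(seq_len(length(bounds) - 1L),
                                      function(k) piece(bounds[k], bounds[k + 1L]),
                                      numeric(1))))
  cum <- function(t) {
    if (t <= 0) return(0)
    k <- findInterval(t, bounds, rightmost.closed = TRUE)
    cum_at_bounds[k] + piece(bounds[k], t)
  }
  if (cum(horizon) < exp_threshold) return(Inf)
  uniroot(function(t) cum(t) - exp_threshold, c(0, horizon),
          tol = tol)$root
}
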
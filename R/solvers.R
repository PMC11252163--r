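#' Exact candidate event time of a harmonic bond factor
#'
#' Under straight-line motion of the active atom the bond length r(t) is a
#' hyperbola, so the uphill increments of the harmonic bond potential can be
#' accumulated in closed form between the monotonicity breakpoints (closest
#' approach and equilibrium-length crossings) and inverted exactly: the
#' candidate is the time at which the integrated factor event rate first
#' equals the exponential threshold.
#'
#' @param factor a bond [ecmc_factor()] containing the active atom.
#' @param system a [water_system()].
#' @param lifted a [lifted_state()]; its active atom must belong to the
#'   factor.
#' @param exp_threshold exponentially distributed threshold (mean 1).
#' @param horizon return `Inf` if the candidate exceeds this time.
#' @param beta inverse temperature in mol/kcal.
#' @return candidate event time (time units of the lifted motion), possibly
#'   `Inf`.
#' @export
bond_event_time <- function(factor, system, lifted, exp_threshold,
                            beta, horizon = Inf) {
  stopifnot(factor$kind == "bond")
  i <- lifted$active_atom
  if (!(i %in% factor$atoms)) stop("active atom not in bond factor")
  j <- setdiff(factor$atoms, i)
  p <- system$params
  v <- lifted$velocity[i, ]
  c0 <- system$positions[i, ] - system$positions[j, ]
  s2 <- sum(v^2)
  s <- sqrt(s2)
  A <- sum(c0^2)
  a <- sum(c0 * v)
  tstar <- -a / s2
  rmin2 <- max(A - a^2 / s2, 0)
  l0 <- p$bond_equilibrium_length
  kb <- p$bond_stiffness

  bps <- 0
  if (rmin2 < l0^2) {
    w <- sqrt(l0^2 - rmin2) / s
    if (tstar - w > 0) bps <- c(bps, tstar - w)
    if (tstar + w > 0) bps <- c(bps, tstar + w)
  }
  if (tstar > 0) bps <- c(bps, tstar)
  bps <- sort(unique(bps))

  r_at <- function(t) sqrt(pmax(A + 2 * a * t + s2 * t^2, 0))
  u_of <- function(r) 0.5 * kb * (r - l0)^2
  E <- exp_threshold
  for (seg in seq_along(bps)) {
    ts <- bps[seg]
    te <- if (seg < length(bps)) bps[seg + 1] else Inf
    us <- u_of(r_at(ts))
    ue <- if (is.finite(te)) u_of(r_at(te)) else Inf
    if (ue <= us) next
    cap <- beta * (ue - us)
    if (E > cap) { E <- E - cap; next }
    ut <- us + E / beta
    dd <- sqrt(2 * ut / kb)
    increasing <- !is.finite(te) || r_at(te) > r_at(ts)
    rt <- if (increasing) l0 + dd else l0 - dd
    disc <- max(rt^2 - rmin2, 0)
    t <- if (increasing) tstar + sqrt(disc) / s else tstar - sqrt(disc) / s
    t <- max(t, ts)
    return(if (t > horizon) Inf else t)
  }
  Inf
}

#' Candidate event time from a piecewise-constant bounding rate
#'
#' Generic thinning front end: the (possibly intractable) factor event rate
#' `rate_fn(t)` is upper-bounded on successive time slices by a constant,
#' the maximum of the rate at the slice endpoints and midpoint times a
#' safety factor. The candidate is drawn from the piecewise-constant bound
#' process; the caller must confirm it with [confirm_event()], which
#' corrects the overestimate exactly.
#'
#' @param rate_fn vectorizable function of time returning the true factor
#'   event rate (>= 0).
#' @param slice_length length of a time slice.
#' @param safety_factor multiplied onto the slice maximum.
#' @param exp_threshold exponential threshold (mean 1) consumed by the bound
#'   process.
#' @param horizon stop searching past this time.
#' @return list with `time` (candidate, or `Inf`) and `bound` (the bounding
#'   rate governing the candidate, for the confirmation step).
#' @export
bounded_event_time <- function(rate_fn, slice_length, safety_factor,
                               exp_threshold, horizon = Inf) {
  stopifnot(slice_length > 0, safety_factor >= 1)
  t <- 0
  E <- exp_threshold
  max_slices <- 1e6
  n <- 0
  while (t < horizon && n < max_slices) {
    tb <- min(t + slice_length, horizon)
    lam <- safety_factor * max(rate_fn(t), rate_fn((t + tb) / 2), rate_fn(tb))
    if (lam > 0) {
      if (E <= lam * (tb - t))
        return(list(time = t + E / lam, bound = lam))
      E <- E - lam * (tb - t)
    }
    t <- tb
    n <- n + 1
  }
  list(time = Inf, bound = 0)
}

#' Thinning confirmation of a candidate event
#'
#' Confirms with probability `true_rate / bound_rate`. A true rate that
#' exceeds its bound breaks the exactness of the method and raises an error
#' in strict mode (the default); with `strict = FALSE` a warning is issued
#' and the event confirmed, for debugging only.
#'
#' @param true_rate exact factor event rate at the candidate time.
#' @param bound_rate the bounding rate that generated the candidate.
#' @param strict abort on bound violation?
#' @return logical: event confirmed?
#' @export
confirm_event <- function(true_rate, bound_rate, strict = TRUE) {
  stopifnot(bound_rate > 0, true_rate >= 0)
  if (true_rate > bound_rate * (1 + 1e-9)) {
    msg <- sprintf("bound violation: true rate %.6g exceeds bound %.6g",
                   true_rate, bound_rate)
    if (strict) stop(msg) else warning(msg)
    return(TRUE)
  }
  runif(1) < true_rate / bound_rate
}
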
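#' Largest Lyapunov exponent of the logistic map
#'
#' Numerical estimate of the largest Lyapunov exponent at growth rate `r`:
#' the orbit average of \eqn{\ln |r (1 - 2 P_t)|} after a burn-in, in nats
#' per step. Negative values indicate convergence to a fixed point or
#' periodic cycle; positive values diagnose chaos. Orbit points where the
#' map derivative is exactly zero (the critical point P = 1/2) contribute a
#' divergent term and are skipped.
#'
#' @param r Growth rate in (0, 4].
#' @param burn_in Iterations discarded before averaging; default 1000.
#' @param n_iter Iterations averaged; default 1e5 (minimum 1e4 for a stable
#'   estimate).
#' @param P0 Orbit start, default 0.1.
#' @return Estimated exponent in nats per step.
#' @examples
#' lyapunov_exponent(1.8) < 0 # stable fixed point
#' @export
lyapunov_exponent <- function(r, burn_in = 1000, n_iter = 1e5, P0 = 0.1) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 4) {
    stop("`r` must lie in (0, 4]", call. = FALSE)
  }
  if (n_iter < 1e4) stop("`n_iter` must be >= 1e4", call. = FALSE)
  lyapunov_cpp(r, P0, burn_in, n_iter)
}

#' Period of the logistic-map attractor
#'
#' Counts the distinct values visited by the post-burn-in orbit, clustering
#' values closer than `tol`. A long burn-in (default 1e6 iterations) is used
#' because convergence slows critically near bifurcation points, where a
#' decaying transient would otherwise masquerade as a higher period.
#'
#' @param r Growth rate in (0, 4].
#' @param burn_in Iterations discarded; default 1e6.
#' @param n_check Orbit window inspected; default 256.
#' @param tol Distinctness tolerance; default 1e-8.
#' @param P0 Orbit start.
#' @return Integer period estimate (number of distinct attractor values in
#'   the window; equals `n_check` on a chaotic orbit).
#' @examples
#' attractor_period(2.9) # 1
#' attractor_period(3.2) # 2
#' @export
attractor_period <- function(r, burn_in = 1e6, n_check = 256, tol = 1e-8,
                             P0 = 0.1) {
  v <- sort(attractor_cpp(r, P0, burn_in, n_check))
  if (length(v) == 1) return(1L)
  sum(diff(v) > tol) + 1L
}

#' Onset of chaos in the logistic map
#'
#' Locates the smallest growth rate at which the map becomes chaotic — the
#' period-doubling accumulation point, approximately 3.56995 — as the first
#' sign change of the Lyapunov exponent approached from below. A coarse
#' scan over \[3.4, 3.7\] finds the first grid point with a positive
#' exponent; bisection then refines the bracket to `tolerance`. Taking the
#' first crossing from below is what makes the search robust to the
#' periodic windows (with negative exponents) interleaved above the onset.
#'
#' @param tolerance Bracket width at which bisection stops; default 1e-5
#'   (must be <= 1e-4).
#' @param burn_in Burn-in per Lyapunov evaluation; default 1e4 — longer
#'   than the generic default because transients decay slowly on the
#'   high-period cycles just below the accumulation point.
#' @param n_iter Averaged iterations per evaluation; default 1e5.
#' @param P0 Orbit start.
#' @return The estimated chaos-onset growth rate.
#' @export
chaos_onset <- function(tolerance = 1e-5, burn_in = 1e4, n_iter = 1e5,
                        P0 = 0.1) {
  if (tolerance > 1e-4) stop("`tolerance` must be <= 1e-4", call. = FALSE)
  grid <- seq(3.4, 3.7, by = 2e-3)
  lam <- vapply(grid, lyapunov_cpp, numeric(1),
                P0 = P0, burn_in = burn_in, n_iter = n_iter)
  hit <- which(lam > 0)
  if (length(hit) == 0) {
    stop("no positive Lyapunov exponent found in the scan bracket",
         call. = FALSE)
  }
  i <- hit[1]
  if (i == 1) stop("scan bracket does not contain the sign change",
                   call. = FALSE)
  lo <- grid[i - 1]
  hi <- grid[i]
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (lyapunov_cpp(mid, P0, burn_in, n_iter) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' First period-doubling bifurcation
#'
#' Locates the smallest growth rate at which the fixed point gives way to a
#' sustained two-value oscillation, by bisecting the period-1/period-2
#' boundary of [attractor_period()] over \[2.5, 3.5\]. Analytically the
#' boundary sits at r = 3.
#'
#' @param resolution Bracket width at which bisection stops; default 1e-4
#'   (must be <= 1e-3).
#' @param burn_in,n_check,tol Passed to [attractor_period()]; the long
#'   default burn-in controls the critical slowing near r = 3.
#' @return The estimated bifurcation growth rate.
#' @export
first_bifurcation <- function(resolution = 1e-4, burn_in = 1e6,
                              n_check = 256, tol = 1e-8) {
  if (resolution > 1e-3) stop("`resolution` must be <= 1e-3", call. = FALSE)
  lo <- 2.5
  hi <- 3.5
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    p <- attractor_period(mid, burn_in = burn_in, n_check = n_check,
                          tol = tol)
    if (p >= 2) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
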
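#' Simulate a plaque trajectory over surveillance visits
#'
#' Iterates the logistic map over `n_visits` discrete visits, with the
#' growth rate supplied either as an explicit per-visit schedule
#' (`r_schedule`) or recomputed each visit from a [growth_aggregate()]
#' (`growth`), including its per-visit increment and lower-bound floor.
#' Exactly one of the two modes must be given. The lumen area follows the
#' positive-remodeling model if `lumen` is supplied, otherwise it stays
#' constant at 1.
#'
#' The returned series include the baseline state, so they have length
#' `n_visits + 1`; `r_series[1]` is `NA` because no growth step leads to the
#' baseline. The first visit at which the burden decreases — the model's
#' signature of plaque erosion/rupture and the beginning of the oscillatory
#' phase — is recorded as `oscillation_onset` (a visit index in
#' `1:n_visits`, or `NA` if the trajectory never decreases).
#'
#' An auxiliary series `stenosis_vs_baseline = P * A / A0` expresses the
#' plaque area relative to the baseline lumen; remodeling lowers the
#' effective stenosis at fixed plaque mass. It is derived output only and
#' never feeds back into the map.
#'
#' @param P0 Initial plaque proportion, strictly inside (0, 1).
#' @param n_visits Number of visits to simulate, >= 1.
#' @param growth A [growth_aggregate()], or `NULL`.
#' @param r_schedule A single growth rate (recycled) or one per visit, or
#'   `NULL`.
#' @param lumen A [remodeling_lumen()], or `NULL` for a constant unit lumen.
#' @return An object of class `plaque_trajectory` with elements `P`, `r`,
#'   `A`, `stenosis_vs_baseline` (numeric, length `n_visits + 1`) and
#'   `oscillation_onset` (integer or `NA`).
#' @examples
#' tr <- simulate_trajectory(0.1, 100, r_schedule = 1.8)
#' tail(tr$P, 1) # ~ (1.8 - 1) / 1.8
#' @export
simulate_trajectory <- function(P0, n_visits, growth = NULL,
                                r_schedule = NULL, lumen = NULL) {
  if (!is.numeric(P0) || length(P0) != 1 || is.na(P0) || P0 <= 0 || P0 >= 1) {
    stop("`P0` must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_visits) || length(n_visits) != 1 || n_visits < 1) {
    stop("`n_visits` must be >= 1", call. = FALSE)
  }
  n_visits <- as.integer(n_visits)
  if (is.null(growth) == is.null(r_schedule)) {
    stop("supply exactly one of `growth` or `r_schedule`", call. = FALSE)
  }
  if (!is.null(growth)) stopifnot(inherits(growth, "growth_aggregate"))
  if (!is.null(r_schedule)) {
    if (!is.numeric(r_schedule) ||
        !(length(r_schedule) %in% c(1L, n_visits))) {
      stop("`r_schedule` must have length 1 or `n_visits`", call. = FALSE)
    }
    r_schedule <- rep_len(r_schedule, n_visits)
  }
  if (!is.null(lumen)) stopifnot(inherits(lumen, "remodeling_lumen"))
  A0 <- if (is.null(lumen)) 1 else lumen$A0

  P <- numeric(n_visits + 1)
  r <- rep(NA_real_, n_visits + 1)
  A <- numeric(n_visits + 1)
  P[1] <- P0
  A[1] <- A0
  for (t in seq_len(n_visits)) {
    rt <- if (is.null(growth)) r_schedule[t] else {
      aggregate_growth_rate(P[t], growth, visit = t)
    }
    if (!is.finite(rt) || rt < 0 || rt > 4) {
      stop(sprintf("growth rate %g outside [0, 4] at visit %d", rt, t),
           call. = FALSE)
    }
    Pt <- rt * P[t] * (1 - P[t])
    if (!is.finite(Pt) || Pt < 0 || Pt > 1) {
      stop(sprintf("plaque proportion left [0, 1] at visit %d", t),
           call. = FALSE)
    }
    P[t + 1] <- Pt
    r[t + 1] <- rt
    A[t + 1] <- if (is.null(lumen)) A[t] else update_lumen(A[t], lumen)
  }
  dec <- which(diff(P) < 0)
  structure(
    list(
      P = P, r = r, A = A,
      stenosis_vs_baseline = P * A / A0,
      oscillation_onset = if (length(dec)) dec[1] else NA_integer_
    ),
    class = "plaque_trajectory"
  )
}

#' @export
print.plaque_trajectory <- function(x, ...) {
  n <- length(x$P) - 1
  cat("<plaque_trajectory>", n, "visits\n")
  cat("  P:", format(x$P[1], digits = 4), "->",
      format(x$P[n + 1], digits = 4), "\n")
  cat("  A:", format(x$A[1], digits = 4), "->",
      format(x$A[n + 1], digits = 4), "\n")
  if (is.na(x$oscillation_onset)) {
    cat("  no decrease in P observed\n")
  } else {
    cat("  first decrease in P at visit", x$oscillation_onset, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.plaque_trajectory <- function(x, ...) {
  data.frame(
    visit = seq_along(x$P) - 1L,
    P = x$P, r = x$r, A = x$A,
    stenosis_vs_baseline = x$stenosis_vs_baseline
  )
}

#' Estimate growth rates from serial measurements
#'
#' Inverts the logistic recurrence for each consecutive pair of planimetric
#' measurements: \eqn{\hat r_t = P_{t+1} / (P_t (1 - P_t))}. This is the
#' route by which repeated ultrasound surveillance can be turned into a
#' per-interval growth-rate estimate. Intervals whose starting measurement
#' is exactly 0 or 1 leave the rate undefined; these are flagged (returned
#' as `NA` with flag `"undefined"`) rather than dropped, so interval
#' indexing is preserved.
#'
#' @param P_measurements Numeric vector of plaque proportions in \[0, 1\],
#'   length >= 2.
#' @return Numeric vector of growth-rate estimates, one per consecutive
#'   interval (length `length(P_measurements) - 1`), with a character
#'   attribute `"flag"` (`"ok"` or `"undefined"` per interval).
#' @examples
#' estimate_r_series(c(0.1, 0.162)) # 1.8
#' @export
estimate_r_series <- function(P_measurements) {
  P <- P_measurements
  if (!is.numeric(P) || length(P) < 2 || anyNA(P) || any(P < 0 | P > 1)) {
    stop("`P_measurements` must be >= 2 proportions in [0, 1]",
         call. = FALSE)
  }
  n <- length(P) - 1
  from <- P[seq_len(n)]
  to <- P[seq_len(n) + 1]
  denom <- from * (1 - from)
  r_hat <- ifelse(denom == 0, NA_real_, to / denom)
  attr(r_hat, "flag") <- ifelse(denom == 0, "undefined", "ok")
  r_hat
}

#' Classify plaque risk from growth-rate estimates
#'
#' Labels a plaque `UNSTABLE` when the summarized growth-rate estimate
#' strictly exceeds the threshold (default 2, the rate above which the map
#' enters its fluctuating/oscillatory regimes), else `STABLE`. The summary
#' is the latest defined estimate by default, or the trailing mean of all
#' defined estimates.
#'
#' @param r_estimates Growth-rate estimates, e.g. from
#'   [estimate_r_series()]; `NA` (undefined) entries are ignored.
#' @param threshold Instability threshold, default 2; strict inequality.
#' @param summary `"latest"` (default) or `"mean"`.
#' @return `"STABLE"` or `"UNSTABLE"`.
#' @examples
#' classify_plaque_risk(c(1.8, 2.1)) # "UNSTABLE"
#' classify_plaque_risk(2.0)         # "STABLE" (strict threshold)
#' @export
classify_plaque_risk <- function(r_estimates, threshold = 2,
                                 summary = c("latest", "mean")) {
  summary <- match.arg(summary)
  r <- r_estimates[!is.na(r_estimates)]
  if (length(r) == 0) {
    stop("all growth-rate estimates are undefined; cannot classify",
         call. = FALSE)
  }
  value <- switch(summary, latest = r[length(r)], mean = mean(r))
  if (value > threshold) "UNSTABLE" else "STABLE"
}
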
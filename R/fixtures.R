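#' Generate a synthetic surveillance measurement series
#'
#' Emulates serial planimetric plaque measurements: a noiseless trajectory
#' is simulated under a constant or additively drifting growth rate, then
#' additive Gaussian measurement noise (truncated by rejection so observed
#' proportions stay strictly inside (0, 1)) is applied to every visit.
#' The generating growth rate of each interval travels with the result so
#' parameter-recovery studies can compare [estimate_r_series()] output
#' against truth.
#'
#' @param n_visits Number of follow-up visits (>= 2); the series has
#'   `n_visits + 1` rows including baseline.
#' @param P0 Baseline plaque proportion, default 0.1.
#' @param r Generating growth rate at the first interval, default 1.8.
#' @param increment Additive per-visit drift of the growth rate, default 0.
#' @param noise_sd Standard deviation of the measurement noise on P,
#'   >= 0; default 0.01 (roughly sub-resolution of surveillance imaging).
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @param patient_id Identifier written into the series.
#' @return A data frame with columns `patient_id`, `visit_index` (0-based),
#'   `P` (observed), and attributes `P_true` (noiseless series) and
#'   `r_true` (generating rate per interval).
#' @examples
#' s <- generate_measurement_series(10, noise_sd = 0, seed = 1)
#' estimate_r_series(s$P) # all 1.8
#' @export
generate_measurement_series <- function(n_visits = 20, P0 = 0.1, r = 1.8,
                                        increment = 0, noise_sd = 0.01,
                                        seed = NULL, patient_id = "P01") {
  if (n_visits < 2) stop("`n_visits` must be >= 2", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  schedule <- r + increment * (seq_len(n_visits) - 1)
  traj <- simulate_trajectory(P0, n_visits, r_schedule = schedule)
  P_true <- traj$P
  P_obs <- P_true
  if (noise_sd > 0) {
    for (i in seq_along(P_obs)) {
      repeat {
        cand <- P_true[i] + stats::rnorm(1, sd = noise_sd)
        if (cand > 0 && cand < 1) break
      }
      P_obs[i] <- cand
    }
  }
  out <- data.frame(
    patient_id = patient_id,
    visit_index = seq_along(P_obs) - 1L,
    P = P_obs
  )
  attr(out, "P_true") <- P_true
  attr(out, "r_true") <- schedule
  out
}

# moving-average smoothing with edge truncation; half-width h in sites
ma_smooth <- function(mat, h) {
  if (h < 1) return(mat)
  nr <- nrow(mat)
  nc <- ncol(mat)
  out <- mat
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rs <- max(1, r - h):min(nr, r + h)
      cs <- max(1, c - h):min(nc, c + h)
      out[r, c] <- mean(mat[rs, cs])
    }
  }
  out
}

#' Generate a synthetic covariate grid
#'
#' Seeded random covariate fields for a plaque-surface lattice: white
#' Gaussian noise around each covariate's mean, optionally smoothed by a
#' moving-average filter of half-width `corr_range` to induce spatial
#' correlation, clipped at zero (covariates are non-negative scores). An
#' optional hotspot adds a constant boost to one covariate inside a
#' rectangular region, emulating a focal inflamed area.
#'
#' @param height,width Lattice dimensions.
#' @param means Named means for `I`, `L`, `S`, `B`; default all 1.
#' @param sd Noise standard deviation (before smoothing), default 0.3.
#' @param corr_range Moving-average half-width in sites; 0 (default)
#'   leaves sites uncorrelated.
#' @param hotspot Optional `list(rows =, cols =, covariate =, boost =)`
#'   adding `boost` to `covariate` over the index ranges `rows`/`cols`.
#' @param seed Optional integer seed.
#' @param adjacency,periodic Passed to [plaque_grid()].
#' @return A [plaque_grid()] (all sites initially stable).
#' @examples
#' g <- generate_covariate_grid(4, 4, seed = 1)
#' @export
generate_covariate_grid <- function(height, width,
                                    means = c(I = 1, L = 1, S = 1, B = 1),
                                    sd = 0.3, corr_range = 0,
                                    hotspot = NULL, seed = NULL,
                                    adjacency = "von_neumann",
                                    periodic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  means <- means[c("I", "L", "S", "B")]
  if (anyNA(means)) {
    stop("`means` must name all of I, L, S, B", call. = FALSE)
  }
  fields <- lapply(means, function(mu) {
    f <- matrix(stats::rnorm(height * width, mean = mu, sd = sd),
                height, width)
    f <- ma_smooth(f, round(corr_range))
    pmax(f, 0)
  })
  if (!is.null(hotspot)) {
    cv <- hotspot$covariate %||% "I"
    if (!cv %in% names(fields)) {
      stop("hotspot covariate must be one of I, L, S, B", call. = FALSE)
    }
    fields[[cv]][hotspot$rows, hotspot$cols] <-
      fields[[cv]][hotspot$rows, hotspot$cols] + hotspot$boost
  }
  plaque_grid(fields$I, fields$L, fields$S, fields$B,
              adjacency = adjacency, periodic = periodic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
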
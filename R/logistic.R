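#' One step of the logistic map
#'
#' Advances the plaque burden one surveillance visit under the logistic
#' recurrence \eqn{P_{t+1} = r P_t (1 - P_t)}, where `P` is the proportion
#' of the arterial lumen occupied by plaque and `r` is the net growth rate.
#' For `r` in \[0, 4\] the unit interval maps into itself, so burdens stay
#' interpretable as proportions.
#'
#' @param P Plaque proportion(s) in \[0, 1\].
#' @param r Growth rate(s) in \[0, 4\].
#' @return The next plaque proportion, same length as the longer input.
#' @examples
#' logistic_step(0.1, 1.8) # 0.162
#' @export
logistic_step <- function(P, r) {
  if (!is.numeric(P) || anyNA(P) || any(P < 0 | P > 1)) {
    stop("`P` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(r) || anyNA(r) || any(r < 0 | r > 4)) {
    stop("`r` must lie in [0, 4]", call. = FALSE)
  }
  r * P * (1 - P)
}

#' Fixed point of the logistic map
#'
#' The non-trivial equilibrium \eqn{(r - 1)/r} toward which trajectories
#' converge for growth rates between 1 and 3; for \eqn{r \le 1} the plaque
#' regresses to extinction and the fixed point is 0.
#'
#' @param r Growth rate(s), strictly positive.
#' @return Equilibrium plaque proportion(s).
#' @examples
#' fixed_point(1.8) # 0.4444...
#' @export
fixed_point <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r <= 0)) {
    stop("`r` must be > 0", call. = FALSE)
  }
  ifelse(r <= 1, 0, (r - 1) / r)
}

#' @rdname classify_regime
#' @format NULL
#' @export
REGIME_LABELS <- c(
  "EXTINCTION", "MONOTONE_CONVERGENCE", "TRANSIENT_FLUCTUATION",
  "PERIODIC", "CHAOTIC"
)

#' Classify the dynamical regime of a growth rate
#'
#' Maps a growth rate to the qualitative behavior of the logistic map:
#' regression to zero (`EXTINCTION`, r in (0, 1\]), monotone convergence to
#' \eqn{(r-1)/r} (`MONOTONE_CONVERGENCE`, r in (1, 2\]), damped fluctuation
#' around the fixed point (`TRANSIENT_FLUCTUATION`, r in (2, 3\]), sustained
#' oscillation through the period-doubling cascade (`PERIODIC`, r in
#' (3, chaos onset)), and chaos at and above the accumulation point
#' (`CHAOTIC`). Boundary rates (exactly 1, 2, 3) fall in the lower regime;
#' note that plaque instability is defined by the strict condition r > 2.
#'
#' @param r Growth rate(s), strictly positive.
#' @param chaos_onset_value Growth rate at which chaos begins; the
#'   period-doubling accumulation point, default 3.56995. Must lie in (3, 4).
#' @return Character vector of regime labels (levels in `REGIME_LABELS`),
#'   with the corresponding fixed points attached as attribute
#'   `"fixed_point"` (NA where no point attracts).
#' @examples
#' classify_regime(c(1.8, 2.8, 3.8))
#' @export
classify_regime <- function(r, chaos_onset_value = 3.56995) {
  if (!is.numeric(r) || anyNA(r) || any(r <= 0)) {
    stop("`r` must be > 0", call. = FALSE)
  }
  if (chaos_onset_value <= 3 || chaos_onset_value >= 4) {
    stop("`chaos_onset_value` must lie in (3, 4)", call. = FALSE)
  }
  label <- ifelse(r <= 1, "EXTINCTION",
    ifelse(r <= 2, "MONOTONE_CONVERGENCE",
      ifelse(r <= 3, "TRANSIENT_FLUCTUATION",
        ifelse(r < chaos_onset_value, "PERIODIC", "CHAOTIC")
      )
    )
  )
  fp <- ifelse(r <= 3, fixed_point(r), NA_real_)
  attr(label, "fixed_point") <- fp
  label
}

#' Proportion of growth rates that destabilize a plaque
#'
#' For a plaque of burden `P`, the fraction of growth rates `r` drawn
#' uniformly from \[0, `r_max`\] for which the next visit shows a decrease,
#' i.e. \eqn{r P (1 - P) < P}. A decrease marks the onset of the oscillatory
#' phase that the model identifies with plaque erosion or rupture, so this
#' curve quantifies how inherently unstable the map becomes as the stenotic
#' degree grows: it rises roughly exponentially in `P` and saturates at 1
#' around \eqn{P \approx 0.7}.
#'
#' The condition reduces to \eqn{r < 1/(1 - P)}, giving the closed form
#' \eqn{\min(1, 1/(r_{max}(1 - P)))}. A brute-force grid evaluation is
#' available as an independent cross-check.
#'
#' @param P Plaque proportion(s) strictly inside (0, 1); the boundaries are
#'   degenerate (no plaque / total occlusion) and rejected.
#' @param r_max Upper bound of the growth-rate range considered, default 3.5
#'   (above which the map is predominantly chaotic).
#' @param method `"closed_form"` (default) or `"grid"` for a uniform grid of
#'   `n_grid` rates.
#' @param n_grid Number of grid points for `method = "grid"`.
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' instability_proportion(0.5)        # 0.5714...
#' instability_proportion(0.72)       # 1
#' @export
instability_proportion <- function(P, r_max = 3.5,
                                   method = c("closed_form", "grid"),
                                   n_grid = 1e6) {
  method <- match.arg(method)
  if (!is.numeric(P) || anyNA(P) || any(P <= 0 | P >= 1)) {
    stop("`P` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(r_max) || length(r_max) != 1 || r_max <= 0) {
    stop("`r_max` must be a single value > 0", call. = FALSE)
  }
  if (method == "closed_form") {
    pmin(1, 1 / (r_max * (1 - P)))
  } else {
    r <- seq(0, r_max, length.out = n_grid)
    vapply(P, function(p) mean(r * p * (1 - p) < p), numeric(1))
  }
}

#' Instability proportion across the stenosis range
#'
#' Evaluates [instability_proportion()] on a grid of plaque burdens,
#' reproducing the instability-versus-stenosis curve.
#'
#' @param P_values Grid of plaque proportions in (0, 1).
#' @param r_max Growth-rate upper bound passed on.
#' @return A data frame with columns `P` and `proportion`.
#' @export
instability_curve <- function(P_values = seq(0.01, 0.99, by = 0.01),
                              r_max = 3.5) {
  data.frame(
    P = P_values,
    proportion = instability_proportion(P_values, r_max = r_max)
  )
}
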
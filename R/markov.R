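#' Covariate profile of a plaque site
#'
#' The four site-level covariates entering the transition model:
#' inflammation level `I`, lipid content `L`, shear stress `S` and plaque
#' burden `B`, all as dimensionless non-negative scores.
#'
#' @param I,L,S,B Finite, non-negative scores.
#' @return An object of class `covariate_profile`.
#' @export
covariate_profile <- function(I = 0, L = 0, S = 0, B = 0) {
  v <- c(I = I, L = L, S = S, B = B)
  if (!is.numeric(v) || length(v) != 4 || any(!is.finite(v)) || any(v < 0)) {
    stop("covariates I, L, S, B must be finite and non-negative",
         call. = FALSE)
  }
  structure(as.list(v), class = "covariate_profile")
}

#' Transition-model weights
#'
#' Base probability and covariate weights of the linear transition model:
#' `base + w1*I + w2*L + w3*S + w4*B` for the aspatial chain, plus
#' `w5 * D` where `D` is the spatial-dependence contribution of a site's
#' neighbors (used only by the spatial model).
#'
#' @param base Base probability in \[0, 1\].
#' @param w1,w2,w3,w4 Weights for inflammation, lipid content, shear
#'   stress and plaque burden.
#' @param w5 Weight of the spatial-dependence term.
#' @return An object of class `transition_weights`.
#' @export
transition_weights <- function(base, w1 = 0, w2 = 0, w3 = 0, w4 = 0,
                               w5 = 0) {
  if (!is.numeric(base) || length(base) != 1 || !is.finite(base) ||
      base < 0 || base > 1) {
    stop("`base` must be a probability in [0, 1]", call. = FALSE)
  }
  w <- c(w1, w2, w3, w4, w5)
  if (!is.numeric(w) || length(w) != 5 || any(!is.finite(w))) {
    stop("weights w1..w5 must be finite", call. = FALSE)
  }
  structure(
    list(base = base, w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5),
    class = "transition_weights"
  )
}

#' Covariate-weighted transition probability (stable to unstable)
#'
#' The probability that a stable plaque (site) becomes unstable:
#' `base + w1*I + w2*L + w3*S + w4*B + w5*D_term`. The linear form can
#' leave \[0, 1\]; with the default `link = "linear"` the value is clamped
#' to the probability scale and the event is recorded in the `"clamped"`
#' attribute, so callers can count and surface misconfigured weights
#' instead of hiding them. `link = "logistic"` applies the same linear
#' predictor on the log-odds scale (`plogis(qlogis(base) + sum)`), which
#' never needs clamping.
#'
#' @param profile A [covariate_profile()].
#' @param weights A [transition_weights()].
#' @param D_term Spatial-dependence contribution in \[0, 1\] (weighted
#'   fraction of unstable neighbors); default 0 recovers the aspatial
#'   model.
#' @param link `"linear"` (default, clamped) or `"logistic"`.
#' @return A probability with logical attribute `"clamped"`.
#' @examples
#' w <- transition_weights(0.05, 0.1, 0.1, 0.1, 0.1)
#' transition_probability(covariate_profile(1, 1, 1, 1), w) # 0.45
#' @export
transition_probability <- function(profile, weights, D_term = 0,
                                   link = c("linear", "logistic")) {
  link <- match.arg(link)
  stopifnot(inherits(profile, "covariate_profile"),
            inherits(weights, "transition_weights"))
  if (!is.numeric(D_term) || length(D_term) != 1 || !is.finite(D_term)) {
    stop("`D_term` must be a single finite value", call. = FALSE)
  }
  lp <- weights$w1 * profile$I + weights$w2 * profile$L +
    weights$w3 * profile$S + weights$w4 * profile$B +
    weights$w5 * D_term
  if (link == "linear") {
    raw <- weights$base + lp
    p <- min(1, max(0, raw))
    clamped <- raw < 0 || raw > 1
  } else {
    p <- stats::plogis(stats::qlogis(weights$base) + lp)
    clamped <- FALSE
  }
  attr(p, "clamped") <- clamped
  p
}

#' Two-state transition matrix for plaque stability
#'
#' Builds the row-stochastic 2x2 matrix of the stable/unstable chain from
#' the two off-diagonal transition probabilities: stable to unstable
#' (`p_su`) and unstable to stable (`p_us`). State order is Stable then
#' Unstable throughout the package.
#'
#' @param p_su,p_us Transition probabilities in \[0, 1\].
#' @return An object of class `two_state_matrix` with elements `p_su`,
#'   `p_us` and `matrix` (2x2, dimnames `S`/`U`).
#' @examples
#' two_state_matrix(0.1, 0.3)$matrix
#' @export
two_state_matrix <- function(p_su, p_us) {
  p <- c(p_su, p_us)
  if (!is.numeric(p) || length(p) != 2 || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p_su` and `p_us` must be probabilities in [0, 1]", call. = FALSE)
  }
  m <- matrix(c(1 - p_su, p_us, p_su, 1 - p_us), nrow = 2,
              dimnames = list(c("S", "U"), c("S", "U")))
  structure(list(p_su = p_su, p_us = p_us, matrix = m),
            class = "two_state_matrix")
}

#' @export
print.two_state_matrix <- function(x, ...) {
  cat("<two_state_matrix> p_su =", x$p_su, " p_us =", x$p_us, "\n")
  print(x$matrix)
  invisible(x)
}

#' Stationary distribution of the stability chain
#'
#' The long-run state-occupancy probabilities, computed as the left
#' eigenvector of the transition matrix associated with eigenvalue 1,
#' normalized to sum to one. A unique stationary distribution requires the
#' chain to mix: the degenerate cases `p_su = p_us = 0` (no transitions at
#' all; every distribution is stationary) and `p_su = p_us = 1`
#' (deterministic alternation; period 2) are rejected.
#'
#' @param m A [two_state_matrix()].
#' @return An object of class `stationary_distribution` with elements
#'   `pi_S`, `pi_U` and the `eigenvalue` the eigenvector was taken from
#'   (equal to 1 up to numerical error).
#' @examples
#' stationary_distribution(two_state_matrix(0.1, 0.3)) # pi_S = 0.75
#' @export
stationary_distribution <- function(m) {
  stopifnot(inherits(m, "two_state_matrix"))
  if (m$p_su == 0 && m$p_us == 0) {
    stop(paste("chain never leaves either state (p_su = p_us = 0):",
               "not irreducible, no unique stationary distribution"),
         call. = FALSE)
  }
  if (m$p_su == 1 && m$p_us == 1) {
    stop(paste("chain alternates deterministically (p_su = p_us = 1):",
               "periodic, no unique stationary distribution"),
         call. = FALSE)
  }
  e <- eigen(t(m$matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  pi <- v / sum(v)
  structure(
    list(pi_S = pi[1], pi_U = pi[2], eigenvalue = Re(e$values[i])),
    class = "stationary_distribution"
  )
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("<stationary_distribution> pi_S =", format(x$pi_S, digits = 6),
      " pi_U =", format(x$pi_U, digits = 6), "\n")
  invisible(x)
}

#' Event probabilities under a constant hazard
#'
#' Under a constant hazard `alpha_su` of destabilization per unit time, the
#' probability of remaining stable through time `t` is `exp(-alpha_su * t)`
#' and the probability of an event by `t` is its complement. The two
#' components sum to one by construction.
#'
#' Note the deliberate double bookkeeping in this model family: `alpha_su`
#' appears both as a one-step transition probability (in
#' [two_state_matrix()]) and as a continuous-time hazard (here). The two
#' readings are kept in separate operations with separate parameters;
#' convert explicitly with [hazard_from_step_probability()].
#'
#' @param alpha_su Hazard of destabilization per unit time, >= 0.
#' @param t Elapsed time, >= 0. Vectorized with the usual recycling.
#' @return A list with components `p_stay` and `p_event`.
#' @examples
#' event_probabilities(0.5, 2) # p_stay = exp(-1)
#' @export
event_probabilities <- function(alpha_su, t) {
  if (!is.numeric(alpha_su) || anyNA(alpha_su) || any(alpha_su < 0)) {
    stop("`alpha_su` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("`t` must be >= 0", call. = FALSE)
  }
  p_stay <- exp(-alpha_su * t)
  list(p_stay = p_stay, p_event = 1 - p_stay)
}

#' Convert between one-step probabilities and hazards
#'
#' `hazard_from_step_probability()` returns the continuous-time hazard
#' `-log(1 - p)` that reproduces a one-step transition probability `p` over
#' a unit interval; `step_probability_from_hazard()` is its inverse.
#'
#' @param p One-step transition probability in \[0, 1).
#' @param hazard Hazard per unit time, >= 0.
#' @return The converted quantity.
#' @export
hazard_from_step_probability <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p >= 1)) {
    stop("`p` must lie in [0, 1)", call. = FALSE)
  }
  -log(1 - p)
}

#' @rdname hazard_from_step_probability
#' @export
step_probability_from_hazard <- function(hazard) {
  if (!is.numeric(hazard) || anyNA(hazard) || any(hazard < 0)) {
    stop("`hazard` must be >= 0", call. = FALSE)
  }
  1 - exp(-hazard)
}

#' Simulate the stability chain
#'
#' Monte-Carlo simulation of the two-state chain; over long runs the
#' empirical state frequencies converge to the stationary distribution.
#'
#' @param m A [two_state_matrix()].
#' @param n_steps Number of steps, >= 1.
#' @param seed Optional integer seed (`set.seed()` is called when given);
#'   the same seed yields the identical sequence.
#' @param initial Starting state, `"S"` or `"U"`.
#' @return Character vector of visited states (`"S"`/`"U"`), one per step.
#' @examples
#' s <- simulate_chain(two_state_matrix(0.1, 0.3), 1000, seed = 1)
#' mean(s == "S") # ~ 0.75
#' @export
simulate_chain <- function(m, n_steps, seed = NULL, initial = c("S", "U")) {
  stopifnot(inherits(m, "two_state_matrix"))
  initial <- match.arg(initial)
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    stop("`n_steps` must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  states <- simulate_chain_cpp(m$p_su, m$p_us, as.integer(n_steps),
                               if (initial == "S") 0L else 1L)
  c("S", "U")[states + 1L]
}
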
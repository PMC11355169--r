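#' Factor functions for the aggregate growth rate
#'
#' Small library of functional forms for the factor terms \eqn{f_i(P)} in
#' the aggregate growth rate: hemodynamic, inflammatory, mechanical and
#' metabolic influences are each summarized as a function of the current
#' plaque burden. `factor_constant()` gives a burden-independent influence,
#' `factor_linear()` one that scales with burden (e.g. plaque attracting
#' further build-up), and `factor_saturating()` a Michaelis-Menten-type
#' response `P / (P + half)` that plateaus for large plaques.
#'
#' @param value Constant value returned for every `P`.
#' @param slope,intercept Coefficients of `intercept + slope * P`.
#' @param half Burden at which the saturating response reaches one half.
#' @return A function of `P`.
#' @name growth_factors
#' @examples
#' f <- factor_saturating(half = 0.5)
#' f(0.5) # 0.5
NULL

#' @rdname growth_factors
#' @export
factor_constant <- function(value = 1) {
  force(value)
  function(P) rep_len(value, length(P))
}

#' @rdname growth_factors
#' @export
factor_linear <- function(slope = 1, intercept = 0) {
  force(slope); force(intercept)
  function(P) intercept + slope * P
}

#' @rdname growth_factors
#' @export
factor_saturating <- function(half = 0.5) {
  force(half)
  function(P) P / (P + half)
}

#' Aggregate growth-rate specification
#'
#' Bundles the baseline growth rate with the weighted factor terms defining
#' the dynamic growth rate
#' \deqn{r(P) = \alpha (1 + \beta_1 f_1(P) + \beta_2 f_2(P) +
#'   \beta_3 f_3(P) + \beta_4 f_4(P)).}
#' Because lesions rarely regress once a predilection site is established,
#' the realized rate is floored at `r_lower_bound` (default 1). The optional
#' per-visit increment models a secular drift of the net growth rate across
#' generations (e.g. +0.05 per visit for a plaque that slowly destabilizes);
#' it is applied after the factor aggregation and before the floor.
#'
#' @param alpha Baseline growth rate, > 0.
#' @param betas Four weighting coefficients \eqn{\beta_1 \ldots \beta_4}.
#' @param factors List of four factor functions \eqn{f_1 \ldots f_4}
#'   mapping a burden in \[0, 1\] to a real number.
#' @param r_lower_bound Floor on the emitted rate, or `NULL` for none.
#'   Default 1.
#' @param r_increment Per-visit additive (or multiplicative) change of the
#'   effective rate; default 0.
#' @param increment_mode `"additive"` (default): `r + r_increment * (visit - 1)`;
#'   `"multiplicative"`: `r * (1 + r_increment)^(visit - 1)`.
#' @return An object of class `growth_aggregate`.
#' @seealso [aggregate_growth_rate()], [simulate_trajectory()]
#' @export
growth_aggregate <- function(alpha,
                             betas = c(0, 0, 0, 0),
                             factors = list(
                               factor_constant(), factor_constant(),
                               factor_constant(), factor_constant()
                             ),
                             r_lower_bound = 1,
                             r_increment = 0,
                             increment_mode = c("additive", "multiplicative")) {
  increment_mode <- match.arg(increment_mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(betas) || length(betas) != 4 || anyNA(betas) ||
      any(!is.finite(betas))) {
    stop("`betas` must be four finite coefficients", call. = FALSE)
  }
  if (!is.list(factors) || length(factors) != 4 ||
      !all(vapply(factors, is.function, logical(1)))) {
    stop("`factors` must be a list of four functions", call. = FALSE)
  }
  if (!is.null(r_lower_bound) &&
      (!is.numeric(r_lower_bound) || length(r_lower_bound) != 1 ||
       !is.finite(r_lower_bound))) {
    stop("`r_lower_bound` must be a single finite value or NULL",
         call. = FALSE)
  }
  structure(
    list(
      alpha = alpha, betas = betas, factors = factors,
      r_lower_bound = r_lower_bound, r_increment = r_increment,
      increment_mode = increment_mode
    ),
    class = "growth_aggregate"
  )
}

#' Evaluate the aggregate growth rate
#'
#' Computes \eqn{r(P) = \alpha (1 + \sum_i \beta_i f_i(P))}, applies the
#' per-visit increment for the given visit, and finally clamps at the lower
#' bound (and at 0, since a negative net growth rate has no meaning in the
#' map). The order — aggregate, then increment, then floor — is fixed.
#'
#' @param P Plaque proportion in \[0, 1\].
#' @param g A [growth_aggregate()].
#' @param visit 1-based visit index used for the increment; visit 1 applies
#'   no increment.
#' @return The realized growth rate.
#' @examples
#' g <- growth_aggregate(alpha = 1, betas = c(0.5, 0, 0, 0),
#'                       r_lower_bound = NULL)
#' aggregate_growth_rate(0.3, g) # 1.5
#' @export
aggregate_growth_rate <- function(P, g, visit = 1) {
  stopifnot(inherits(g, "growth_aggregate"))
  if (!is.numeric(P) || length(P) != 1 || is.na(P) || P < 0 || P > 1) {
    stop("`P` must be a single value in [0, 1]", call. = FALSE)
  }
  s <- 1
  for (i in seq_len(4)) {
    fi <- g$factors[[i]](P)
    if (!is.numeric(fi) || length(fi) != 1 || !is.finite(fi)) {
      stop(sprintf("factor f%d evaluated to a non-finite value at P = %g",
                   i, P), call. = FALSE)
    }
    s <- s + g$betas[i] * fi
  }
  r <- g$alpha * s
  if (visit > 1 && g$r_increment != 0) {
    r <- switch(g$increment_mode,
      additive = r + g$r_increment * (visit - 1),
      multiplicative = r * (1 + g$r_increment)^(visit - 1)
    )
  }
  r <- max(0, r)
  if (!is.null(g$r_lower_bound)) r <- max(g$r_lower_bound, r)
  r
}

#' Positive-remodeling lumen model
#'
#' In early disease the arterial wall remodels outward so that the lumen
#' area expands from its initial value `A0` toward a maximal remodeled area
#' `Amax`, preserving perfusion. The approach is geometric: each visit the
#' remaining gap to `Amax` shrinks by the factor `rate`.
#'
#' @param A0 Initial lumen area, > 0 (arbitrary area units).
#' @param Amax Maximal remodeled area, >= `A0`.
#' @param rate Per-visit approach rate in (0, 1\].
#' @return An object of class `remodeling_lumen`.
#' @export
remodeling_lumen <- function(A0, Amax, rate = 0.25) {
  if (!is.numeric(A0) || length(A0) != 1 || !is.finite(A0) || A0 <= 0) {
    stop("`A0` must be a single value > 0", call. = FALSE)
  }
  if (!is.numeric(Amax) || length(Amax) != 1 || !is.finite(Amax) ||
      Amax < A0) {
    stop("`Amax` must be a single value >= A0", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) ||
      rate <= 0 || rate > 1) {
    stop("`rate` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(A0 = A0, Amax = Amax, rate = rate),
            class = "remodeling_lumen")
}

#' Advance the lumen area one visit
#'
#' One step of the geometric approach `A + rate * (Amax - A)`: monotone
#' non-decreasing, with `Amax` as its fixed point and limit.
#'
#' @param A Current lumen area, within \[`A0`, `Amax`\].
#' @param lum A [remodeling_lumen()].
#' @return The lumen area at the next visit.
#' @examples
#' update_lumen(10, remodeling_lumen(10, 14, rate = 0.5)) # 12
#' @export
update_lumen <- function(A, lum) {
  stopifnot(inherits(lum, "remodeling_lumen"))
  if (!is.numeric(A) || length(A) != 1 || is.na(A) ||
      A < lum$A0 || A > lum$Amax) {
    stop("`A` must lie in [A0, Amax]", call. = FALSE)
  }
  A + lum$rate * (lum$Amax - A)
}
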
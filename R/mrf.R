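#' Markov random field over a plaque-surface lattice
#'
#' Defines a Gibbs distribution over complete stability configurations of a
#' `height` x `width` lattice through the energy function
#' \deqn{E(config) = \sum_i V(s_i) + \sum_{(i,j)} U(s_i, s_j),}
#' where `V` is the site potential, `U` the pair potential over neighboring
#' sites (each undirected edge counted once), and
#' \eqn{P(config) \propto e^{-\beta E(config)}}. Lower-energy
#' configurations are more probable.
#'
#' `V` may be a named pair `c(S = ., U = .)` shared by all sites or an
#' n x 2 matrix of per-site potentials (rows in row-major site order),
#' which is how covariate information enters the field. `U` is a 2x2
#' matrix indexed by the two states in order S, U; it must be symmetric
#' because the adjacency is undirected.
#'
#' @param height,width Lattice dimensions.
#' @param V Site potentials: named numeric `c(S = , U = )` or an n x 2
#'   matrix (columns S, U).
#' @param U Pair potential: symmetric 2x2 numeric matrix.
#' @param beta Inverse-temperature scaling of the energy, default 1.
#' @param adjacency `"von_neumann"` (default) or `"moore"`.
#' @param periodic Wrap lattice edges? Default `FALSE`.
#' @return An object of class `mrf_model`.
#' @seealso [ising_model()] for the standard two-parameter family,
#'   [energy()], [exact_distribution()], [gibbs_sample()],
#'   [marginal_instability()].
#' @export
mrf_model <- function(height, width, V, U, beta = 1,
                      adjacency = c("von_neumann", "moore"),
                      periodic = FALSE) {
  adjacency <- match.arg(adjacency)
  n <- as.integer(height) * as.integer(width)
  if (n < 1) stop("lattice must have at least one site", call. = FALSE)
  if (is.matrix(V)) {
    if (!identical(dim(V), c(n, 2L)) || any(!is.finite(V))) {
      stop("matrix `V` must be n x 2 and finite", call. = FALSE)
    }
    Vmat <- V
  } else {
    if (length(V) != 2 || any(!is.finite(V))) {
      stop("`V` must be two finite potentials (states S, U)", call. = FALSE)
    }
    if (!is.null(names(V))) V <- V[c("S", "U")]
    Vmat <- matrix(rep(as.numeric(V), each = n), nrow = n)
  }
  if (!is.matrix(U) || !identical(dim(U), c(2L, 2L)) ||
      any(!is.finite(U))) {
    stop("`U` must be a finite 2x2 matrix", call. = FALSE)
  }
  if (abs(U[1, 2] - U[2, 1]) > 1e-12) {
    stop("`U` must be symmetric (undirected adjacency)", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta)) {
    stop("`beta` must be a single finite value", call. = FALSE)
  }
  nbrs <- lattice_neighbors(height, width, adjacency, periodic)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- nbrs[[i]]
    js <- js[js > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  structure(
    list(
      height = as.integer(height), width = as.integer(width), n_sites = n,
      V = Vmat, U = U, beta = beta, neighbors = nbrs, edges = edges,
      adjacency = adjacency, periodic = periodic
    ),
    class = "mrf_model"
  )
}

#' Ising-family field for plaque stability
#'
#' The simplest potential family consistent with joint stability of
#' neighboring plaque regions: a site potential `v_u` penalizing (or, if
#' negative, favoring) the unstable state, and an attractive coupling
#' `U(s, s') = -J` when neighboring states agree (`J >= 0` makes
#' neighboring sites tend to share their stability state). An optional
#' per-site field `v_site` is added to the unstable-state potential, e.g.
#' a covariate-linear predictor, so that the field nests the covariate
#' transition model.
#'
#' @param height,width Lattice dimensions.
#' @param v_u Potential of the unstable state (stable state has 0).
#' @param J Agreement coupling, >= 0 for attraction.
#' @param v_site Optional numeric vector (length n, row-major) or matrix
#'   (`height` x `width`) added to each site's unstable-state potential.
#' @param beta,adjacency,periodic Passed to [mrf_model()].
#' @return An `mrf_model`.
#' @examples
#' m <- ising_model(3, 3, v_u = 0.5, J = 0.2)
#' @export
ising_model <- function(height, width, v_u = 0, J = 0, v_site = NULL,
                        beta = 1, adjacency = "von_neumann",
                        periodic = FALSE) {
  if (J < 0) stop("`J` must be >= 0 (attractive coupling)", call. = FALSE)
  n <- as.integer(height) * as.integer(width)
  Vmat <- matrix(c(rep(0, n), rep(v_u, n)), nrow = n)
  if (!is.null(v_site)) {
    if (is.matrix(v_site)) v_site <- as.vector(t(v_site))
    if (length(v_site) != n) {
      stop("`v_site` must supply one value per site", call. = FALSE)
    }
    Vmat[, 2] <- Vmat[, 2] + v_site
  }
  U <- matrix(c(-J, 0, 0, -J), nrow = 2)
  mrf_model(height, width, V = Vmat, U = U, beta = beta,
            adjacency = adjacency, periodic = periodic)
}

# coerce a configuration to a 0/1 vector in row-major site order
config_to_int <- function(config, m) {
  if (is.matrix(config)) config <- as.vector(t(config))
  if (is.character(config)) {
    if (!all(config %in% c("S", "U"))) {
      stop("states must be \"S\" or \"U\"", call. = FALSE)
    }
    config <- as.integer(config == "U")
  }
  if (length(config) != m$n_sites || anyNA(config) ||
      !all(config %in% c(0L, 1L))) {
    stop("`config` must assign a state (S/U or 0/1) to every site",
         call. = FALSE)
  }
  as.integer(config)
}

#' Energy of a stability configuration
#'
#' Evaluates \eqn{E(config) = \sum_i V(s_i) + \sum_{(i,j)} U(s_i, s_j)}
#' with the pair sum running once over each undirected lattice edge.
#'
#' @param config Complete state assignment: character vector/matrix of
#'   `"S"`/`"U"` or 0/1 integers (0 = S), row-major site order.
#' @param m An [mrf_model()].
#' @return The (dimensionless) energy, before any `beta` scaling.
#' @examples
#' m <- ising_model(1, 2, J = 1)
#' energy(c("S", "S"), m) # -1
#' @export
energy <- function(config, m) {
  stopifnot(inherits(m, "mrf_model"))
  s <- config_to_int(config, m)
  e <- sum(m$V[cbind(seq_len(m$n_sites), s + 1L)])
  if (nrow(m$edges)) {
    e <- e + sum(m$U[cbind(s[m$edges[, 1]] + 1L, s[m$edges[, 2]] + 1L)])
  }
  e
}

#' Exact Gibbs distribution by enumeration
#'
#' Enumerates all \eqn{2^n} stability configurations of a small lattice,
#' computes \eqn{e^{-\beta E}} for each and normalizes by the partition
#' function. Feasible only for lattices of at most 20 sites; larger fields
#' must use [gibbs_sample()].
#'
#' @param m An [mrf_model()] with `n_sites <= 20`.
#' @return An object of class `mrf_distribution`: a list with `configs`
#'   (2^n x n 0/1 matrix, row-major site order), `energy`, `prob`
#'   (summing to 1) and `log_Z`.
#' @examples
#' d <- exact_distribution(ising_model(1, 1, v_u = log(3)))
#' d$prob # 0.75, 0.25
#' @export
exact_distribution <- function(m) {
  stopifnot(inherits(m, "mrf_model"))
  n <- m$n_sites
  if (n > 20) {
    stop(paste("exact enumeration is limited to 20 sites;",
               "use gibbs_sample() for larger lattices"), call. = FALSE)
  }
  configs <- as.matrix(expand.grid(rep(list(0:1), n),
                                   KEEP.OUT.ATTRS = FALSE))
  dimnames(configs) <- NULL
  storage.mode(configs) <- "integer"
  E <- configs %*% (m$V[, 2] - m$V[, 1]) + sum(m$V[, 1])
  if (nrow(m$edges)) {
    for (k in seq_len(nrow(m$edges))) {
      si <- configs[, m$edges[k, 1]]
      sj <- configs[, m$edges[k, 2]]
      E <- E + m$U[cbind(si + 1L, sj + 1L)]
    }
  }
  E <- as.vector(E)
  w <- -m$beta * E
  log_Z <- max(w) + log(sum(exp(w - max(w))))
  prob <- exp(w - log_Z)
  structure(
    list(configs = configs, energy = E, prob = prob, log_Z = log_Z,
         model = m),
    class = "mrf_distribution"
  )
}

#' Gibbs sampling from the stability field
#'
#' Systematic-scan single-site Gibbs sampler: sites are resampled in a
#' fixed raster order from their conditional distribution given their
#' neighbors (which depends only on the site's potentials and the pair
#' potential with its neighborhood). One configuration is retained per
#' sweep after the burn-in. Runs are reproducible given `seed`.
#'
#' @param m An [mrf_model()].
#' @param n_sweeps Retained sweeps, >= 1.
#' @param burn_in Discarded initial sweeps, default 1000.
#' @param seed Optional integer seed.
#' @param init Initial configuration (as in [energy()]); default all
#'   stable.
#' @return Integer matrix (`n_sweeps` x `n_sites`) of 0/1 states, row-major
#'   site order.
#' @export
gibbs_sample <- function(m, n_sweeps, burn_in = 1000, seed = NULL,
                         init = NULL) {
  stopifnot(inherits(m, "mrf_model"))
  if (!is.numeric(n_sweeps) || length(n_sweeps) != 1 || n_sweeps < 1) {
    stop("`n_sweeps` must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  s0 <- if (is.null(init)) integer(m$n_sites) else config_to_int(init, m)
  nbrs0 <- lapply(m$neighbors, function(v) v - 1L)
  gibbs_cpp(m$V, m$U, nbrs0, s0, as.integer(n_sweeps),
            as.integer(burn_in), m$beta)
}

#' Per-site marginal probability of instability
#'
#' The probability that each site is in the unstable state under the
#' field's Gibbs distribution, by exact enumeration (small lattices) or by
#' averaging Gibbs samples. The result uses the same matrix layout as
#' [instability_heatmap()] and can be passed to [write_heatmap()].
#'
#' @param m An [mrf_model()].
#' @param method `"exact"` (requires <= 20 sites) or `"gibbs"`.
#' @param n_sweeps,burn_in,seed Sampler settings for `method = "gibbs"`.
#' @return `height` x `width` matrix of marginal probabilities.
#' @examples
#' marginal_instability(ising_model(2, 2), method = "exact") # all 0.5
#' @export
marginal_instability <- function(m, method = c("exact", "gibbs"),
                                 n_sweeps = 5000, burn_in = 1000,
                                 seed = NULL) {
  stopifnot(inherits(m, "mrf_model"))
  method <- match.arg(method)
  p <- if (method == "exact") {
    d <- exact_distribution(m)
    as.vector(crossprod(d$configs, d$prob))
  } else {
    colMeans(gibbs_sample(m, n_sweeps, burn_in = burn_in, seed = seed))
  }
  matrix(p, nrow = m$height, ncol = m$width, byrow = TRUE)
}
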
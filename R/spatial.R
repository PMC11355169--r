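#' Lattice of plaque-surface sites
#'
#' Represents a flattened patch of plaque surface as a `height` x `width`
#' lattice. Each site carries the four covariates (inflammation `I`, lipid
#' content `L`, shear stress `S`, plaque burden `B`) and a stability state
#' (`"S"` stable or `"U"` unstable). Sites are addressed either as
#' `(row, col)` pairs or by a row-major linear index
#' `(row - 1) * width + col`.
#'
#' @param I,L,S,B Covariate matrices of identical dimension, finite and
#'   non-negative.
#' @param states Character matrix of `"S"`/`"U"` of the same dimension, or
#'   `NULL` for all-stable.
#' @param adjacency Neighborhood rule: `"von_neumann"` (4 orthogonal
#'   neighbors, default) or `"moore"` (8 neighbors).
#' @param periodic Wrap the lattice edges? Default `FALSE`: a plaque
#'   surface patch has edges.
#' @return An object of class `plaque_grid`.
#' @export
plaque_grid <- function(I, L, S, B, states = NULL,
                        adjacency = c("von_neumann", "moore"),
                        periodic = FALSE) {
  adjacency <- match.arg(adjacency)
  covs <- list(I = I, L = L, S = S, B = B)
  dims <- dim(I)
  if (is.null(dims)) stop("covariates must be matrices", call. = FALSE)
  for (nm in names(covs)) {
    m <- covs[[nm]]
    if (!is.matrix(m) || !identical(dim(m), dims)) {
      stop("covariate matrices must share one dimension", call. = FALSE)
    }
    if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
      stop(sprintf("covariate %s must be finite and non-negative", nm),
           call. = FALSE)
    }
  }
  if (is.null(states)) {
    states <- matrix("S", dims[1], dims[2])
  }
  if (!is.matrix(states) || !identical(dim(states), dims) ||
      !all(states %in% c("S", "U"))) {
    stop("`states` must be a matrix of \"S\"/\"U\" matching the covariates",
         call. = FALSE)
  }
  structure(
    list(
      height = dims[1], width = dims[2],
      I = I, L = L, S = S, B = B, states = states,
      adjacency = adjacency, periodic = periodic
    ),
    class = "plaque_grid"
  )
}

#' @export
print.plaque_grid <- function(x, ...) {
  cat("<plaque_grid>", x$height, "x", x$width, "sites,",
      sum(x$states == "U"), "unstable,", x$adjacency, "adjacency\n")
  invisible(x)
}

# row-major linear index <-> (row, col)
site_linear <- function(grid, site) {
  if (length(site) == 2) {
    r <- site[1]; c <- site[2]
    if (r < 1 || r > grid$height || c < 1 || c > grid$width) {
      stop("site outside the lattice", call. = FALSE)
    }
    (r - 1L) * grid$width + c
  } else if (length(site) == 1) {
    if (site < 1 || site > grid$height * grid$width) {
      stop("site outside the lattice", call. = FALSE)
    }
    as.integer(site)
  } else {
    stop("`site` must be a linear index or a (row, col) pair",
         call. = FALSE)
  }
}

# coordinates of all sites in row-major order
grid_coords <- function(grid) {
  n <- grid$height * grid$width
  k <- seq_len(n) - 1L
  data.frame(row = k %/% grid$width + 1L, col = k %% grid$width + 1L)
}

# states in row-major linear order
grid_states_linear <- function(grid) {
  as.vector(t(grid$states))
}

# list of 1-based neighbor vectors (row-major linear ids) for a lattice
lattice_neighbors <- function(height, width,
                              adjacency = c("von_neumann", "moore"),
                              periodic = FALSE) {
  adjacency <- match.arg(adjacency)
  offsets <- if (adjacency == "von_neumann") {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  }
  n <- height * width
  out <- vector("list", n)
  for (k in seq_len(n)) {
    r <- (k - 1) %/% width + 1
    c <- (k - 1) %% width + 1
    nb <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      rr <- r + offsets[o, 1]
      cc <- c + offsets[o, 2]
      if (periodic) {
        rr <- ((rr - 1) %% height) + 1
        cc <- ((cc - 1) %% width) + 1
      }
      if (rr >= 1 && rr <= height && cc >= 1 && cc <= width) {
        nb <- c(nb, (rr - 1) * width + cc)
      }
    }
    out[[k]] <- unique(as.integer(nb))
  }
  out
}

#' Spatial dependence matrix of a lattice
#'
#' Quantifies the influence of each site on every other as a site-by-site
#' matrix `d`, with `d[i, j]` the strength of the dependence of site `i` on
#' site `j`. Entries are a kernel of the Euclidean inter-site distance,
#' zero beyond `range`: the `"uniform"` kernel gives 1 to every site within
#' range (range 1 reproduces the 4-neighborhood), `"exponential"` gives
#' `exp(-distance / range)` within range. The diagonal is set to 1 by
#' convention (a site fully "depends" on itself); neighbor summaries
#' exclude it explicitly. Sites are ordered row-major.
#'
#' @param grid A [plaque_grid()].
#' @param kernel `"uniform"` or `"exponential"`.
#' @param range Kernel range (support and, for the exponential kernel,
#'   decay length), > 0.
#' @return An object of class `dependence_matrix`: the n x n matrix with
#'   attributes `kernel` and `range`.
#' @examples
#' g <- plaque_grid(matrix(0, 2, 2), matrix(0, 2, 2),
#'                  matrix(0, 2, 2), matrix(0, 2, 2))
#' build_dependence_matrix(g, "uniform", 1)
#' @export
build_dependence_matrix <- function(grid,
                                    kernel = c("uniform", "exponential"),
                                    range = 1) {
  stopifnot(inherits(grid, "plaque_grid"))
  kernel <- match.arg(kernel)
  if (!is.numeric(range) || length(range) != 1 || range <= 0) {
    stop("`range` must be a single value > 0", call. = FALSE)
  }
  xy <- grid_coords(grid)
  dr <- abs(outer(xy$row, xy$row, "-"))
  dc <- abs(outer(xy$col, xy$col, "-"))
  if (grid$periodic) {
    dr <- pmin(dr, grid$height - dr)
    dc <- pmin(dc, grid$width - dc)
  }
  dist <- sqrt(dr^2 + dc^2)
  d <- switch(kernel,
    uniform = (dist <= range) * 1,
    exponential = ifelse(dist <= range, exp(-dist / range), 0)
  )
  diag(d) <- 1
  structure(d, class = c("dependence_matrix", "matrix"),
            kernel = kernel, range = range)
}

#' Spatial-dependence contribution of a site's neighborhood
#'
#' The scalar `D` entering the spatial transition model at a site: the
#' dependence-weighted fraction of unstable neighbors,
#' `sum_j d[i, j] * [state_j == U] / sum_j d[i, j]` over `j != i`. Always
#' in \[0, 1\]; an isolated site (no positive dependence on any other site)
#' contributes 0.
#'
#' @param grid A [plaque_grid()].
#' @param dep A [build_dependence_matrix()] result for the same lattice.
#' @param site Linear (row-major) index or `(row, col)` pair.
#' @return The spatial contribution in \[0, 1\].
#' @export
neighbor_term <- function(grid, dep, site) {
  stopifnot(inherits(grid, "plaque_grid"),
            inherits(dep, "dependence_matrix"))
  i <- site_linear(grid, site)
  w <- dep[i, ]
  w[i] <- 0
  den <- sum(w)
  if (den == 0) return(0)
  st <- grid_states_linear(grid)
  sum(w * (st == "U")) / den
}

#' Per-site transition probability on the lattice
#'
#' Evaluates the covariate-weighted transition probability at a site with
#' the spatial-dependence term of its neighborhood:
#' `base + w1*I + w2*L + w3*S + w4*B + w5*D`. With `w5 = 0` this reduces
#' exactly to the aspatial model.
#'
#' @param grid A [plaque_grid()].
#' @param dep A [build_dependence_matrix()] result.
#' @param weights A [transition_weights()].
#' @param site Linear index or `(row, col)` pair.
#' @param link Passed to [transition_probability()].
#' @return Probability with attribute `"clamped"`.
#' @export
site_transition_probability <- function(grid, dep, weights, site,
                                        link = c("linear", "logistic")) {
  link <- match.arg(link)
  i <- site_linear(grid, site)
  xy <- grid_coords(grid)
  prof <- covariate_profile(
    I = grid$I[xy$row[i], xy$col[i]],
    L = grid$L[xy$row[i], xy$col[i]],
    S = grid$S[xy$row[i], xy$col[i]],
    B = grid$B[xy$row[i], xy$col[i]]
  )
  transition_probability(prof, weights,
                         D_term = neighbor_term(grid, dep, i), link = link)
}

#' Couple a dependence modifier into a transition matrix
#'
#' Element-wise (Hadamard) product of a non-negative 2x2 modifier with the
#' 2x2 transition matrix, followed by row renormalization so each row is
#' again a probability distribution. Renormalization is required because an
#' element-wise product of a stochastic matrix with an arbitrary modifier
#' is not stochastic; the total probability mass adjusted away is reported
#' in the attribute `"mass_adjusted"` (sum over rows of `|1 - row sum|`
#' before renormalization). A row whose product is identically zero leaves
#' no distribution to renormalize and is an error.
#'
#' @param modifier 2x2 matrix of non-negative finite entries.
#' @param m A [two_state_matrix()].
#' @return A [two_state_matrix()] with attribute `"mass_adjusted"`.
#' @examples
#' hadamard_combine(matrix(c(1, 1, 2, 1), 2), two_state_matrix(0.2, 0.3))
#' @export
hadamard_combine <- function(modifier, m) {
  stopifnot(inherits(m, "two_state_matrix"))
  if (!is.matrix(modifier) || !identical(dim(modifier), c(2L, 2L)) ||
      !is.numeric(modifier) || any(!is.finite(modifier)) ||
      any(modifier < 0)) {
    stop("`modifier` must be a 2x2 matrix of non-negative finite entries",
         call. = FALSE)
  }
  prod <- modifier * m$matrix
  rs <- rowSums(prod)
  if (any(rs == 0)) {
    stop("Hadamard product left a zero row: degenerate model", call. = FALSE)
  }
  renorm <- prod / rs
  out <- two_state_matrix(p_su = renorm[1, 2], p_us = renorm[2, 1])
  attr(out, "mass_adjusted") <- sum(abs(1 - rs))
  out
}

#' Per-site spatially modified transition matrix
#'
#' The literal matrix reading of coupling spatial dependence into the
#' chain: each site derives a 2x2 modifier block from its neighborhood —
#' the stable row's transition toward instability is inflated by
#' `1 + D_i`, where `D_i` is the site's [neighbor_term()] — and the block
#' is combined with the base transition matrix by [hadamard_combine()].
#' The scalar pathway ([site_transition_probability()]) is the default for
#' heatmaps; this operation exists to honor the element-wise matrix
#' coupling directly.
#'
#' @param grid,dep,site As in [neighbor_term()].
#' @param m Base [two_state_matrix()] shared by all sites.
#' @return A renormalized [two_state_matrix()] for the site.
#' @export
spatial_transition_matrix <- function(grid, dep, site, m) {
  D_i <- neighbor_term(grid, dep, site)
  modifier <- matrix(c(1, 1, 1 + D_i, 1), nrow = 2)
  hadamard_combine(modifier, m)
}

#' Instability heatmap of a plaque surface
#'
#' The per-site probability of destabilization, `P(S -> U)`, across the
#' lattice — the field rendered as a heatmap (warm colors marking sites at
#' elevated risk; see [write_heatmap()]). Clamping events from the linear
#' link are counted across sites; a warning is raised when more than 1% of
#' sites clamp, since widespread clamping signals misconfigured weights.
#'
#' @param grid A [plaque_grid()].
#' @param dep A [build_dependence_matrix()] result.
#' @param weights A [transition_weights()].
#' @param link Passed to [transition_probability()].
#' @return A `height` x `width` numeric matrix of probabilities with
#'   attribute `"n_clamped"`.
#' @export
instability_heatmap <- function(grid, dep, weights,
                                link = c("linear", "logistic")) {
  link <- match.arg(link)
  stopifnot(inherits(grid, "plaque_grid"))
  n <- grid$height * grid$width
  p <- numeric(n)
  clamped <- logical(n)
  for (i in seq_len(n)) {
    pi <- site_transition_probability(grid, dep, weights, i, link = link)
    p[i] <- as.numeric(pi)
    clamped[i] <- attr(pi, "clamped")
  }
  n_clamped <- sum(clamped)
  if (n_clamped > 0.01 * n) {
    warning(sprintf(
      "%d of %d site probabilities were clamped to [0, 1]; check weights",
      n_clamped, n
    ), call. = FALSE)
  }
  field <- matrix(p, nrow = grid$height, ncol = grid$width, byrow = TRUE)
  attr(field, "n_clamped") <- n_clamped
  field
}

#' Evolve the lattice states over time
#'
#' Seeded stochastic evolution of the site states: at each step every
#' stable site destabilizes with its current [site_transition_probability()]
#' and every unstable site restabilizes with the constant `p_us` (the
#' reverse transition carries no covariate model). Updates are synchronous
#' by default — all sites see the previous step's neighbor states — or
#' asynchronous in row-major order.
#'
#' @param grid A [plaque_grid()].
#' @param dep A [build_dependence_matrix()] result.
#' @param weights A [transition_weights()].
#' @param p_us Probability of an unstable site restabilizing per step.
#' @param steps Number of update steps.
#' @param seed Optional integer seed.
#' @param mode `"synchronous"` (default) or `"asynchronous"`.
#' @return The grid with updated states; the list of state matrices after
#'   each step is attached as attribute `"history"`.
#' @export
evolve_grid <- function(grid, dep, weights, p_us = 0.1, steps = 1,
                        seed = NULL,
                        mode = c("synchronous", "asynchronous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "plaque_grid"))
  if (!is.null(seed)) set.seed(seed)
  n <- grid$height * grid$width
  history <- vector("list", steps)
  for (s in seq_len(steps)) {
    if (mode == "synchronous") {
      p_field <- instability_heatmap(grid, dep, weights)
      u <- matrix(stats::runif(n), grid$height, grid$width)
      st <- grid$states
      new_st <- st
      new_st[st == "S" & u < p_field] <- "U"
      new_st[st == "U" & u < p_us] <- "S"
      grid$states <- new_st
    } else {
      for (i in seq_len(n)) {
        xy <- grid_coords(grid)
        cur <- grid$states[xy$row[i], xy$col[i]]
        if (cur == "S") {
          p <- as.numeric(site_transition_probability(grid, dep, weights, i))
          if (stats::runif(1) < p) grid$states[xy$row[i], xy$col[i]] <- "U"
        } else {
          if (stats::runif(1) < p_us) grid$states[xy$row[i], xy$col[i]] <- "S"
        }
      }
    }
    history[[s]] <- grid$states
  }
  attr(grid, "history") <- history
  grid
}
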
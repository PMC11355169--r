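test_that("dependence matrix encodes the kernel and neighborhood", {
  g <- homogeneous_grid(3, 3)
  d <- build_dependence_matrix(g, "uniform", range = 1)
  # center site (2,2) = linear 5: orthogonal neighbors only
  expect_equal(unname(d[5, ]), c(0, 1, 0, 1, 1, 1, 0, 1, 0))
  expect_true(isSymmetric(unclass(d)))

  # exponential kernel decays by exp(-1/range) per unit distance
  g15 <- homogeneous_grid(1, 5)
  de <- build_dependence_matrix(g15, "exponential", range = 2.5)
  expect_equal(de[1, 3] / de[1, 2], exp(-1 / 2.5))

  # degenerate single-site lattice keeps the diagonal convention
  g1 <- homogeneous_grid(1, 1)
  expect_equal(unname(unclass(build_dependence_matrix(g1, "uniform", 1))),
               matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("neighbor term is the weighted fraction of unstable neighbors", {
  st <- matrix("S", 3, 3)
  g <- homogeneous_grid(3, 3, states = st)
  d <- build_dependence_matrix(g, "uniform", 1)
  expect_equal(neighbor_term(g, d, c(2, 2)), 0)

  st[1, 2] <- "U" # one of four orthogonal neighbors of the center
  g <- homogeneous_grid(3, 3, states = st)
  expect_equal(neighbor_term(g, d, c(2, 2)), 0.25)

  st[, ] <- "U"
  g <- homogeneous_grid(3, 3, states = st)
  expect_equal(neighbor_term(g, d, c(2, 2)), 1)

  # isolated site: no neighbors, zero contribution
  g1 <- homogeneous_grid(1, 1)
  d1 <- build_dependence_matrix(g1, "uniform", 1)
  expect_equal(neighbor_term(g1, d1, 1), 0)
})

test_that("adding an unstable neighbor never lowers the neighbor term", {
  set.seed(41)
  g0 <- generate_covariate_grid(4, 4, seed = 5)
  d <- build_dependence_matrix(g0, "uniform", 1)
  st <- matrix(sample(c("S", "U"), 16, replace = TRUE), 4, 4)
  for (k in 1:10) {
    stable_sites <- which(st == "S")
    if (length(stable_sites) == 0) break
    g_before <- plaque_grid(g0$I, g0$L, g0$S, g0$B, states = st)
    flip <- sample(stable_sites, 1)
    st2 <- st
    st2[flip] <- "U"
    g_after <- plaque_grid(g0$I, g0$L, g0$S, g0$B, states = st2)
    for (i in 1:16) {
      expect_gte(neighbor_term(g_after, d, i), neighbor_term(g_before, d, i))
    }
    st <- st2
  }
})

test_that("with w5 = 0 the spatial model reduces to the aspatial one", {
  g <- homogeneous_grid(4, 4, value = 1)
  d <- build_dependence_matrix(g, "uniform", 1)
  w <- transition_weights(0.05, 0.1, 0.02, 0.03, 0.04, w5 = 0)
  aspatial <- transition_probability(covariate_profile(1, 1, 1, 1), w)
  for (i in 1:16) {
    expect_equal(as.numeric(site_transition_probability(g, d, w, i)),
                 as.numeric(aspatial), tolerance = 1e-12)
  }
})

test_that("spatial dependence raises site probabilities as specified", {
  st <- matrix("U", 3, 3)
  g <- homogeneous_grid(3, 3, value = 0, states = st)
  d <- build_dependence_matrix(g, "uniform", 1)
  w <- transition_weights(0.1, w5 = 0.4)
  expect_equal(as.numeric(site_transition_probability(g, d, w, c(2, 2))),
               0.5)
})

test_that("hadamard coupling renormalizes rows and flags degeneracy", {
  m <- two_state_matrix(0.2, 0.3)
  ident <- hadamard_combine(matrix(1, 2, 2), m)
  expect_equal(ident$matrix, m$matrix)
  expect_equal(attr(ident, "mass_adjusted"), 0)

  out <- hadamard_combine(matrix(c(1, 1, 2, 1), 2), two_state_matrix(0.2, 0.3))
  expect_equal(unname(out$matrix),
               matrix(c(0.8 / 1.2, 0.3, 0.4 / 1.2, 0.7), 2))

  expect_error(hadamard_combine(matrix(c(0, 1, 0, 1), 2),
                                two_state_matrix(0.2, 0.3)),
               "zero row")
  expect_error(hadamard_combine(matrix(-1, 2, 2), m), "non-negative")
})

test_that("renormalized hadamard output is always row-stochastic", {
  set.seed(42)
  for (i in 1:500) {
    m <- two_state_matrix(runif(1, 0.01, 0.99), runif(1, 0.01, 0.99))
    mod <- matrix(runif(4, 0.01, 3), 2)
    out <- hadamard_combine(mod, m)
    expect_true(all(abs(rowSums(out$matrix) - 1) < 1e-12))
  }
})

test_that("per-site modifier blocks shift mass toward instability", {
  st <- matrix("U", 3, 3)
  g <- homogeneous_grid(3, 3, value = 0, states = st)
  d <- build_dependence_matrix(g, "uniform", 1)
  m <- two_state_matrix(0.2, 0.3)
  sm <- spatial_transition_matrix(g, d, c(2, 2), m)
  expect_gt(sm$p_su, m$p_su)
  expect_equal(sm$p_us, m$p_us)
  expect_true(all(abs(rowSums(sm$matrix) - 1) < 1e-12))
})

test_that("instability heatmaps respond to seeds and stay in [0, 1]", {
  g <- homogeneous_grid(4, 4)
  d <- build_dependence_matrix(g, "uniform", 1)
  # all weights zero: constant base field
  f0 <- instability_heatmap(g, d, transition_weights(0.2))
  expect_true(all(f0 == 0.2))

  # single unstable seed with only w5 active: elevated at its
  # orthogonal neighbors, base elsewhere
  st <- matrix("S", 4, 4)
  st[2, 2] <- "U"
  gs <- homogeneous_grid(4, 4, states = st)
  f <- instability_heatmap(gs, d, transition_weights(0.1, w5 = 0.3))
  expect_true(all(f >= 0 & f <= 1))
  expect_gt(f[1, 2], 0.1)
  expect_gt(f[2, 1], 0.1)
  expect_equal(f[4, 4], 0.1)
  expect_equal(f[2, 2], 0.1) # the seed site itself has stable neighbors
})

test_that("widespread clamping triggers a warning", {
  g <- homogeneous_grid(3, 3, value = 5)
  d <- build_dependence_matrix(g, "uniform", 1)
  w <- transition_weights(0.5, w1 = 1)
  expect_warning(instability_heatmap(g, d, w), "clamped")
})

test_that("lattice evolution is reproducible under a seed", {
  g <- generate_covariate_grid(5, 5, seed = 9)
  d <- build_dependence_matrix(g, "uniform", 1)
  w <- transition_weights(0.1, w1 = 0.05, w5 = 0.2)
  e1 <- evolve_grid(g, d, w, p_us = 0.1, steps = 5, seed = 3)
  e2 <- evolve_grid(g, d, w, p_us = 0.1, steps = 5, seed = 3)
  expect_identical(e1$states, e2$states)
  expect_length(attr(e1, "history"), 5)
  ea <- evolve_grid(g, d, w, steps = 2, seed = 3, mode = "asynchronous")
  expect_true(all(ea$states %in% c("S", "U")))
})
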
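test_that("covariate-weighted transition probability sums and clamps", {
  w0 <- transition_weights(0.1)
  expect_equal(as.numeric(transition_probability(covariate_profile(), w0)),
               0.1)
  w <- transition_weights(0.05, 0.1, 0.1, 0.1, 0.1)
  p <- transition_probability(covariate_profile(1, 1, 1, 1), w)
  expect_equal(as.numeric(p), 0.45)
  expect_false(attr(p, "clamped"))
  # ceiling clamp is recorded, not hidden
  wc <- transition_weights(0.9, w1 = 0.5)
  pc <- transition_probability(covariate_profile(I = 1), wc)
  expect_equal(as.numeric(pc), 1)
  expect_true(attr(pc, "clamped"))
  expect_error(covariate_profile(I = -1), "non-negative")
  expect_error(transition_weights(1.2), "base")
})

test_that("logistic link keeps probabilities interior without clamping", {
  w <- transition_weights(0.9, w1 = 5)
  p <- transition_probability(covariate_profile(I = 1), w,
                              link = "logistic")
  expect_true(p > 0 && p < 1)
  expect_false(attr(p, "clamped"))
  # zero linear predictor reproduces the base probability
  p0 <- transition_probability(covariate_profile(), w, link = "logistic")
  expect_equal(as.numeric(p0), 0.9)
})

test_that("two-state matrix is row-stochastic with the stated layout", {
  m <- two_state_matrix(0.1, 0.3)
  expect_equal(unname(m$matrix),
               matrix(c(0.9, 0.3, 0.1, 0.7), 2))
  expect_equal(unname(two_state_matrix(0, 0)$matrix), diag(2))
  expect_equal(unname(two_state_matrix(1, 1)$matrix),
               matrix(c(0, 1, 1, 0), 2))
  set.seed(31)
  for (i in 1:50) {
    mm <- two_state_matrix(runif(1), runif(1))
    expect_true(all(abs(rowSums(mm$matrix) - 1) < 1e-12))
  }
  expect_error(two_state_matrix(1.1, 0.2), "probabilities")
})

test_that("eigen-based stationary distribution matches the closed form", {
  s <- stationary_distribution(two_state_matrix(0.3, 0.3))
  expect_equal(c(s$pi_S, s$pi_U), c(0.5, 0.5), tolerance = 1e-12)
  s <- stationary_distribution(two_state_matrix(0.1, 0.3))
  expect_equal(c(s$pi_S, s$pi_U), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(s$eigenvalue, 1, tolerance = 1e-12)
  set.seed(32)
  for (i in 1:200) {
    p_su <- runif(1, 0.01, 0.99)
    p_us <- runif(1, 0.01, 0.99)
    m <- two_state_matrix(p_su, p_us)
    s <- stationary_distribution(m)
    pi <- c(s$pi_S, s$pi_U)
    expect_lt(max(abs(pi - stationary_oracle(p_su, p_us))), 1e-10)
    # left-eigenvector residual: pi M = pi
    expect_lt(max(abs(pi %*% m$matrix - pi)), 1e-10)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }
})

test_that("degenerate chains are rejected with the mixing conditions", {
  expect_error(stationary_distribution(two_state_matrix(0, 0)),
               "irreducible")
  expect_error(stationary_distribution(two_state_matrix(1, 1)),
               "periodic")
  # one-sided zero is fine: absorbing stable state
  s <- stationary_distribution(two_state_matrix(0, 0.3))
  expect_equal(c(s$pi_S, s$pi_U), c(1, 0), tolerance = 1e-12)
})

test_that("event probabilities follow the exponential survival curve", {
  e <- event_probabilities(0.5, 2)
  expect_equal(e$p_stay, exp(-1))
  expect_equal(e$p_event, 1 - exp(-1))
  expect_equal(event_probabilities(0.5, 0), list(p_stay = 1, p_event = 0))
  expect_equal(event_probabilities(0, 7), list(p_stay = 1, p_event = 0))
  expect_error(event_probabilities(-0.1, 1), "alpha_su")
  expect_error(event_probabilities(0.1, -1), "t")
})

test_that("hazard and one-step probability conversions are inverse", {
  p <- c(0, 0.05, 0.5, 0.99)
  expect_equal(step_probability_from_hazard(hazard_from_step_probability(p)),
               p)
  expect_equal(hazard_from_step_probability(1 - exp(-0.7)), 0.7)
})

test_that("chain simulation is seeded and converges to the stationary law", {
  m_id <- two_state_matrix(0, 0)
  expect_true(all(simulate_chain(m_id, 100, seed = 1) == "S"))
  m <- two_state_matrix(0.1, 0.3)
  s1 <- simulate_chain(m, 5000, seed = 42)
  s2 <- simulate_chain(m, 5000, seed = 42)
  expect_identical(s1, s2)
  # empirical frequency near pi_S = 0.75 within Monte-Carlo error; the
  # chain's autocorrelation rho = 1 - p_su - p_us enters the variance
  n <- 1e5
  s <- simulate_chain(m, n, seed = 7)
  rho <- 1 - 0.1 - 0.3
  se <- sqrt(0.75 * 0.25 / n * (1 + rho) / (1 - rho))
  expect_lt(abs(mean(s == "S") - 0.75), 3 * se)
})
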
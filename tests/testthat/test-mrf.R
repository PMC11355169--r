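test_that("energy sums site and edge potentials once per edge", {
  m0 <- mrf_model(2, 2, V = c(S = 0, U = 0), U = matrix(0, 2, 2))
  expect_equal(energy(c(0, 1, 1, 0), m0), 0)

  m1 <- mrf_model(1, 1, V = c(S = 1, U = 2), U = matrix(0, 2, 2))
  expect_equal(energy("S", m1), 1)
  expect_equal(energy("U", m1), 2)

  # 2-site chain, agreement favored: U(s, s') = -1 if equal else +1
  m2 <- mrf_model(1, 2, V = c(S = 0, U = 0),
                  U = matrix(c(-1, 1, 1, -1), 2))
  expect_equal(energy(c("S", "S"), m2), -1)
  expect_equal(energy(c("S", "U"), m2), 1)

  expect_error(energy(c("S", "X"), m2), "S.*U|states")
  expect_error(energy(c(0, 1, 0), m2), "every site")
  expect_error(mrf_model(1, 2, V = c(S = 0, U = 0),
                         U = matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("exact distribution normalizes and matches hand computations", {
  d <- exact_distribution(mrf_model(1, 1, V = c(S = 0, U = 0),
                                    U = matrix(0, 2, 2)))
  expect_equal(d$prob, c(0.5, 0.5))

  d3 <- exact_distribution(ising_model(1, 1, v_u = log(3)))
  expect_equal(d3$prob, c(0.75, 0.25))

  set.seed(51)
  m <- ising_model(2, 3, v_u = rnorm(1), J = runif(1, 0, 0.5))
  d <- exact_distribution(m)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_true(all(d$prob >= 0))

  big <- ising_model(5, 5)
  expect_error(exact_distribution(big), "20 sites")
})

test_that("the Gibbs measure is invariant under shifting all potentials", {
  m <- ising_model(2, 2, v_u = 0.7, J = 0.3)
  shifted <- mrf_model(2, 2, V = m$V + 5, U = m$U)
  expect_equal(exact_distribution(m)$prob,
               exact_distribution(shifted)$prob, tolerance = 1e-12)
})

test_that("with no pair potential the field factorizes over sites", {
  set.seed(52)
  v <- rnorm(4)
  m <- ising_model(2, 2, J = 0, v_site = v)
  d <- exact_distribution(m)
  site_pU <- exp(-v) / (1 + exp(-v))
  for (k in seq_len(nrow(d$configs))) {
    s <- d$configs[k, ]
    expect_equal(d$prob[k],
                 prod(ifelse(s == 1, site_pU, 1 - site_pU)),
                 tolerance = 1e-12)
  }
})

test_that("exact marginals obey symmetry and independence structure", {
  # symmetric potentials: every marginal exactly one half
  m <- ising_model(2, 2, v_u = 0, J = 0.4)
  expect_equal(marginal_instability(m, "exact"), matrix(0.5, 2, 2))

  # V favoring U at one site, no coupling: only that site deviates
  m1 <- ising_model(2, 2, J = 0, v_site = c(-1, 0, 0, 0))
  mi <- marginal_instability(m1, "exact")
  expect_gt(mi[1, 1], 0.5)
  expect_equal(mi[c(2, 3, 4)], rep(0.5, 3))

  # attractive coupling with one near-clamped unstable site pulls its
  # neighbors above one half
  m2 <- ising_model(2, 2, J = 0.8, v_site = c(-50, 0, 0, 0))
  mi2 <- marginal_instability(m2, "exact")
  expect_gt(mi2[1, 2], 0.5)
  expect_gt(mi2[2, 1], 0.5)
})

test_that("gibbs sampling is seeded and recovers a uniform field", {
  m <- mrf_model(3, 3, V = c(S = 0, U = 0), U = matrix(0, 2, 2))
  s1 <- gibbs_sample(m, 200, burn_in = 50, seed = 8)
  s2 <- gibbs_sample(m, 200, burn_in = 50, seed = 8)
  expect_identical(s1, s2)
  s <- gibbs_sample(m, 4000, burn_in = 200, seed = 9)
  p <- colMeans(s)
  se <- apply(s, 2, batch_se)
  expect_true(all(abs(p - 0.5) < 4 * pmax(se, 1e-3)))
})

test_that("gibbs marginals agree with enumeration on a coupled lattice", {
  m <- ising_model(3, 3, v_u = 0.4, J = 0.3)
  exact <- as.vector(t(marginal_instability(m, "exact")))
  s <- gibbs_sample(m, 5000, burn_in = 1000, seed = 10)
  est <- colMeans(s)
  se <- apply(s, 2, batch_se)
  z <- abs(est - exact) / pmax(se, 1e-4)
  expect_lt(max(z), 5)
  expect_gt(mean(z < 3), 0.85)
})
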
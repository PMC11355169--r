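test_that("constant-rate trajectories reach their analytic limits", {
  # sub-unit growth: plaque regression to extinction
  tr <- simulate_trajectory(0.1, 500, r_schedule = 0.8)
  expect_lt(tail(tr$P, 1), 1e-6)
  # r in (1, 2): convergence to (r - 1)/r
  tr <- simulate_trajectory(0.1, 500, r_schedule = 1.8)
  expect_equal(tail(tr$P, 1), 0.8 / 1.8, tolerance = 1e-9)
})

test_that("trajectories converge to the fixed point for r in (1, 3)", {
  set.seed(21)
  for (i in 1:8) {
    r <- runif(1, 1.1, 2.9)
    P0 <- runif(1, 0.05, 0.95)
    tr <- simulate_trajectory(P0, 1e4, r_schedule = r)
    expect_lt(abs(tail(tr$P, 1) - (r - 1) / r), 1e-6)
  }
})

test_that("series lengths agree and modes are mutually exclusive", {
  g <- growth_aggregate(alpha = 1.6)
  tr <- simulate_trajectory(0.1, 25, growth = g,
                            lumen = remodeling_lumen(10, 14))
  expect_length(tr$P, 26)
  expect_length(tr$r, 26)
  expect_length(tr$A, 26)
  expect_true(all(diff(tr$A) >= 0))
  expect_true(is.na(tr$r[1]))
  expect_error(simulate_trajectory(0.1, 10), "exactly one")
  expect_error(simulate_trajectory(0.1, 10, growth = g, r_schedule = 1.5),
               "exactly one")
  expect_error(simulate_trajectory(0, 10, r_schedule = 1.5), "P0")
})

test_that("stenosis relative to baseline reflects remodeling", {
  lum <- remodeling_lumen(10, 14, rate = 0.5)
  tr <- simulate_trajectory(0.2, 10, r_schedule = 1.8, lumen = lum)
  expect_equal(tr$stenosis_vs_baseline, tr$P * tr$A / 10)
  df <- as.data.frame(tr)
  expect_equal(names(df), c("visit", "P", "r", "A", "stenosis_vs_baseline"))
  expect_equal(df$visit[1], 0)
})

test_that("oscillation onset marks the first decrease in plaque burden", {
  # constant r > 2 from a small plaque: the burden overshoots the fixed
  # point and the first decrease begins the oscillatory phase
  tr <- simulate_trajectory(0.1, 50, r_schedule = 2.8)
  onset <- tr$oscillation_onset
  expect_false(is.na(onset))
  expect_lt(tr$P[onset + 1], tr$P[onset])
  expect_true(all(diff(tr$P[seq_len(onset)]) >= 0))
  expect_gt(tr$r[onset + 1], 2)

  # a stable scenario never decreases
  tr_stable <- simulate_trajectory(0.1, 100, r_schedule = 1.8)
  expect_true(is.na(tr_stable$oscillation_onset))

  # a slowly drifting rate lets the burden track the moving equilibrium
  # from below: no rupture signature while the drift lasts
  tr_drift <- simulate_trajectory(0.1, 30, r_schedule = 1.2 + 0.08 * (0:29))
  expect_true(is.na(tr_drift$oscillation_onset))
})

test_that("growth rates outside [0, 4] abort with the visit index", {
  schedule <- 1 + 0.08 * (0:39) # exceeds 4 at visit 39
  expect_error(simulate_trajectory(0.1, 40, r_schedule = schedule),
               "visit 39")
})

test_that("estimate_r_series inverts the map interval by interval", {
  expect_equal(as.numeric(estimate_r_series(c(0.5, 0.5))), 2)
  expect_equal(as.numeric(estimate_r_series(c(0.1, 0.162))), 1.8)
  # exact inversion of a noiseless simulated series
  tr <- simulate_trajectory(0.1, 30, r_schedule = 1.7)
  r_hat <- estimate_r_series(tr$P)
  expect_equal(as.numeric(r_hat), rep(1.7, 30), tolerance = 1e-12)
  expect_true(all(attr(r_hat, "flag") == "ok"))
  expect_error(estimate_r_series(0.5), ">= 2")
})

test_that("degenerate measurements are flagged, not dropped", {
  r_hat <- estimate_r_series(c(0.2, 0, 0.1, 0.3))
  expect_length(r_hat, 3)
  expect_true(is.na(r_hat[2]))
  expect_equal(attr(r_hat, "flag"), c("ok", "undefined", "ok"))
})

test_that("risk classification applies the strict r > 2 rule", {
  expect_equal(classify_plaque_risk(c(1.4, 1.6, 1.9)), "STABLE")
  expect_equal(classify_plaque_risk(c(1.8, 2.1)), "UNSTABLE")
  expect_equal(classify_plaque_risk(2.0), "STABLE")
  expect_equal(classify_plaque_risk(c(3, NA)), "UNSTABLE")
  expect_equal(classify_plaque_risk(c(1.0, 4.0), summary = "mean"),
               "UNSTABLE")
  expect_error(classify_plaque_risk(c(NA_real_, NA_real_)), "undefined")
})
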
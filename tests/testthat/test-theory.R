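test_that("delta_p_nfds is the linear pull toward the equilibrium", {
  expect_equal(delta_p_nfds(0.8, D = -0.5, p_eq = 0.7), -0.05)
  expect_equal(delta_p_nfds(0.7, D = -0.5, p_eq = 0.7), 0)
  expect_equal(delta_p_nfds(c(0.2, 0.7, 0.9), -0.4, 0.7),
               -0.4 * (c(0.2, 0.7, 0.9) - 0.7))
  expect_error(delta_p_nfds(1.2, -0.5, 0.7))
})

test_that("overdominance has its protected equilibrium at s2/(s1+s2)", {
  s1 <- 0.3; s2 <- 0.3
  p_star <- s2 / (s1 + s2)
  expect_equal(delta_p_overdominance(p_star, s1, s2), 0)
  expect_gt(delta_p_overdominance(p_star - 0.2, s1, s2), 0)
  expect_lt(delta_p_overdominance(p_star + 0.2, s1, s2), 0)
  # underdominance is the same closed form with reversed stability
  expect_lt(delta_p_underdominance(0.3, -0.3, -0.3), 0)
  expect_gt(delta_p_underdominance(0.7, -0.3, -0.3), 0)
})

test_that("directional selection and migration behave as expected", {
  expect_equal(delta_p_directional(0, 0.1), 0)
  expect_equal(delta_p_directional(1, 0.1), 0)
  expect_gt(delta_p_directional(0.5, 0.1), 0)
  expect_lt(delta_p_directional(0.5, -0.1), 0)
  expect_equal(delta_p_migration(0.2, m = 0.1, p_m = 0.5), 0.1 * (0.5 - 0.2))
  expect_equal(delta_p_migration(0.5, 0.1, 0.5), 0)
})

test_that("classify_dynamics applies the D-range rules", {
  expect_equal(
    classify_dynamics(c(-0.48, -0.999, -1.5, -2.5, 0.3), quiet = TRUE),
    c("converging", "converging", "dampened_oscillation",
      "diverging_oscillation", "positive_FDS")
  )
  expect_equal(classify_dynamics(-2, quiet = TRUE), "stable_oscillation")
  # the -2 boundary is detected within the stated tolerance
  expect_equal(classify_dynamics(-2 + 1e-10, quiet = TRUE),
               "stable_oscillation")
  expect_equal(classify_dynamics(-2 + 1e-6, quiet = TRUE),
               "dampened_oscillation")
  expect_equal(classify_dynamics(-2 - 1e-6, quiet = TRUE),
               "diverging_oscillation")
})

test_that("boundary D values go to the adjacent class toward zero, with a message", {
  expect_message(out0 <- classify_dynamics(0), "boundary")
  expect_equal(out0, "converging")
  expect_message(out1 <- classify_dynamics(-1), "boundary")
  expect_equal(out1, "converging")
  expect_silent(classify_dynamics(c(0, -1), quiet = TRUE))
  expect_silent(classify_dynamics(-0.5))
  expect_error(classify_dynamics(NA_real_))
  expect_error(classify_dynamics(Inf))
})

test_that("iterate_nfds converges monotonically for -1 < D < 0", {
  traj <- iterate_nfds(0.95, D = -0.5, p_eq = 0.7, n_steps = 30)
  dev <- abs(traj$p - 0.7)
  expect_true(all(diff(dev) <= 0))
  expect_lt(dev[31], 1e-8)
})

test_that("iterate_nfds oscillates as the classification predicts", {
  # dampened oscillation: alternating sign, shrinking amplitude
  traj <- iterate_nfds(0.9, D = -1.5, p_eq = 0.5, n_steps = 20)
  dev <- traj$p - 0.5
  expect_true(all(dev[-1] * dev[-21] < 0))
  expect_true(all(diff(abs(dev)) < 0))
  # stable two-point oscillation at D = -2
  traj2 <- iterate_nfds(0.6, D = -2, p_eq = 0.5, n_steps = 10)
  expect_equal(abs(traj2$p - 0.5), rep(0.1, 11))
})

test_that("theory_curves returns the long tibble of all processes", {
  tc <- theory_curves()
  expect_s3_class(tc, "tbl_df")
  expect_named(tc, c("process", "params", "p", "delta_p"))
  expect_setequal(
    unique(tc$process),
    c("nfds", "overdominance", "directional_positive",
      "directional_negative", "underdominance", "migration")
  )
  nfds <- tc[tc$process == "nfds" & tc$params == "D=-0.5", ]
  expect_equal(nfds$delta_p, -0.5 * (nfds$p - 0.5))
})
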
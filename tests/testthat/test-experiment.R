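test_that("relative_fitness and the equilibrium solver agree with closed forms", {
  expect_equal(relative_fitness(c(a = 1.6, b = -0.8), c(0, 0.5, 1)),
               c(1.6, 1.2, 0.8))
  eq <- solve_fitness_equilibrium(c(a = 1.6, b = -0.8), "linear")
  expect_equal(eq$equilibrium, 0.75)
  expect_false(eq$no_crossing)
  expect_true(solve_fitness_equilibrium(c(a = 1.6, b = 0), "linear")$no_crossing)
  expect_true(solve_fitness_equilibrium(c(a = 3, b = -0.5), "linear")$no_crossing)
  # sigmoidal: w(p) = 1 at p = mid + log((upper-1)/(1-lower))/steep... solved
  # here against the analytic crossing of the default generator parameters
  par <- c(lower = 0.6, upper = 1.6, mid = 0.5, steep = -12)
  eq_s <- solve_fitness_equilibrium(par, "sigmoidal")
  analytic <- 0.5 + log(1.5) / 12
  expect_equal(eq_s$equilibrium, analytic, tolerance = 1e-6)
  expect_true(solve_fitness_equilibrium(
    c(lower = 1.1, upper = 1.6, mid = 0.5, steep = -12), "sigmoidal"
  )$no_crossing)
})

test_that("fit_fitness_function enforces its design preconditions", {
  ex <- sim_transplant_experiment(seed = 1)[1:4, ]
  expect_error(fit_fitness_function(ex, "linear"), ">= 5 bushes")
})

test_that("the linear fitness fit recovers slope sign and equilibrium", {
  ex <- sim_transplant_experiment(n_per_bush = 500, seed = 21)
  fit <- fit_fitness_function(ex, "linear", mcmc = tiny_mcmc(), seed = 22)
  b <- fit$params$estimate[fit$params$term == "b"]
  expect_lt(b, 0)
  expect_lt(abs(fit$equilibrium$equilibrium - 0.75), 0.05)
  expect_gt(fit$equilibrium$prop_crossing, 0.9)
  expect_true(is.finite(fit$waic["waic"]))
  # reproducible under the seed
  fit2 <- fit_fitness_function(ex, "linear", mcmc = tiny_mcmc(), seed = 22)
  expect_equal(fit$params, fit2$params)
})

test_that("WAIC prefers the sigmoidal form on strongly step-like data", {
  ex <- sim_transplant_experiment(
    n_per_bush = 500,
    fitness = fitness_sigmoidal(lower = 0.5, upper = 1.5, midpoint = 0.5,
                                steepness = -25),
    seed = 31
  )
  cmp <- fit_fitness_function(ex, "both", mcmc = tiny_mcmc(), seed = 32)
  expect_s3_class(cmp, "fitness_comparison")
  expect_equal(cmp$preferred, "sigmoidal")
  expect_equal(nrow(cmp$comparison), 2)
  expect_true(all(cmp$comparison$delta_waic >= 0))
})

test_that("the experiment-level D regression recovers the NFDS signal", {
  # full 0-1 grid: delta-p is a hump with a zero crossing at the
  # equilibrium, so the global linear slope is weak but negative
  ex <- sim_transplant_experiment(n_per_bush = 500, seed = 41)
  fit <- fit_experiment_d(ex, mcmc = tiny_mcmc(), seed = 42)
  expect_lt(fit$estimates$D, 0)
  # near-equilibrium grid: the linearisation D = d(delta-p)/dp at p_eq
  # holds, the slope is clearly negative and -alpha/D sits near 0.75
  ex2 <- sim_transplant_experiment(
    release_freqs = rep(seq(0.65, 0.85, by = 0.05), 10),
    n_per_bush = 2000, seed = 43
  )
  fit2 <- fit_experiment_d(ex2, mcmc = tiny_mcmc(), seed = 44)
  expect_lt(fit2$estimates$D_hi, 0)
  expect_lt(abs(fit2$estimates$p_eq_hat - 0.75), 0.05)
})

test_that("fit_experiment_d drops empty bushes and needs frequency spread", {
  ex <- sim_transplant_experiment(n_per_bush = 20, base_recapture = 0.4,
                                  seed = 51)
  ex$recaptured_striped[3] <- 0L
  ex$recaptured_other[3] <- 0L
  expect_message(
    fit_experiment_d(ex, mcmc = tiny_mcmc(chains = 2, warmup = 300,
                                          iter = 300), seed = 52),
    "zero total recaptures"
  )
  flat <- ex[rep(11, 6), ]
  flat$bush <- sprintf("B%02d", 1:6)
  expect_error(fit_experiment_d(flat), "one release frequency")
})

test_that("the blocked advantage model recovers the log-odds advantage", {
  ex <- sim_advantage_experiment(n_blocks = 20, n_per_morph = 60,
                                 beta = log(4), seed = 61)
  fit <- fit_morph_advantage(ex, mcmc = tiny_mcmc(), seed = 62)
  expect_lt(abs(fit$estimates$beta - log(4)), 0.5)
  expect_true(fit$estimates$beta_lo <= log(4) &&
                log(4) <= fit$estimates$beta_hi)
  expect_gt(fit$estimates$beta_lo, 0)
  expect_equal(nrow(fit$blocks), 20)
  expect_error(fit_morph_advantage(ex[1, ]), ">= 2 blocks")
})
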
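test_that("eligible_localities counts consecutive-year pairs after pooling hosts", {
  mk <- function(locality, years) {
    tibble::tibble(
      locality = locality, year = rep(years, each = 2),
      host = rep(c("Adenostoma", "Ceanothus"), length(years)),
      n_striped = 5L, n_green = 5L, n_melanic = 1L
    )
  }
  series <- dplyr::bind_rows(
    mk("A", 2000:2011),                 # 11 consecutive pairs
    mk("B", seq(2000, 2020, by = 2))    # no consecutive pairs
  )
  expect_equal(eligible_localities(series, min_pairs = 10), "A")
  expect_equal(eligible_localities(series, min_pairs = 12), character(0))
  expect_equal(eligible_localities(series[0, ]), character(0))
})

test_that("equilibrium_from_fit is -alpha/D with range flagging", {
  expect_equal(equilibrium_from_fit(0.35, -0.5), 0.7,
               ignore_attr = "in_range")
  expect_equal(equilibrium_from_fit(0, -0.3), 0, ignore_attr = "in_range")
  out <- equilibrium_from_fit(c(0.35, 1), c(-0.5, -0.5))
  expect_equal(attr(out, "in_range"), c(TRUE, FALSE))
  expect_error(equilibrium_from_fit(0.2, 0), "D = 0")
})

test_that("host-year frequencies match the Beta-Binomial conjugate oracle", {
  series <- tibble::tibble(
    locality = "A", year = 2000L, host = "Adenostoma",
    n_striped = 70L, n_green = 30L, n_melanic = 0L
  )
  out <- fit_host_year_frequencies(series)
  expect_equal(out$freq, stats::qbeta(0.5, 71, 31))
  expect_equal(out$freq_lo, stats::qbeta(0.025, 71, 31))
  expect_equal(out$freq_hi, stats::qbeta(0.975, 71, 31))
  expect_lt(abs(out$freq - 0.70), 0.01)
})

test_that("host-year frequencies are flat for identical counts and skip empty cells", {
  series <- tibble::tibble(
    locality = "A", year = rep(2000:2004, each = 2),
    host = rep(c("Adenostoma", "Ceanothus"), 5),
    n_striped = rep(c(40L, 0L), 5), n_green = rep(c(60L, 0L), 5),
    n_melanic = 0L
  )
  out <- fit_host_year_frequencies(series)
  # the empty Ceanothus cells are omitted
  expect_equal(unique(out$host), "Adenostoma")
  expect_equal(length(unique(out$freq)), 1)
})

test_that("a noise-free series recovers the OLS slope of delta-p on p", {
  cfg <- sim_config(
    n_localities = 3, years_per_locality = 20,
    D_true = -0.5, p_eq_true = c(0.4, 0.6, 0.7), p0 = c(0.1, 0.2, 0.97),
    Ne = 1e9, forcing_sd = 0, sample_size = 1e5, seed = 101
  )
  sim <- sim_morph_series(cfg)
  fit <- fit_d_model(sim$counts, mcmc = tiny_mcmc(), seed = 102,
                     rhat_limit = Inf)
  ols <- sim$counts |>
    dplyr::group_by(locality, year) |>
    dplyr::summarise(p = sum(n_striped) / sum(n_striped + n_green),
                     .groups = "drop") |>
    dplyr::group_by(locality) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(diff(p) ~ p[-length(p)]))[2],
      .groups = "drop"
    )
  merged <- dplyr::inner_join(fit$estimates, ols, by = "locality")
  expect_true(all(abs(merged$D - merged$slope) < 0.02))
  expect_true(all(merged$class == "converging"))
})

test_that("the fitted equilibrium equals -alpha/D draw by draw", {
  fit <- fixture_fit()
  expect_equal(fit$draws$p_eq, -fit$draws$alpha / fit$draws$D)
  # and the reported medians summarise those draws
  expect_equal(fit$estimates$p_eq_hat,
               apply(fit$draws$p_eq, 2, stats::median), ignore_attr = TRUE)
})

test_that("the hierarchical fit returns coherent per-locality summaries", {
  fit <- fixture_fit()
  est <- fit$estimates
  expect_equal(nrow(est), 4)
  expect_true(all(est$D_lo <= est$D & est$D <= est$D_hi))
  expect_true(all(est$D < 0))
  expect_true(all(est$sigma > 0))
  expect_equal(nrow(fit$trajectories), 4 * 15)
  expect_equal(nrow(fit$deltas), 4 * 14)
  expect_true(all(fit$trajectories$p >= 0 & fit$trajectories$p <= 1))
  # identical seed reproduces the fit
  fit2 <- fit_d_model(fixture_sim()$counts, mcmc = tiny_mcmc(), seed = 12,
                      rhat_limit = Inf)
  expect_equal(fit2$estimates, est)
})

test_that("fit_d_model errors cleanly without eligible localities", {
  series <- tibble::tibble(
    locality = "A", year = c(2000L, 2002L), host = "Adenostoma",
    n_striped = 5L, n_green = 5L, n_melanic = 0L
  )
  expect_error(fit_d_model(series), "no eligible localities")
})

test_that("equilibrium_vs_mean tracks the observed mean frequencies", {
  fit <- fixture_fit()
  out <- equilibrium_vs_mean(fit, fixture_sim()$counts)
  expect_equal(out$n_localities, 4)
  expect_gt(out$r, 0.9)
  short <- fit
  short$estimates <- short$estimates[1:2, ]
  expect_error(equilibrium_vs_mean(short, fixture_sim()$counts),
               "at least 3")
})

test_that("equilibrium_vs_host fits the simple linear regression", {
  fake <- structure(
    list(estimates = tibble::tibble(
      locality = sprintf("L%02d", 1:5),
      p_eq_hat = 0.1 + 0.008 * c(10, 30, 50, 70, 90) +
        c(1, -1, 2, -2, 0) * 1e-9
    )),
    class = "nfds_d_fit"
  )
  out <- equilibrium_vs_host(fake, c(10, 30, 50, 70, 90))
  expect_equal(out$r_squared, 1, tolerance = 1e-6)
  expect_equal(out$slope, 0.008, tolerance = 1e-6)
  expect_error(equilibrium_vs_host(fake, c(10, 30)), "length must match")
})
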
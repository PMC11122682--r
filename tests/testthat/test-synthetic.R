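test_that("sim_config validates its inputs", {
  expect_error(sim_config(p_eq_true = 1.2), "open interval")
  expect_error(sim_config(forcing_sd = -0.1))
  expect_error(sim_config(sample_size = 0))
  cfg <- sim_config(n_localities = 3, D_true = -0.5)
  expect_length(cfg$D_true, 3)
  expect_length(cfg$p_eq_true, 3)
})

test_that("the generator is deterministic in (config, seed)", {
  cfg <- sim_config(n_localities = 3, seed = 99)
  expect_identical(sim_morph_series(cfg), sim_morph_series(cfg))
  cfg2 <- sim_config(n_localities = 3, seed = 100)
  expect_false(identical(sim_morph_series(cfg)$counts,
                         sim_morph_series(cfg2)$counts))
})

test_that("counts are non-negative and conserve the sample size", {
  sim <- sim_morph_series(sim_config(n_localities = 4, seed = 5))
  counts <- sim$counts
  expect_true(all(counts$n_striped >= 0 & counts$n_green >= 0 &
                    counts$n_melanic >= 0))
  totals <- counts |>
    dplyr::count(locality, year,
                 wt = n_striped + n_green + n_melanic, name = "total")
  expect_true(all(totals$total == 70))
  # years are consecutive integers within each locality
  by_loc <- split(unique(counts[, c("locality", "year")])$year,
                  unique(counts[, c("locality", "year")])$locality)
  expect_true(all(vapply(by_loc, function(y) all(diff(sort(y)) == 1),
                         logical(1))))
})

test_that("latent frequencies stay in [0, 1] and the absorbed flag is consistent", {
  sim <- sim_morph_series(sim_config(n_localities = 6, Ne = 2, p0 = 0.05,
                                     D_true = 0, forcing_sd = 0,
                                     years_per_locality = 30, seed = 3))
  expect_true(all(sim$truth$p_true >= 0 & sim$truth$p_true <= 1))
  flag <- sim$truth |>
    dplyr::group_by(locality) |>
    dplyr::summarise(absorbed = absorbed[1],
                     hit = any(p_true %in% c(0, 1)), .groups = "drop")
  expect_equal(flag$absorbed, flag$hit)
})

test_that("drift variance matches p(1-p)/(2Ne) (D = 0, no forcing)", {
  ne <- 1000
  sim <- sim_morph_series(sim_config(
    n_localities = 100, years_per_locality = 101, D_true = 0,
    p_eq_true = 0.5, p0 = 0.5, Ne = ne, forcing_sd = 0, sample_size = 1,
    seed = 21
  ))
  z <- sim$truth |>
    dplyr::group_by(locality) |>
    dplyr::reframe(z = diff(p_true) /
                     sqrt(p_true[-dplyr::n()] * (1 - p_true[-dplyr::n()]) /
                            (2 * ne)))
  expect_gte(nrow(z), 1e4)
  # standardised one-step changes have unit variance under pure drift
  expect_lt(abs(stats::var(z$z) - 1), 0.05)
  expect_lt(abs(mean(z$z)), 0.02)
})

test_that("the NFDS pull moves the frequency toward the equilibrium", {
  # drift and forcing off: one step from 0.9 with D=-0.5, p_eq=0.7 is 0.8
  sim <- sim_morph_series(sim_config(
    n_localities = 1, years_per_locality = 2, D_true = -0.5,
    p_eq_true = 0.7, p0 = 0.9, Ne = 1e9, forcing_sd = 0, seed = 1
  ))
  expect_lt(abs(sim$truth$p_true[2] - 0.8), 1e-6)
})

test_that("host assignment follows the locality's host composition", {
  sim <- sim_morph_series(sim_config(n_localities = 2, pct_adenostoma = 100,
                                     seed = 8))
  cea <- sim$counts[sim$counts$host == "Ceanothus", ]
  expect_true(all(cea$n_striped + cea$n_green + cea$n_melanic == 0))
})

test_that("sim_transplant_experiment reproduces the 21-treatment design", {
  ex <- sim_transplant_experiment(seed = 4)
  expect_equal(nrow(ex), 21)
  expect_equal(ex$release_freq, seq(0, 1, by = 0.05))
  expect_equal(ex$released_striped, as.integer(round(seq(0, 1, by = 0.05) * 20)))
  expect_true(all(ex$released_striped + ex$released_other == 20))
  expect_true(all(ex$recaptured_striped <= ex$released_striped))
  expect_true(all(ex$recaptured_other <= ex$released_other))
  expect_identical(ex, sim_transplant_experiment(seed = 4))
  expect_warning(sim_transplant_experiment(release_freqs = 0.33),
                 "rounded half-to-even")
})

test_that("sim_advantage_experiment respects the blocked design", {
  ex <- sim_advantage_experiment(seed = 2)
  expect_equal(nrow(ex), 8)
  expect_true(all(ex$released_striped == 10 & ex$released_melanic == 10))
  expect_true(all(ex$recaptured_striped <= 10 & ex$recaptured_melanic <= 10))
  # a strongly positive log-odds advantage shows up in raw recaptures
  big <- sim_advantage_experiment(n_blocks = 200, n_per_morph = 50,
                                  beta = 2, seed = 9)
  expect_gt(sum(big$recaptured_striped), sum(big$recaptured_melanic))
})

test_that("sim_genotypes validates and generates six-cluster dosage data", {
  expect_error(sim_genotypes(10, rep(0.2, 6)), "sum to 1")
  expect_error(sim_genotypes(10, c(-0.1, 0.3, 0.2, 0.2, 0.2, 0.2)),
               "non-negative")
  gs <- sim_genotypes(50, rep(1 / 6, 6), n_snps = 40, seed = 6)
  expect_equal(nrow(gs$individuals), 50)
  expect_true(all(gs$individuals$genotype_cluster %in%
                    genotype_cluster_levels()))
  expect_equal(dim(gs$snps), c(50, 40))
  expect_true(all(gs$snps %in% 0:2))
  expect_identical(gs, sim_genotypes(50, rep(1 / 6, 6), n_snps = 40, seed = 6))
})
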
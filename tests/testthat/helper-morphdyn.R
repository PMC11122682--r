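# Shared fixtures for the test suite. MCMC-based fixtures are built once
# per test run and cached.

.fixtures <- new.env(parent = emptyenv())

tiny_mcmc <- function(chains = 2, warmup = 1500, iter = 1500) {
  mcmc_settings(chains = chains, warmup = warmup, iter = iter, adapt = 400)
}

fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(
      n_localities = 4, years_per_locality = 15,
      D_true = rep(-0.5, 4), p_eq_true = c(0.3, 0.5, 0.6, 0.7),
      sample_size = 150, seed = 11
    )
    .fixtures$sim <- sim_morph_series(cfg)
  }
  .fixtures$sim
}

# One shared hierarchical D fit reused across test files (R-hat recorded
# but not gated here; convergence gating has its own test).
fixture_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- fit_d_model(
      fixture_sim()$counts, min_pairs = 10,
      mcmc = tiny_mcmc(), seed = 12, rhat_limit = Inf
    )
  }
  .fixtures$fit
}
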
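# Internal helpers around rjags: reproducible chain initialisation,
# posterior summaries, split-chain R-hat, and WAIC from pointwise
# log-likelihood draws.

#' MCMC settings
#'
#' @param chains Number of chains.
#' @param warmup Burn-in iterations per chain (after adaptation).
#' @param iter Retained sampling iterations per chain.
#' @param adapt Adaptation iterations.
#' @param thin Thinning interval.
#' @return A `mcmc_settings` list.
#' @export
mcmc_settings <- function(chains = 4, warmup = 2000, iter = 2000,
                          adapt = 500, thin = 1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, adapt >= 100, thin >= 1)
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 adapt = adapt, thin = thin), class = "mcmc_settings")
}

# Run a JAGS model with seed-derived per-chain RNG state. Returns a list
# with $draws (named list of matrices, total iterations x dims) and
# $chains (list of per-chain mcmc matrices) for diagnostics.
run_jags <- function(model_string, data, monitor, mcmc, seed, inits = NULL) {
  stopifnot(inherits(mcmc, "mcmc_settings"))
  seed <- as.integer(seed)
  chain_inits <- lapply(seq_len(mcmc$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (seed * 101L + ch) %% .Machine$integer.max)
    if (!is.null(inits)) ini <- c(ini, inits)
    ini
  })
  model <- rjags::jags.model(
    textConnection(model_string), data = data, inits = chain_inits,
    n.chains = mcmc$chains, n.adapt = mcmc$adapt, quiet = TRUE
  )
  if (mcmc$warmup > 0) {
    stats::update(model, n.iter = mcmc$warmup, progress.bar = "none")
  }
  samp <- rjags::coda.samples(model, variable.names = monitor,
                              n.iter = mcmc$iter, thin = mcmc$thin,
                              progress.bar = "none")
  chains <- lapply(samp, as.matrix)
  all_draws <- do.call(rbind, chains)
  vars <- sub("\\[.*$", "", colnames(all_draws))
  draws <- lapply(split(seq_along(vars), vars), function(idx) {
    all_draws[, idx, drop = FALSE]
  })
  list(draws = draws, chains = chains)
}

# Split-chain potential scale reduction factor for one parameter column.
split_rhat_one <- function(cols) {
  halves <- unlist(lapply(cols, function(v) {
    n <- length(v) %/% 2
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# R-hat for every column of a monitored matrix across chains.
split_rhat <- function(chains, columns) {
  vapply(columns, function(cn) {
    split_rhat_one(lapply(chains, function(ch) ch[, cn]))
  }, numeric(1))
}

# Posterior median and 95% equal-tailed probability interval.
post_summary <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  c(median = q[1], lo = q[2], hi = q[3])
}

# WAIC from an iterations x observations matrix of pointwise
# log-likelihoods.
waic_from_loglik <- function(ll) {
  lppd <- sum(apply(ll, 2, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  }))
  p_waic <- sum(apply(ll, 2, stats::var))
  c(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}
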
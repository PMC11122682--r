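# Models for the frequency-manipulation transplant experiments: linear
# versus sigmoidal NFDS fitness functions (with WAIC comparison), the
# experiment-level D regression, and the striped-versus-melanic
# advantage GLM.

# Bushes that released zero of a morph contribute only the other morph's
# likelihood: the observation loops run over index vectors of bushes with
# positive releases (JAGS dbin needs a positive size).
fitness_lik_block <- "
  for (i in 1:B) {
    logit(qg[i]) <- g0 + u[i]
    u[i] ~ dnorm(0, tau_u)
    qs[i] <- max(0.001, min(0.999, w[i] * qg[i]))
  }
  for (k in 1:Bs) {
    ys[k] ~ dbin(qs[idx_s[k]], ns[k])
    ll_s[k] <- logdensity.bin(ys[k], qs[idx_s[k]], ns[k])
  }
  for (k in 1:Bg) {
    yg[k] ~ dbin(qg[idx_g[k]], ng[k])
    ll_g[k] <- logdensity.bin(yg[k], qg[idx_g[k]], ng[k])
  }
  g0 ~ dnorm(0, 0.25)
  sd_u ~ dnorm(0, 1) T(0,)
  tau_u <- pow(sd_u, -2)
"

fitness_model_linear <- paste0("
model {
  for (i in 1:B) {
    w[i] <- a + b * pfreq[i]
  }
", fitness_lik_block, "
  a ~ dnorm(1, 1) T(0,)
  b ~ dnorm(0, 1)
}
")

fitness_model_sigmoidal <- paste0("
model {
  for (i in 1:B) {
    w[i] <- lower + (upper - lower) / (1 + exp(-steep * (pfreq[i] - mid)))
  }
", fitness_lik_block, "
  lower ~ dnorm(1, 1) T(0,)
  upper ~ dnorm(1, 1) T(0,)
  mid ~ dunif(0, 1)
  steep ~ dnorm(0, 0.01)
}
")

#' Fit an NFDS fitness function to a transplant experiment
#'
#' Binomial likelihood for per-bush recaptures of each morph. The green
#' (unstriped) recapture probability has a bush-level random effect on
#' the logit scale (bushes differ in baseline survival); the striped
#' probability is the green probability times the relative fitness
#' `w(p)` of the striped morph at the bush's release stripe frequency
#' `p`. `w` is either linear, `a + b * p`, or a four-parameter logistic
#' ("sigmoidal", step-like): `lower + (upper - lower) /
#' (1 + exp(-steepness * (p - midpoint)))`. The product `w * q_green` is
#' constrained to (0.001, 0.999). Because relative fitness multiplies
#' the shared bush baseline, it is invariant to bush-level rescaling of
#' both morphs' recapture probabilities by construction.
#'
#' Models are scored by WAIC computed from pointwise posterior
#' log-likelihood draws; `form = "both"` fits both and reports the
#' difference.
#'
#' @param table Experiment tibble with columns `release_freq` (or
#'   computable from releases), `released_striped`, `released_other`,
#'   `recaptured_striped`, `recaptured_other`. Bushes with zero released
#'   of a morph contribute only the other morph's likelihood.
#' @param form `"linear"`, `"sigmoidal"`, or `"both"`.
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed.
#' @return For a single form, a `fitness_fit` with `params` (posterior
#'   tibble), `draws`, `waic`, `equilibrium` (see
#'   [predict_equilibrium_from_fitness()]); for `"both"`, a
#'   `fitness_comparison` list with both fits, a `comparison` tibble and
#'   the `preferred` form (lower WAIC).
#' @export
fit_fitness_function <- function(table, form = c("linear", "sigmoidal", "both"),
                                 mcmc = mcmc_settings(), seed = 1) {
  form <- match.arg(form)
  if (form == "both") {
    lin <- fit_fitness_function(table, "linear", mcmc, seed)
    sig <- fit_fitness_function(table, "sigmoidal", mcmc, seed)
    cmp <- tibble::tibble(
      form = c("linear", "sigmoidal"),
      waic = c(lin$waic["waic"], sig$waic["waic"])
    )
    cmp$delta_waic <- cmp$waic - min(cmp$waic)
    return(structure(
      list(linear = lin, sigmoidal = sig, comparison = cmp,
           preferred = cmp$form[which.min(cmp$waic)]),
      class = "fitness_comparison"
    ))
  }
  tab <- prep_experiment(table)
  if (nrow(tab) < 5 || length(unique(tab$release_freq)) < 3) {
    stop("need >= 5 bushes spanning >= 3 distinct release frequencies",
         call. = FALSE)
  }
  is_s <- which(tab$released_striped > 0)
  is_g <- which(tab$released_other > 0)
  data <- list(
    B = nrow(tab), pfreq = tab$release_freq,
    Bs = length(is_s), idx_s = is_s,
    ys = tab$recaptured_striped[is_s], ns = tab$released_striped[is_s],
    Bg = length(is_g), idx_g = is_g,
    yg = tab$recaptured_other[is_g], ng = tab$released_other[is_g]
  )
  model <- if (form == "linear") fitness_model_linear else fitness_model_sigmoidal
  pars <- if (form == "linear") c("a", "b") else c("lower", "upper", "mid", "steep")
  fit <- run_jags(model, data, monitor = c(pars, "g0", "sd_u", "ll_s", "ll_g"),
                  mcmc = mcmc, seed = seed)
  draws <- do.call(cbind, fit$draws[pars])
  colnames(draws) <- pars
  params <- purrr::map_dfr(pars, function(v) {
    q <- post_summary(draws[, v])
    tibble::tibble(term = v, estimate = q["median"],
                   lo = q["lo"], hi = q["hi"])
  })
  out <- structure(
    list(
      form = form, params = params, draws = draws,
      waic = waic_from_loglik(cbind(fit$draws$ll_s, fit$draws$ll_g)),
      data = tab, mcmc = mcmc, seed = seed
    ),
    class = "fitness_fit"
  )
  out$equilibrium <- predict_equilibrium_from_fitness(out)
  out
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("<fitness_fit>", x$form, "relative-fitness function; WAIC =",
      round(x$waic["waic"], 1), "\n")
  print(x$params)
  if (is.na(x$equilibrium$equilibrium)) {
    cat("no internal equilibrium (fitted function does not cross 1 in [0,1])\n")
  } else {
    cat("predicted equilibrium stripe frequency:",
        round(x$equilibrium$equilibrium, 3), "\n")
  }
  invisible(x)
}

#' @export
print.fitness_comparison <- function(x, ...) {
  cat("<fitness_comparison> preferred form:", x$preferred, "\n")
  print(x$comparison)
  invisible(x)
}

prep_experiment <- function(table) {
  tab <- tibble::as_tibble(table)
  if (!"release_freq" %in% names(tab)) {
    tab$release_freq <- tab$released_striped /
      (tab$released_striped + tab$released_other)
  }
  tab
}

#' Relative fitness at given frequencies from parameter values
#'
#' Evaluates the linear (`a + b * p`) or four-parameter logistic
#' relative-fitness function at `p`.
#'
#' @param params Named vector/list: `a`, `b` (linear) or `lower`,
#'   `upper`, `mid`, `steep` (sigmoidal).
#' @param p Frequencies.
#' @param form `"linear"` or `"sigmoidal"`.
#' @return Numeric vector of relative fitness values.
#' @export
relative_fitness <- function(params, p, form = c("linear", "sigmoidal")) {
  form <- match.arg(form)
  params <- as.list(params)
  if (form == "linear") {
    params$a + params$b * p
  } else {
    params$lower + (params$upper - params$lower) /
      (1 + exp(-params$steep * (p - params$mid)))
  }
}

#' Solve the fitness function for its internal equilibrium
#'
#' The equilibrium is the frequency where the relative fitness of the
#' striped morph equals 1. Closed form for the linear model,
#' `(1 - a) / b`; bisection for the sigmoidal model. If the function
#' never crosses 1 inside \[0, 1\] the result is `NA` with
#' `no_crossing = TRUE`.
#'
#' @inheritParams relative_fitness
#' @return Tibble with `equilibrium` and `no_crossing`.
#' @export
solve_fitness_equilibrium <- function(params, form = c("linear", "sigmoidal")) {
  form <- match.arg(form)
  params <- as.list(params)
  no_eq <- tibble::tibble(equilibrium = NA_real_, no_crossing = TRUE)
  if (form == "linear") {
    if (params$b == 0) {
      return(no_eq)
    }
    p_star <- (1 - params$a) / params$b
    if (p_star < 0 || p_star > 1) {
      return(no_eq)
    }
    return(tibble::tibble(equilibrium = p_star, no_crossing = FALSE))
  }
  f <- function(p) relative_fitness(params, p, "sigmoidal") - 1
  if (sign(f(0)) == sign(f(1)) && f(0) != 0 && f(1) != 0) {
    return(no_eq)
  }
  root <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
  tibble::tibble(equilibrium = root, no_crossing = FALSE)
}

#' Predicted equilibrium frequency from a fitted fitness function
#'
#' Solves `w(p) = 1` on the posterior-median parameters, and reports the
#' equal-tailed interval of the draw-wise crossings together with the
#' posterior fraction of draws whose fitness function crosses 1 inside
#' \[0, 1\].
#'
#' @param fit A `fitness_fit`.
#' @return Tibble with `equilibrium`, `lo`, `hi`, `prop_crossing`,
#'   `no_crossing`.
#' @export
predict_equilibrium_from_fitness <- function(fit) {
  stopifnot(inherits(fit, "fitness_fit"))
  med <- stats::setNames(fit$params$estimate, fit$params$term)
  point <- solve_fitness_equilibrium(med, fit$form)
  eq_draws <- apply(fit$draws, 1, function(d) {
    solve_fitness_equilibrium(d, fit$form)$equilibrium
  })
  ok <- !is.na(eq_draws)
  tibble::tibble(
    equilibrium = point$equilibrium,
    lo = if (any(ok)) stats::quantile(eq_draws[ok], 0.025, names = FALSE) else NA_real_,
    hi = if (any(ok)) stats::quantile(eq_draws[ok], 0.975, names = FALSE) else NA_real_,
    prop_crossing = mean(ok),
    no_crossing = point$no_crossing
  )
}

experiment_d_model <- "
model {
  for (i in 1:B) {
    ys[i] ~ dbin(pprime[i], m[i])
    pprime[i] ~ dnorm(p[i] + alpha + D * p[i], tau) T(0,1)
  }
  alpha ~ dnorm(0, 1)
  D ~ dnorm(0, 1)
  sigma ~ dnorm(0, 1) T(0,)
  tau <- pow(sigma, -2)
}
"

#' Experiment-level D from a transplant experiment
#'
#' Treats each bush as one generation of evolution: the release stripe
#' frequency is `p`, the recapture stripe frequency is a latent `p'`
#' observed through binomial counts among total recaptures, and
#' `p' - p` is regressed on `p` with a single intercept and slope
#' (`delta-p = alpha + D * p`), the non-hierarchical analogue of the
#' time-series model. Bushes with zero total recaptures carry no
#' information about `p'` and are dropped with a message.
#'
#' @param table Experiment tibble (see [fit_fitness_function()]).
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed.
#' @return Object of class `experiment_d_fit`: `estimates` (tibble with
#'   `D`, `alpha`, `p_eq_hat` and ETPIs) and `draws`.
#' @export
fit_experiment_d <- function(table, mcmc = mcmc_settings(), seed = 1) {
  tab <- prep_experiment(table)
  m <- tab$recaptured_striped + tab$recaptured_other
  if (any(m == 0)) {
    message("dropping ", sum(m == 0), " bush(es) with zero total recaptures")
    tab <- tab[m > 0, ]
    m <- m[m > 0]
  }
  if (length(unique(tab$release_freq)) < 2) {
    stop("all bushes share one release frequency: no slope identifiable",
         call. = FALSE)
  }
  data <- list(B = nrow(tab), p = tab$release_freq,
               ys = tab$recaptured_striped, m = m)
  fit <- run_jags(experiment_d_model, data,
                  monitor = c("alpha", "D", "sigma"), mcmc = mcmc, seed = seed)
  D <- as.numeric(fit$draws$D)
  alpha <- as.numeric(fit$draws$alpha)
  peq <- -alpha / D
  Dq <- post_summary(D); aq <- post_summary(alpha); pq <- post_summary(peq)
  structure(
    list(
      estimates = tibble::tibble(
        D = Dq["median"], D_lo = Dq["lo"], D_hi = Dq["hi"],
        alpha = aq["median"], alpha_lo = aq["lo"], alpha_hi = aq["hi"],
        p_eq_hat = pq["median"], p_eq_lo = pq["lo"], p_eq_hi = pq["hi"]
      ),
      draws = list(D = D, alpha = alpha, p_eq = peq),
      data = tab, seed = seed
    ),
    class = "experiment_d_fit"
  )
}

#' @export
print.experiment_d_fit <- function(x, ...) {
  cat("<experiment_d_fit> D =", round(x$estimates$D, 3),
      "[", round(x$estimates$D_lo, 3), ",", round(x$estimates$D_hi, 3), "];",
      "p_eq_hat =", round(x$estimates$p_eq_hat, 3), "\n")
  invisible(x)
}

advantage_model <- "
model {
  for (i in 1:B) {
    ys[i] ~ dbin(qs[i], ns[i])
    ym[i] ~ dbin(qm[i], nm[i])
    logit(qs[i]) <- b0 + u[i] + beta
    logit(qm[i]) <- b0 + u[i]
    u[i] ~ dnorm(0, tau_u)
  }
  b0 ~ dnorm(0, 0.25)
  beta ~ dnorm(0, 0.25)
  sd_u ~ dnorm(0, 1) T(0,)
  tau_u <- pow(sd_u, -2)
}
"

#' Striped-versus-melanic fitness advantage (blocked mark-recapture GLM)
#'
#' Hierarchical Bayesian logistic model of recapture on morph with a
#' block-level random effect: `logit(q) = b0 + u_block + beta * striped`.
#' `beta` is the log-odds recapture (survival) advantage of the striped
#' morph. Blocks with zero recaptures of both morphs are retained (they
#' inform the intercept and shrinkage).
#'
#' @param table Tibble with columns `block`, `released_striped`,
#'   `released_melanic`, `recaptured_striped`, `recaptured_melanic`.
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed.
#' @return Object of class `morph_advantage_fit`: `estimates` (tibble
#'   with `beta` median and 95% ETPI), `blocks` (block effects), `draws`.
#' @export
fit_morph_advantage <- function(table, mcmc = mcmc_settings(), seed = 1) {
  tab <- tibble::as_tibble(table)
  if (nrow(tab) < 2) {
    stop("need >= 2 blocks", call. = FALSE)
  }
  data <- list(
    B = nrow(tab),
    ys = tab$recaptured_striped, ns = tab$released_striped,
    ym = tab$recaptured_melanic, nm = tab$released_melanic
  )
  fit <- run_jags(advantage_model, data,
                  monitor = c("beta", "b0", "u", "sd_u"),
                  mcmc = mcmc, seed = seed)
  beta <- as.numeric(fit$draws$beta)
  bq <- post_summary(beta)
  u <- fit$draws$u
  blocks <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    q <- post_summary(u[, i])
    tibble::tibble(block = tab$block[i], effect = q["median"],
                   lo = q["lo"], hi = q["hi"])
  })
  structure(
    list(
      estimates = tibble::tibble(beta = bq["median"], beta_lo = bq["lo"],
                                 beta_hi = bq["hi"]),
      blocks = blocks,
      draws = list(beta = beta, b0 = as.numeric(fit$draws$b0)),
      data = tab, seed = seed
    ),
    class = "morph_advantage_fit"
  )
}

#' @export
print.morph_advantage_fit <- function(x, ...) {
  cat("<morph_advantage_fit> beta =", round(x$estimates$beta, 2),
      "95% ETPI [", round(x$estimates$beta_lo, 2), ",",
      round(x$estimates$beta_hi, 2), "]\n")
  invisible(x)
}
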
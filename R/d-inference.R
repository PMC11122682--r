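# Hierarchical Bayesian estimation of the NFDS parameter D, the intercept
# alpha and the equilibrium frequency per locality from replicated
# morph-count time series, plus the equilibrium-versus-mean and
# equilibrium-versus-host-composition summaries and per-year host
# frequency estimates.

# Pool hosts within locality-year and compute the stripe-versus-green
# sample frequency (melanics are excluded from the NFDS pair).
pool_hosts <- function(series) {
  series |>
    dplyr::group_by(.data$locality, .data$year) |>
    dplyr::summarise(
      n_striped = sum(.data$n_striped),
      n_green = sum(.data$n_green),
      n_melanic = sum(.data$n_melanic),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_pair = .data$n_striped + .data$n_green,
      p_raw = ifelse(.data$n_pair > 0, .data$n_striped / .data$n_pair, NA_real_)
    ) |>
    dplyr::arrange(.data$locality, .data$year)
}

count_pairs <- function(pooled) {
  pooled |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(
      n_pairs = sum(diff(sort(.data$year)) == 1L),
      .groups = "drop"
    )
}

#' Localities eligible for D estimation
#'
#' A locality qualifies when, after pooling hosts, it has at least
#' `min_pairs` pairs of consecutive years (each pair contributes one
#' (p, delta-p) observation to the D regression).
#'
#' @param series Morph-count tibble (`locality`, `year`, `host`,
#'   `n_striped`, `n_green`, `n_melanic`).
#' @param min_pairs Minimum number of consecutive-year pairs.
#' @return Character vector of eligible locality identifiers.
#' @export
eligible_localities <- function(series, min_pairs = 10) {
  if (nrow(series) == 0) return(character(0))
  pairs <- count_pairs(pool_hosts(series))
  sort(pairs$locality[pairs$n_pairs >= min_pairs])
}

d_model_hier <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
  }
  for (r in 1:Nroot) {
    z[r] ~ dnorm(0, 0.44444444)
    p[root[r]] <- ilogit(z[r])
  }
  for (k in 1:Npair) {
    mu[k] <- p[a[k]] + alphac[locp[k]] + D[locp[k]] * (p[a[k]] - pbar[locp[k]])
    p[b[k]] ~ dnorm(mu[k], tau[locp[k]]) T(0,1)
  }
  for (j in 1:J) {
    alphac[j] ~ dnorm(0, 1)
    alpha[j] <- alphac[j] - D[j] * pbar[j]
    eta[j] ~ dnorm(0, 1)
    D[j] <- mu_D + sd_D * eta[j]
    sigma[j] ~ dnorm(0, 1) T(0,)
    tau[j] <- pow(sigma[j], -2)
  }
  mu_D ~ dnorm(0, 1)
  sd_D ~ dnorm(0, 1) T(0,)
}
"

# Index records of one pooled series into chain roots and consecutive
# pairs (years with no predecessor start a new chain; gaps break chains).
index_chains <- function(pooled) {
  pooled <- dplyr::arrange(pooled, .data$locality, .data$year)
  key <- paste(pooled$locality, pooled$year)
  prev <- match(paste(pooled$locality, pooled$year - 1L), key)
  has_prev <- !is.na(prev)
  list(
    pooled = pooled,
    root = which(!has_prev),
    a = prev[has_prev],
    b = which(has_prev)
  )
}

#' Fit the hierarchical NFDS model to a morph-count time series
#'
#' The model treats the yearly stripe frequency in each locality as a
#' latent quantity `p[j, t]` observed through binomial counts
#' `y ~ Binomial(n, p)` (hosts pooled within locality; melanics
#' excluded from the stripe/green pair). Between consecutive years the
#' frequency follows the linear NFDS regression
#' `delta-p = alpha_j + D_j * p` plus Normal(0, sigma_j) residual noise
#' (which absorbs drift, gene flow and non-NFDS selection), truncated so
#' frequencies stay in (0, 1). The locality-level slopes are partially
#' pooled: `D_j ~ Normal(mu_D, sd_D)`. Priors are weakly informative:
#' logit-scale Normal(0, 1.5) on chain-initial frequencies, Normal(0, 1)
#' on `alpha_j` and `mu_D`, half-Normal(1) on `sigma_j` and `sd_D`.
#'
#' The per-locality equilibrium `p_eq_hat = -alpha / D` is computed
#' draw-by-draw from the joint posterior.
#'
#' @param series Morph-count tibble.
#' @param localities Localities to fit; defaults to
#'   [eligible_localities()] under `min_pairs`.
#' @param min_pairs Eligibility threshold (consecutive-year pairs).
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed; fixed seed gives reproducible chains.
#' @param rhat_limit Error if split-chain R-hat on any `D_j` exceeds this
#'   (set to `Inf` to disable the gate).
#' @return An object of class `nfds_d_fit` with elements `estimates`
#'   (per-locality tibble: `D`, `alpha`, `sigma` posterior median/ETPI,
#'   `p_eq_hat` with in-range flag, dynamics `class`), `hyper`
#'   (posterior of `mu_D`, `sd_D`), `trajectories` (latent yearly
#'   frequencies, median and 95% ETPI), `deltas` (per consecutive pair),
#'   `draws`, `rhat`, and the pooled data.
#' @export
fit_d_model <- function(series, localities = NULL, min_pairs = 10,
                        mcmc = mcmc_settings(), seed = 1,
                        rhat_limit = 1.05) {
  if (is.null(localities)) {
    localities <- eligible_localities(series, min_pairs)
  }
  if (length(localities) == 0) {
    stop("no eligible localities (need >= ", min_pairs,
         " consecutive-year pairs)", call. = FALSE)
  }
  pooled <- pool_hosts(dplyr::filter(series, .data$locality %in% localities))
  idx <- index_chains(pooled)
  pooled <- idx$pooled
  loc_levels <- sort(unique(pooled$locality))
  J <- length(loc_levels)
  loc_i <- match(pooled$locality, loc_levels)

  data <- list(
    y = pooled$n_striped, n = pooled$n_pair, N = nrow(pooled),
    root = idx$root, Nroot = length(idx$root),
    a = idx$a, b = idx$b, Npair = length(idx$b),
    locp = loc_i[idx$b], J = J,
    # per-locality centring constant for the regressor (exact
    # reparameterisation; decorrelates intercept and slope)
    pbar = vapply(split(pooled$p_raw, loc_i), function(v) {
      m <- mean(v, na.rm = TRUE)
      if (is.finite(m)) m else 0.5
    }, numeric(1))
  )
  fit <- run_jags(d_model_hier, data,
                  monitor = c("D", "alpha", "sigma", "mu_D", "sd_D", "p"),
                  mcmc = mcmc, seed = seed)

  d_cols <- grep("^D(\\[|$)", colnames(fit$chains[[1]]), value = TRUE)
  rhat <- split_rhat(fit$chains, d_cols)
  names(rhat) <- loc_levels
  if (any(rhat > rhat_limit, na.rm = TRUE)) {
    stop("MCMC did not converge: split R-hat on D exceeds ", rhat_limit,
         " for ", paste(loc_levels[which(rhat > rhat_limit)], collapse = ", "),
         " (R-hat: ",
         paste(sprintf("%.3f", rhat[rhat > rhat_limit]), collapse = ", "),
         "); increase warmup/iterations", call. = FALSE)
  }

  D_draws <- fit$draws$D
  a_draws <- fit$draws$alpha
  s_draws <- fit$draws$sigma
  peq_draws <- -a_draws / D_draws

  est <- purrr::map_dfr(seq_len(J), function(j) {
    Dq <- post_summary(D_draws[, j])
    aq <- post_summary(a_draws[, j])
    pq <- post_summary(peq_draws[, j])
    tibble::tibble(
      locality = loc_levels[j],
      D = Dq["median"], D_lo = Dq["lo"], D_hi = Dq["hi"],
      alpha = aq["median"], alpha_lo = aq["lo"], alpha_hi = aq["hi"],
      sigma = stats::median(s_draws[, j]),
      p_eq_hat = pq["median"], p_eq_lo = pq["lo"], p_eq_hi = pq["hi"],
      p_eq_in_range = pq["median"] >= 0 && pq["median"] <= 1,
      class = classify_dynamics(Dq["median"], quiet = TRUE),
      rhat_D = rhat[j]
    )
  })

  p_draws <- fit$draws$p
  traj <- purrr::map_dfr(seq_len(nrow(pooled)), function(i) {
    q <- post_summary(p_draws[, i])
    tibble::tibble(
      locality = pooled$locality[i], year = pooled$year[i],
      n = pooled$n_pair[i], p_raw = pooled$p_raw[i],
      p = q["median"], p_lo = q["lo"], p_hi = q["hi"]
    )
  })
  dp_draws <- p_draws[, idx$b, drop = FALSE] - p_draws[, idx$a, drop = FALSE]
  deltas <- purrr::map_dfr(seq_along(idx$b), function(k) {
    q <- post_summary(dp_draws[, k])
    tibble::tibble(
      locality = pooled$locality[idx$b[k]],
      year = pooled$year[idx$a[k]],
      p = stats::median(p_draws[, idx$a[k]]),
      delta_p = q["median"], delta_p_lo = q["lo"], delta_p_hi = q["hi"]
    )
  })

  structure(
    list(
      estimates = est,
      hyper = tibble::tibble(
        term = c("mu_D", "sd_D"),
        estimate = c(stats::median(fit$draws$mu_D),
                     stats::median(fit$draws$sd_D)),
        lo = c(stats::quantile(fit$draws$mu_D, 0.025),
               stats::quantile(fit$draws$sd_D, 0.025)),
        hi = c(stats::quantile(fit$draws$mu_D, 0.975),
               stats::quantile(fit$draws$sd_D, 0.975))
      ),
      trajectories = traj,
      deltas = deltas,
      draws = list(D = D_draws, alpha = a_draws, sigma = s_draws,
                   p_eq = peq_draws,
                   mu_D = as.numeric(fit$draws$mu_D),
                   sd_D = as.numeric(fit$draws$sd_D)),
      rhat = rhat,
      pooled = pooled,
      localities = loc_levels,
      mcmc = mcmc, seed = seed
    ),
    class = "nfds_d_fit"
  )
}

#' @export
print.nfds_d_fit <- function(x, ...) {
  cat("<nfds_d_fit>", length(x$localities), "localities;",
      "mean posterior-median D =", round(mean(x$estimates$D), 3), "\n")
  print(x$estimates[, c("locality", "D", "D_lo", "D_hi", "p_eq_hat", "class")])
  invisible(x)
}

#' Equilibrium frequency from the linear NFDS fit
#'
#' For the linear model `delta-p = alpha + D * p` the internal
#' equilibrium is `-alpha / D`. Values outside \[0, 1\] are returned but
#' flagged via the `in_range` attribute.
#'
#' @param alpha Intercept(s).
#' @param D Slope(s); must be nonzero.
#' @return Numeric vector of equilibria with an `in_range` logical
#'   attribute.
#' @export
equilibrium_from_fit <- function(alpha, D) {
  if (any(D == 0)) {
    stop("D = 0: no internal equilibrium exists", call. = FALSE)
  }
  out <- -alpha / D
  attr(out, "in_range") <- out >= 0 & out <= 1
  out
}

#' Correlation between fitted equilibria and observed mean frequencies
#'
#' Pearson correlation (two-sided t-approximation p-value) between each
#' locality's fitted equilibrium `p_eq_hat` and its observed mean stripe
#' frequency (mean of the yearly host-pooled sample frequencies).
#'
#' @param fit An `nfds_d_fit`.
#' @param series The morph-count tibble the fit was computed from.
#' @return Tibble with `r`, `p_value`, `n_localities`.
#' @export
equilibrium_vs_mean <- function(fit, series) {
  stopifnot(inherits(fit, "nfds_d_fit"))
  obs <- pool_hosts(series) |>
    dplyr::filter(.data$locality %in% fit$localities) |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(mean_freq = mean(.data$p_raw, na.rm = TRUE),
                     .groups = "drop")
  m <- dplyr::inner_join(fit$estimates, obs, by = "locality")
  if (nrow(m) < 3) {
    stop("need at least 3 localities for the correlation", call. = FALSE)
  }
  ct <- stats::cor.test(m$p_eq_hat, m$mean_freq, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_localities = nrow(m))
}

#' Regression of fitted equilibria on host-plant composition
#'
#' Simple linear regression of the fitted equilibrium stripe frequency on
#' the percentage of the thin-leaved host at each locality.
#'
#' @param fit An `nfds_d_fit`.
#' @param host_pct Tibble with columns `locality` and `pct_adenostoma`,
#'   or a numeric vector in the order of `fit$localities`.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_localities`.
#' @export
equilibrium_vs_host <- function(fit, host_pct) {
  stopifnot(inherits(fit, "nfds_d_fit"))
  if (is.data.frame(host_pct)) {
    m <- dplyr::inner_join(fit$estimates, host_pct, by = "locality")
    x <- m$pct_adenostoma
    y <- m$p_eq_hat
  } else {
    if (length(host_pct) != nrow(fit$estimates)) {
      stop("`host_pct` length must match the number of fitted localities",
           call. = FALSE)
    }
    x <- as.numeric(host_pct)
    y <- fit$estimates$p_eq_hat
  }
  lmfit <- stats::lm(y ~ x)
  sm <- summary(lmfit)
  tibble::tibble(
    slope = unname(stats::coef(lmfit)[2]),
    intercept = unname(stats::coef(lmfit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_localities = length(x)
  )
}

#' Yearly average stripe frequency by host plant
#'
#' Pools counts across localities within each year-by-host cell and
#' reports the exact conjugate Beta posterior (uniform Beta(1, 1) prior)
#' of the stripe-versus-green frequency: median and 95% ETPI. Cells with
#' no records on a host are omitted.
#'
#' @param series Morph-count tibble.
#' @param localities Optional locality filter.
#' @return Tibble with `year`, `host`, `n_striped`, `n_pair`, `freq`,
#'   `freq_lo`, `freq_hi`.
#' @export
fit_host_year_frequencies <- function(series, localities = NULL) {
  if (!is.null(localities)) {
    series <- dplyr::filter(series, .data$locality %in% localities)
  }
  series |>
    dplyr::group_by(.data$year, .data$host) |>
    dplyr::summarise(
      n_striped = sum(.data$n_striped),
      n_pair = sum(.data$n_striped + .data$n_green),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pair > 0) |>
    dplyr::mutate(
      freq = stats::qbeta(0.5, 1 + .data$n_striped,
                          1 + .data$n_pair - .data$n_striped),
      freq_lo = stats::qbeta(0.025, 1 + .data$n_striped,
                             1 + .data$n_pair - .data$n_striped),
      freq_hi = stats::qbeta(0.975, 1 + .data$n_striped,
                             1 + .data$n_pair - .data$n_striped)
    )
}
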
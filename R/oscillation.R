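# Test for dampening oscillations: hierarchical regression of the
# absolute year-to-year frequency change on year. Under pure NFDS with
# -1 < D < 0 the fluctuation amplitude should decay; a flat or rising
# amplitude implies sustained external forcing.

dampening_model <- "
model {
  for (i in 1:N) {
    adp[i] ~ dnorm(a[loc[i]] + b[loc[i]] * yr[i], tau)
  }
  for (j in 1:J) {
    a[j] ~ dnorm(0, 1)
    b[j] ~ dnorm(mu_b, tau_b)
  }
  mu_b ~ dnorm(0, 1)
  sd_b ~ dnorm(0, 1) T(0,)
  tau_b <- pow(sd_b, -2)
  sigma ~ dnorm(0, 1) T(0,)
  tau <- pow(sigma, -2)
}
"

#' Test for dampening of frequency fluctuations over time
#'
#' Fits the hierarchical linear model
#' `|delta-p| ~ a_j + b_j * (year - from_year)` with partial pooling of
#' the per-locality slopes, and reports the posterior probability that
#' each slope — and the across-locality mean slope — is negative
#' (dampening). Years are centred at `from_year` for numerical
#' stability; centring affects intercepts only.
#'
#' @param trajectories Either an `nfds_d_fit` (its posterior-median
#'   latent frequencies are used, the plug-in default) or a tibble with
#'   columns `locality`, `year`, `p` (consecutive years).
#' @param from_year Only years `>= from_year` enter the test.
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed.
#' @return An object of class `dampening_fit` with `locality` (tibble:
#'   slope median/ETPI and `pp_negative` per locality) and `mean`
#'   (tibble: hyper-mean slope and `pp_negative`).
#' @export
test_dampening <- function(trajectories, from_year = 2000,
                           mcmc = mcmc_settings(), seed = 1) {
  if (inherits(trajectories, "nfds_d_fit")) {
    traj <- trajectories$trajectories[, c("locality", "year", "p")]
  } else {
    traj <- tibble::as_tibble(trajectories)[, c("locality", "year", "p")]
  }
  traj <- traj |>
    dplyr::filter(.data$year >= from_year) |>
    dplyr::arrange(.data$locality, .data$year)
  dps <- traj |>
    dplyr::group_by(.data$locality) |>
    dplyr::reframe(
      year = .data$year[-dplyr::n()][diff(.data$year) == 1L],
      adp = abs(diff(.data$p))[diff(.data$year) == 1L]
    )
  keep <- dps |>
    dplyr::count(.data$locality) |>
    dplyr::filter(.data$n >= 2)
  dps <- dplyr::semi_join(dps, keep, by = "locality")
  if (nrow(dps) == 0) {
    stop("no locality retains >= 2 |delta-p| values after the year filter",
         call. = FALSE)
  }
  loc_levels <- sort(unique(dps$locality))
  data <- list(
    adp = dps$adp, yr = dps$year - from_year,
    loc = match(dps$locality, loc_levels),
    N = nrow(dps), J = length(loc_levels)
  )
  fit <- run_jags(dampening_model, data,
                  monitor = c("a", "b", "mu_b", "sd_b", "sigma"),
                  mcmc = mcmc, seed = seed)
  b <- fit$draws$b
  loc_tbl <- purrr::map_dfr(seq_along(loc_levels), function(j) {
    q <- post_summary(b[, j])
    tibble::tibble(
      locality = loc_levels[j],
      slope = q["median"], slope_lo = q["lo"], slope_hi = q["hi"],
      pp_negative = mean(b[, j] < 0)
    )
  })
  mu_b <- as.numeric(fit$draws$mu_b)
  structure(
    list(
      locality = loc_tbl,
      mean = tibble::tibble(
        slope = stats::median(mu_b),
        slope_lo = stats::quantile(mu_b, 0.025),
        slope_hi = stats::quantile(mu_b, 0.975),
        pp_negative = mean(mu_b < 0)
      ),
      data = dps, from_year = from_year, seed = seed
    ),
    class = "dampening_fit"
  )
}

#' @export
print.dampening_fit <- function(x, ...) {
  cat("<dampening_fit> pp(mean slope < 0) =",
      round(x$mean$pp_negative, 3), "\n")
  print(x$locality)
  invisible(x)
}
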
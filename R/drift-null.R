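# NFDS + genetic drift null model: forward simulation of the fitted
# deterministic NFDS pull with binomial resampling of 2*Ne gene copies,
# comparison of observed fluctuation magnitude against the null,
# Fisher's combined probability test, and the Ne sensitivity analysis.

#' Simulate the NFDS + drift null distribution of fluctuation magnitude
#'
#' Each replicate starts from `p0` and iterates: deterministic NFDS
#' `delta-p = D * (p - p_eq)` (expected frequency clamped to \[0, 1\]),
#' then drift `p' ~ Binomial(2 * Ne, p + delta-p) / (2 * Ne)`, for
#' `n_generations - 1` transitions. Each replicate is summarised as its
#' mean absolute per-generation change. Fixation is permitted: a
#' trajectory absorbed at 0 or 1 re-enters (0, 1) whenever the NFDS pull
#' at the boundary is interior.
#'
#' @param D NFDS parameter.
#' @param p_eq Equilibrium frequency.
#' @param p0 Initial frequency in \[0, 1\].
#' @param n_generations Length of the (observed) series being emulated;
#'   the replicate contributes `n_generations - 1` changes.
#' @param Ne Effective population size (>= 1).
#' @param reps Number of replicates.
#' @param seed Integer seed (optional).
#' @return Numeric vector of length `reps`: mean |delta-p| per replicate.
#' @export
simulate_drift_null <- function(D, p_eq, p0, n_generations, Ne = 110,
                                reps = 100, seed = NULL) {
  stopifnot(p0 >= 0, p0 <= 1, Ne >= 1, n_generations >= 2, reps >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  p <- rep(p0, reps)
  acc <- numeric(reps)
  for (t in seq_len(n_generations - 1)) {
    pe <- pmin(pmax(p + D * (p - p_eq), 0), 1)
    p_new <- stats::rbinom(reps, 2 * Ne, pe) / (2 * Ne)
    acc <- acc + abs(p_new - p)
    p <- p_new
  }
  acc / (n_generations - 1)
}

#' Compare an observed fluctuation magnitude against the drift null
#'
#' One-sided Monte-Carlo p-value with the add-one correction,
#' `p = (#\{null >= observed\} + 1) / (reps + 1)`, and the fold excess
#' `observed / mean(null)`.
#'
#' @param null Numeric vector of null mean |delta-p| values.
#' @param observed Observed mean |delta-p|.
#' @return Tibble with `observed`, `null_mean`, `p_value`, `fold_excess`,
#'   `reps`.
#' @export
compare_observed <- function(null, observed) {
  stopifnot(length(null) >= 1)
  if (mean(null) == 0) {
    stop("null distribution has zero mean; fold excess undefined",
         call. = FALSE)
  }
  tibble::tibble(
    observed = observed,
    null_mean = mean(null),
    p_value = (sum(null >= observed) + 1) / (length(null) + 1),
    fold_excess = observed / mean(null),
    reps = length(null)
  )
}

#' Fisher's combined probability test
#'
#' Combines k independent one-sided p-values as
#' `chi-square = -2 * sum(log(p))` on `2k` degrees of freedom.
#'
#' @param p_values Vector of p-values in (0, 1\].
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
fisher_combined <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) {
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  }
  stat <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  tibble::tibble(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Per-locality drift-null comparison for a fitted NFDS model
#'
#' For each fitted locality, simulates the NFDS + drift null using the
#' locality's posterior-median `D` and equilibrium, starting from the
#' first latent-frequency median and running for the locality's observed
#' series length, then compares the observed mean |delta-p| (from the
#' posterior-median latent frequencies) against the null and combines
#' the per-locality p-values with Fisher's method.
#'
#' @param fit An `nfds_d_fit`.
#' @param Ne Effective population size.
#' @param reps Null replicates per locality.
#' @param seed Integer seed.
#' @return Object of class `drift_null` with `locality` (tibble:
#'   observed, null mean, p-value, fold excess), `fisher` (combined
#'   test) and `null` (long tibble of null replicates for plotting).
#' @export
drift_null_analysis <- function(fit, Ne = 110, reps = 100, seed = 1) {
  stopifnot(inherits(fit, "nfds_d_fit"))
  withr::local_seed(seed)
  obs <- observed_fluctuation(fit)
  rows <- vector("list", nrow(obs))
  nulls <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    est <- fit$estimates[fit$estimates$locality == obs$locality[i], ]
    null <- simulate_drift_null(
      D = est$D, p_eq = est$p_eq_hat, p0 = obs$p0[i],
      n_generations = obs$n_generations[i], Ne = Ne, reps = reps
    )
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(locality = obs$locality[i]),
      compare_observed(null, obs$observed[i])
    )
    nulls[[i]] <- tibble::tibble(locality = obs$locality[i],
                                 mean_abs_dp = null)
  }
  loc_tbl <- dplyr::bind_rows(rows)
  structure(
    list(
      locality = loc_tbl,
      fisher = fisher_combined(loc_tbl$p_value),
      null = dplyr::bind_rows(nulls),
      Ne = Ne, reps = reps, seed = seed
    ),
    class = "drift_null"
  )
}

#' @export
print.drift_null <- function(x, ...) {
  cat("<drift_null> Ne =", x$Ne, ";", x$reps, "reps/locality; Fisher chi2 =",
      round(x$fisher$statistic, 2), "df =", x$fisher$df, "\n")
  print(x$locality)
  invisible(x)
}

# Observed mean |delta-p| per locality from posterior-median latent
# frequencies, with the first-year frequency and series length.
observed_fluctuation <- function(fit) {
  fit$deltas |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(observed = mean(abs(.data$delta_p)),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      fit$trajectories |>
        dplyr::group_by(.data$locality) |>
        dplyr::summarise(p0 = .data$p[which.min(.data$year)],
                         n_generations = dplyr::n(), .groups = "drop"),
      by = "locality"
    )
}

#' Effective-population-size sensitivity analysis
#'
#' Repeats the drift-null comparison over a grid of `Ne` values and
#' reports, per locality and `Ne`, the one-sided Monte-Carlo p-value,
#' together with the largest `Ne` in the grid at which at least
#' `fraction` of the localities are non-significant at `alpha` (i.e.
#' drift of that strength suffices to explain the observed fluctuation).
#'
#' @param estimates Tibble with columns `locality`, `D`, `p_eq`, `p0`,
#'   `n_generations`, `observed` — or an `nfds_d_fit`, from which these
#'   are derived.
#' @param ne_grid Grid of `Ne` values (default 100 down to 20 by 10).
#' @param reps Null replicates per locality and `Ne`.
#' @param alpha Significance level.
#' @param fraction Fraction of localities that must be non-significant
#'   (default 1 = all).
#' @param seed Integer seed.
#' @return List with `grid` (tibble: `locality`, `Ne`, `p_value`,
#'   `fold_excess`) and `threshold_ne` (largest qualifying `Ne`, or `NA`
#'   if none in the grid qualifies).
#' @export
ne_sensitivity <- function(estimates, ne_grid = seq(100, 20, by = -10),
                           reps = 100, alpha = 0.05, fraction = 1,
                           seed = 1) {
  stopifnot(length(ne_grid) >= 1)
  if (inherits(estimates, "nfds_d_fit")) {
    fit <- estimates
    estimates <- observed_fluctuation(fit) |>
      dplyr::left_join(
        fit$estimates[, c("locality", "D", "p_eq_hat")], by = "locality"
      ) |>
      dplyr::rename(p_eq = "p_eq_hat")
  }
  withr::local_seed(seed)
  grid <- purrr::map_dfr(ne_grid, function(ne) {
    purrr::map_dfr(seq_len(nrow(estimates)), function(i) {
      e <- estimates[i, ]
      null <- simulate_drift_null(e$D, e$p_eq, e$p0, e$n_generations,
                                  Ne = ne, reps = reps)
      cmp <- compare_observed(null, e$observed)
      tibble::tibble(locality = e$locality, Ne = ne,
                     p_value = cmp$p_value, fold_excess = cmp$fold_excess)
    })
  })
  by_ne <- grid |>
    dplyr::group_by(.data$Ne) |>
    dplyr::summarise(frac_ns = mean(.data$p_value > alpha), .groups = "drop")
  ok <- by_ne$Ne[by_ne$frac_ns >= fraction]
  list(grid = grid,
       threshold_ne = if (length(ok) > 0) max(ok) else NA_real_)
}
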
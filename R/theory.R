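# Closed-form single-generation allele/morph frequency change under the
# classical deterministic processes, and the D-based classification of
# NFDS dynamics.

#' Per-generation frequency change under NFDS
#'
#' The linearised model of negative frequency-dependent selection near an
#' internal equilibrium: `delta_p = D * (p - p_eq)`. `D` is the slope of the
#' regression of the per-generation change on the current frequency
#' (Lewontin's NFDS parameter); `D < 0` pulls the frequency back toward
#' `p_eq`.
#'
#' @param p Current frequency, in \[0, 1\]. Vectorised.
#' @param D NFDS parameter (slope of delta-p on p).
#' @param p_eq Equilibrium frequency, where the change is zero.
#' @return Numeric vector of per-generation changes.
#' @examples
#' delta_p_nfds(0.8, D = -0.5, p_eq = 0.7)
#' @export
delta_p_nfds <- function(p, D, p_eq) {
  stopifnot(all(p >= 0 & p <= 1))
  D * (p - p_eq)
}

#' Per-generation change under overdominance or underdominance
#'
#' One-locus two-allele viability selection with heterozygote fitness 1 and
#' homozygote fitnesses `1 - s1` and `1 - s2`:
#' `delta_p = p * (1 - p) * (s2 - p * (s1 + s2))`. Positive `s1`, `s2` give
#' overdominance (a protected internal equilibrium at `s2 / (s1 + s2)`);
#' negative values give underdominance (an unstable internal point).
#' `delta_p_underdominance()` is the same closed form, provided so call
#' sites can state intent.
#'
#' @param p Current frequency, in \[0, 1\]. Vectorised.
#' @param s1,s2 Homozygote selection coefficients (deviations from the
#'   heterozygote).
#' @return Numeric vector of per-generation changes.
#' @examples
#' delta_p_overdominance(0.25, s1 = 0.3, s2 = 0.3)
#' @export
delta_p_overdominance <- function(p, s1, s2) {
  stopifnot(all(p >= 0 & p <= 1))
  p * (1 - p) * (s2 - p * (s1 + s2))
}

#' @rdname delta_p_overdominance
#' @export
delta_p_underdominance <- function(p, s1, s2) {
  delta_p_overdominance(p, s1, s2)
}

#' Per-generation change under directional selection
#'
#' `delta_p = s * p * (1 - p) * (p + h * (1 - 2 * p))` with selection
#' coefficient `s` and heterozygote effect `h` (`h = 0.5` is additivity).
#'
#' @param p Current frequency, in \[0, 1\]. Vectorised.
#' @param s Selection coefficient (sign gives the direction).
#' @param h Heterozygote effect in \[0, 1\].
#' @return Numeric vector of per-generation changes.
#' @export
delta_p_directional <- function(p, s, h = 0.5) {
  stopifnot(all(p >= 0 & p <= 1), h >= 0, h <= 1)
  s * p * (1 - p) * (p + h * (1 - 2 * p))
}

#' Per-generation change under mainland-island migration
#'
#' `delta_p = (p * (1 - m) + p_m * m) - p`, which simplifies to
#' `m * (p_m - p)`: the island frequency moves a fraction `m` of the way to
#' the mainland frequency each generation.
#'
#' @param p Island (focal population) frequency, in \[0, 1\]. Vectorised.
#' @param m Migration rate in \[0, 1\].
#' @param p_m Mainland (source) frequency in \[0, 1\].
#' @return Numeric vector of per-generation changes.
#' @export
delta_p_migration <- function(p, m, p_m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 0, m <= 1, p_m >= 0, p_m <= 1)
  (p * (1 - m) + p_m * m) - p
}

#' Classify expected NFDS dynamics from D
#'
#' Under the linear NFDS model and no other process, the value of `D`
#' determines the qualitative dynamics: gradual convergence to the
#' equilibrium for `-1 < D < 0`, dampened oscillations for `-2 < D < -1`,
#' a stable two-point oscillation at exactly `D = -2`, diverging
#' oscillations for `D < -2`, and positive frequency dependence
#' (runaway from the internal point) for `D > 0`.
#'
#' The published rules are stated on open intervals; the boundary values
#' `D = 0` and `D = -1` are assigned deterministically to the adjacent
#' class nearer zero (`converging`), with a message, and `D = -2` is
#' detected within a tolerance of `tol`.
#'
#' @param D Numeric vector of NFDS parameters; must be finite.
#' @param tol Absolute tolerance used to detect the `D = -2` boundary.
#' @param quiet Suppress the boundary-value message.
#' @return Character vector with values in `positive_FDS`, `converging`,
#'   `dampened_oscillation`, `stable_oscillation`, `diverging_oscillation`.
#' @examples
#' classify_dynamics(c(-0.48, -1.5, -2, -2.5, 0.3))
#' @export
classify_dynamics <- function(D, tol = 1e-9, quiet = FALSE) {
  if (any(!is.finite(D))) {
    stop("`D` must be finite", call. = FALSE)
  }
  out <- character(length(D))
  stable <- abs(D + 2) <= tol
  boundary <- abs(D) <= tol | abs(D + 1) <= tol
  out[D > tol] <- "positive_FDS"
  out[D <= tol & D >= -1 - tol & !stable] <- "converging"
  out[D < -1 - tol & D > -2 & !stable] <- "dampened_oscillation"
  out[stable] <- "stable_oscillation"
  out[D < -2 & !stable] <- "diverging_oscillation"
  if (any(boundary) && !quiet) {
    message(
      "boundary D value(s) ",
      paste(unique(signif(D[boundary], 3)), collapse = ", "),
      " assigned to the adjacent class toward zero ('converging')"
    )
  }
  out
}

#' Iterate the deterministic NFDS map
#'
#' Applies `p <- p + D * (p - p_eq)` repeatedly, clamping to \[0, 1\] after
#' each step (clamping only matters for large `|D|`; the analytic theory
#' is drift-free).
#'
#' @param p0 Starting frequency in \[0, 1\].
#' @param D NFDS parameter.
#' @param p_eq Equilibrium frequency.
#' @param n_steps Number of generations to iterate.
#' @return A tibble with columns `step` (0-based) and `p`.
#' @export
iterate_nfds <- function(p0, D, p_eq, n_steps = 50) {
  stopifnot(p0 >= 0, p0 <= 1, n_steps >= 1)
  p <- numeric(n_steps + 1)
  p[1] <- p0
  for (i in seq_len(n_steps)) {
    p[i + 1] <- min(max(p[i] + D * (p[i] - p_eq), 0), 1)
  }
  tibble::tibble(step = 0:n_steps, p = p)
}

#' Theoretical delta-p curves for each evolutionary process
#'
#' Evaluates the per-generation change over a frequency grid for NFDS,
#' overdominance, positive and negative directional selection,
#' underdominance and mainland-island migration, each over a small set of
#' representative parameter values, as a long tibble suitable for
#' faceting.
#'
#' @param p Frequency grid.
#' @param D_values NFDS parameters to show.
#' @param s1_values Homozygote coefficients for the dominance panels
#'   (paired with `s2 = 0.3` for overdominance, `s2 = -0.3` for
#'   underdominance).
#' @param s_values Directional selection coefficients (`h = 0.5`).
#' @param m_values Migration rates (`p_m = 0.5`).
#' @return Tibble with columns `process`, `params`, `p`, `delta_p`.
#' @export
theory_curves <- function(p = seq(0, 1, by = 0.01),
                          D_values = c(-0.5, -1, -1.5, -2, -2.5),
                          s1_values = c(0.1, 0.3, 0.5),
                          s_values = c(0.05, 0.1, 0.2),
                          m_values = c(0.05, 0.1, 0.2)) {
  panel <- function(process, params, delta_p) {
    tibble::tibble(process = process, params = params, p = p, delta_p = delta_p)
  }
  dplyr::bind_rows(
    purrr::map(D_values, function(D) {
      panel("nfds", sprintf("D=%g", D), delta_p_nfds(p, D, p_eq = 0.5))
    }),
    purrr::map(s1_values, function(s1) {
      panel("overdominance", sprintf("s1=%g, s2=0.3", s1),
            delta_p_overdominance(p, s1, 0.3))
    }),
    purrr::map(s_values, function(s) {
      panel("directional_positive", sprintf("s=%g, h=0.5", s),
            delta_p_directional(p, s, 0.5))
    }),
    purrr::map(s_values, function(s) {
      panel("directional_negative", sprintf("s=%g, h=0.5", -s),
            delta_p_directional(p, -s, 0.5))
    }),
    purrr::map(s1_values, function(s1) {
      panel("underdominance", sprintf("s1=%g, s2=-0.3", -s1),
            delta_p_underdominance(p, -s1, -0.3))
    }),
    purrr::map(m_values, function(m) {
      panel("migration", sprintf("m=%g, p_m=0.5", m),
            delta_p_migration(p, m, 0.5))
    })
  )
}
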
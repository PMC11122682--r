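# broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hierarchical NFDS fit
#'
#' One row per locality: posterior median and 95% ETPI of `D`, the
#' intercept, the derived equilibrium, and the dynamics class.
#'
#' @param x An `nfds_d_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nfds_d_fit
#' @export
tidy.nfds_d_fit <- function(x, ...) {
  x$estimates
}

#' Hyper-level summary of a hierarchical NFDS fit
#'
#' @param x An `nfds_d_fit`.
#' @param ... Unused.
#' @return One-row tibble: across-locality mean and SD of `D`
#'   (posterior medians with ETPIs), number of localities, max R-hat.
#' @method glance nfds_d_fit
#' @export
glance.nfds_d_fit <- function(x, ...) {
  h <- x$hyper
  tibble::tibble(
    mean_D = h$estimate[h$term == "mu_D"],
    mean_D_lo = h$lo[h$term == "mu_D"],
    mean_D_hi = h$hi[h$term == "mu_D"],
    sd_D = h$estimate[h$term == "sd_D"],
    n_localities = length(x$localities),
    max_rhat_D = max(x$rhat, na.rm = TRUE)
  )
}

#' @method tidy dampening_fit
#' @export
tidy.dampening_fit <- function(x, ...) {
  x$locality
}

#' @method glance dampening_fit
#' @export
glance.dampening_fit <- function(x, ...) {
  dplyr::bind_cols(x$mean,
                   tibble::tibble(n_localities = nrow(x$locality)))
}

#' @method tidy fitness_fit
#' @export
tidy.fitness_fit <- function(x, ...) {
  x$params
}

#' @method glance fitness_fit
#' @export
glance.fitness_fit <- function(x, ...) {
  tibble::tibble(
    form = x$form,
    waic = unname(x$waic["waic"]),
    p_waic = unname(x$waic["p_waic"]),
    equilibrium = x$equilibrium$equilibrium,
    no_crossing = x$equilibrium$no_crossing
  )
}

#' @method tidy experiment_d_fit
#' @export
tidy.experiment_d_fit <- function(x, ...) {
  x$estimates
}

#' @method tidy morph_advantage_fit
#' @export
tidy.morph_advantage_fit <- function(x, ...) {
  x$blocks
}

#' @method glance morph_advantage_fit
#' @export
glance.morph_advantage_fit <- function(x, ...) {
  dplyr::bind_cols(x$estimates,
                   tibble::tibble(n_blocks = nrow(x$blocks)))
}

#' @method tidy drift_null
#' @export
tidy.drift_null <- function(x, ...) {
  x$locality
}

#' @method glance drift_null
#' @export
glance.drift_null <- function(x, ...) {
  dplyr::bind_cols(x$fisher, tibble::tibble(Ne = x$Ne, reps = x$reps))
}

#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  x$assignments
}
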
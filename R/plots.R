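# ggplot2 displays for the main result types.

#' Plot morph-frequency time series
#'
#' Yearly host-pooled stripe frequency per locality.
#'
#' @param series Morph-count tibble.
#' @return A ggplot.
#' @export
plot_morph_series <- function(series) {
  pooled <- pool_hosts(series)
  ggplot2::ggplot(pooled,
                  ggplot2::aes(x = .data$year, y = .data$p_raw,
                               colour = .data$locality)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = "Stripe frequency", colour = "Locality") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot theoretical delta-p curves
#'
#' @param curves Output of [theory_curves()].
#' @return A ggplot faceted by process.
#' @export
plot_theory_curves <- function(curves = theory_curves()) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$p, y = .data$delta_p,
                               colour = .data$params)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~process, scales = "free_y") +
    ggplot2::labs(x = "Frequency p", y = expression(Delta * p)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-morphdyn
#' @method autoplot nfds_d_fit
#' @export
autoplot.nfds_d_fit <- function(object, ...) {
  dat <- object$deltas
  est <- object$estimates
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p, y = .data$delta_p)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      data = est,
      ggplot2::aes(slope = .data$D, intercept = .data$alpha),
      colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~locality) +
    ggplot2::labs(x = "Stripe frequency p", y = expression(Delta * p)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-morphdyn
#' @method autoplot fitness_fit
#' @export
autoplot.fitness_fit <- function(object, ...) {
  tab <- object$data
  med <- stats::setNames(object$params$estimate, object$params$term)
  grid <- tibble::tibble(p = seq(0, 1, by = 0.01))
  grid$w <- relative_fitness(med, grid$p, object$form)
  obs <- tab |>
    dplyr::mutate(
      qs_hat = ifelse(.data$released_striped > 0,
                      .data$recaptured_striped / .data$released_striped, NA),
      qg_hat = ifelse(.data$released_other > 0,
                      .data$recaptured_other / .data$released_other, NA),
      w_hat = .data$qs_hat / .data$qg_hat
    )
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$release_freq, y = .data$w_hat)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$p, y = .data$w),
                       colour = "firebrick") +
    ggplot2::labs(x = "Release stripe frequency",
                  y = "Relative fitness (striped / green)") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for morphdyn result objects
#'
#' @param object A fitted morphdyn object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-morphdyn
#' @rdname autoplot-morphdyn
#' @method autoplot drift_null
#' @export
autoplot.drift_null <- function(object, ...) {
  ggplot2::ggplot(object$null,
                  ggplot2::aes(x = .data$locality, y = .data$mean_abs_dp)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::geom_point(data = object$locality,
                        ggplot2::aes(y = .data$observed),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "Locality",
                  y = "Mean |delta-p| per generation",
                  subtitle = paste0("Red: observed; boxes: NFDS + drift null (Ne = ",
                                    object$Ne, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-morphdyn
#' @method autoplot cluster_assignment
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "Cluster") +
    ggplot2::theme_minimal()
}
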
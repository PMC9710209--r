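#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for oligoflux results
#'
#' `autoplot()` methods give quick diagnostic figures: the fitted sigmoid
#' over the data for a logistic fit, the oligomer-flux bell with its peak
#' marked for a flux profile, and the fitted saturation curve on a
#' log-concentration axis for a binding fit. `plot_flux_metrics()` draws the
#' control-normalized flux metrics per condition as bars.
#'
#' @param object a fitted object.
#' @param ... unused.
#' @return A ggplot object.
#' @name oligoflux-plots
NULL

#' @rdname oligoflux-plots
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  check_logistic_fit(object)
  d <- object$data
  tt <- seq(min(d$time_min), max(d$time_min), length.out = 400)
  curve <- tibble::tibble(time_min = tt,
                          signal = gl_mass(tt, object$a, object$kappa, object$c))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(data = curve, color = "#c2185b", linewidth = 0.8,
                       linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = "normalized ThT signal",
                  title = sprintf("generalized logistic fit: t_half = %.0f min",
                                  object$t_half)) +
    ggplot2::theme_minimal()
}

#' @rdname oligoflux-plots
#' @method autoplot flux_profile
#' @export
autoplot.flux_profile <- function(object, ...) {
  s <- flux_summary(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$phi)) +
    ggplot2::geom_area(fill = "#90caf9", alpha = 0.5) +
    ggplot2::geom_line(color = "#1565c0") +
    ggplot2::geom_vline(xintercept = s$phi_time, linetype = "dotted") +
    ggplot2::labs(x = "time (min)", y = "oligomer flux (1/min)",
                  title = sprintf("phi_peak = %.3g, phi_area = %.3g, phi_time = %.0f min",
                                  s$phi_peak, s$phi_area, s$phi_time)) +
    ggplot2::theme_minimal()
}

#' @rdname oligoflux-plots
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  d <- object$data
  xx <- exp(seq(log(min(d$concentration_uM)), log(max(d$concentration_uM)),
                length.out = 200))
  curve <- tibble::tibble(
    concentration_uM = xx,
    response = object$bmax * xx / (object$kd + xx) + object$offset)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_uM, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, color = "#c2185b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "response",
                  title = if (object$converged)
                    sprintf("K_d = %.3g uM (R^2 = %.2f)", object$kd, object$r_squared)
                  else "fit does not converge") +
    ggplot2::theme_minimal()
}

#' @rdname oligoflux-plots
#' @param metrics a [flux_metrics_table()] result.
#' @export
plot_flux_metrics <- function(metrics, ...) {
  needed <- c("phi_peak_rel", "phi_area_rel", "phi_time_rel")
  if (!all(needed %in% names(metrics)))
    stop_input("`metrics` must carry the `_rel` columns (see flux_metrics_table()).")
  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(needed),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$condition, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "#78909c") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative to control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
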
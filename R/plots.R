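#' Plot an impact trace
#'
#' Force and (averaged) displacement against time, one panel each.
#'
#' @param object An `impact_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot impact_trace
#' @export
autoplot.impact_trace <- function(object, ...) {
  d <- tibble::tibble(
    time_s = object$time_s,
    `displacement (mm)` = average_displacement(object) * 1000,
    `force (N)` = object$force_n
  )
  long <- tidyr::pivot_longer(d, -"time_s", names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmented displacement-force curve
#'
#' Loading, unloading and discarded samples in the style of the
#' segmentation figure: compression on the x axis, force on the y axis.
#'
#' @param object A `segmented_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot segmented_curve
#' @export
autoplot.segmented_curve <- function(object, ...) {
  d <- tidy.segmented_curve(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$disp_m * 1000, .data$force_n,
                                  colour = .data$phase)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(
      data = tibble::tibble(disp_m = object$peak$peak_displacement,
                            force_n = object$peak$peak_force,
                            phase = "peak"),
      size = 2
    ) +
    ggplot2::scale_colour_manual(
      values = c(loading = "#c0392b", unloading = "#27ae60",
                 discarded = "grey40", peak = "black")
    ) +
    ggplot2::labs(x = "compression (mm)", y = "force (N)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a transfer function
#'
#' Measured versus undamped peak forces with the fitted through-origin
#' line.
#'
#' @param object A `transfer_fn`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transfer_fn
#' @export
autoplot.transfer_fn <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$measured_n / 1000,
                                  .data$undamped_n / 1000)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "#2980b9") +
    ggplot2::labs(
      x = "measured peak force (kN)", y = "undamped force (kN)",
      title = sprintf("%s layer(s): k = %.1f, R² = %.3f",
                      object$n_layers, object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the repeated-loading degradation
#'
#' Mean force at the reference energy (error bars: one SD) against the
#' repetition number, one facet per layer count.
#'
#' @param table1 List of `repeated_loading_result` from [build_table1()].
#' @return A ggplot.
#' @export
plot_repeated_loading <- function(table1) {
  d <- purrr::map_dfr(table1, tidy.repeated_loading_result)
  ggplot2::ggplot(d, ggplot2::aes(.data$repetition, .data$mean_n)) +
    ggplot2::geom_col(fill = "#95a5a6") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_n - .data$sd_n,
                   ymax = .data$mean_n + .data$sd_n),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~n_layers, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "repetition", y = "force at E_ref (N)") +
    ggplot2::theme_minimal()
}
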
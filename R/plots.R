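#' Plot a steady-state nuclear gradient and its entry routes
#'
#' Total nuclear Dorsal (solid), the direct-flow component (dotted) and
#' the Toll-induced component (dashed) along the ventral-to-dorsal half
#' axis.
#'
#' @param object A `dl_steady_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dl_steady_state <- function(object, ...) {
  d <- decompose_nuclear(object)
  long <- tidyr::pivot_longer(d, -"position", names_to = "component",
                              values_to = "nDl")
  long$component <- factor(long$component,
                           levels = c("nDl_total", "nDl0", "nDlstar"))
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$nDl,
                                     linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(nDl_total = "solid", nDl0 = "dotted", nDlstar = "dashed")) +
    ggplot2::labs(x = "position (ventral -> dorsal)",
                  y = "nuclear Dorsal (dimensionless)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration run's cost history
#'
#' @param object A `dl_ga_fit`.
#' @param ... Unused.
#' @return A ggplot object with per-generation best and mean cost on a
#'   log axis.
#' @export
autoplot.dl_ga_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"generation",
                           names_to = "series", values_to = "cost")
  ggplot2::ggplot(h, ggplot2::aes(.data$generation, .data$cost,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "quadratic loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the profiles of a parameter sweep
#'
#' @param sweep Tibble returned by [parameter_sweep()].
#' @param y Column to plot (default `nDl_total`).
#' @return A ggplot object, one curve per sweep factor.
#' @export
plot_sweep <- function(sweep, y = "nDl_total") {
  stopifnot(is.data.frame(sweep), "factor" %in% names(sweep),
            y %in% names(sweep))
  ggplot2::ggplot(sweep,
                  ggplot2::aes(.data$position, .data[[y]],
                               colour = factor(.data$factor),
                               group = factor(.data$factor))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (ventral -> dorsal)", y = y,
                  colour = "factor") +
    ggplot2::theme_minimal()
}
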
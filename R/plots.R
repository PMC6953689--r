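# Quick-look figures.

#' Plot a waveform trace
#'
#' Current (and voltage, when present) against time.
#'
#' @param trace A `waveform_trace` tibble.
#' @return A ggplot object.
#' @export
plot_waveform <- function(trace) {
  validate_trace(trace)
  long <- tidyr::pivot_longer(tibble::as_tibble(trace), -"time_us",
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_us, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(current_ka = "current (kA)", voltage_kv = "voltage (kV)"))) +
    ggplot2::labs(x = "time (µs)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot waveform_trace
#' @export
autoplot.waveform_trace <- function(object, ...) plot_waveform(object)

#' Observed-versus-fitted plot for a power-law fit
#'
#' Both axes on log scales; a perfect power law falls on the identity line.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- tibble::tibble(observed = exp(object$lm_fit$model$.logy),
                      fitted = exp(stats::fitted(object$lm_fit)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste("fitted", object$response),
                  y = paste("observed", object$response)) +
    ggplot2::theme_minimal()
}
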
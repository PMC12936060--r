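#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an overall cumulative exposure-response curve
#'
#' Relative risk versus temperature with a Wald confidence ribbon and the
#' reference temperature marked.
#'
#' @param object An `er_curve` from [overall_cumulative()].
#' @param level Confidence level for the ribbon.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot er_curve
#' @export
autoplot.er_curve <- function(object, level = 0.95, ...) {
  d <- curve_confidence(object, level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rr_low,
                                      ymax = .data$rr_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "reference"),
                        linetype = "dotted") +
    ggplot2::labs(x = "Temperature (°C)", y = "Relative risk",
                  title = "Overall cumulative exposure-response")
}

#' Plot a lag-response curve
#'
#' @param object A `lag_curve` from [lag_response()].
#' @param level Confidence level for the ribbon.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lag_curve
#' @export
autoplot.lag_curve <- function(object, level = 0.95, ...) {
  d <- curve_confidence(object, level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rr_low,
                                      ymax = .data$rr_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "Lag (days)", y = "Relative risk",
      title = paste0("Lag-response at ",
                     format(attr(object, "at_temperature"), digits = 3),
                     " °C")
    )
}

#' Plot attributable fractions by component
#'
#' Bars of the attributable fraction per temperature component, with
#' empirical confidence bars when present.
#'
#' @param object An `attrib_result` from [component_af()] or
#'   [attrib_eci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attrib_result
#' @export
autoplot.attrib_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$component <- factor(d$component,
                        levels = c("extreme_cold", "moderate_cold",
                                   "moderate_heat", "extreme_heat"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$af)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Attributable fraction (%)",
                  title = "Temperature-attributable mortality")
  if (all(c("af_low", "af_high") %in% names(d))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$af_low, ymax = .data$af_high), width = 0.2
    )
  }
  p
}
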
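# ggplot2 methods mirroring the study's diagnostic figures.

#' Plot volume-dependence curves
#'
#' Log-log plot of feature value versus VOI volume, one panel per parameter
#' (the volume-dependence figure of the homogeneous-phantom experiment).
#'
#' @param object A `volume_curves` tibble.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot volume_curves
#' @export
autoplot.volume_curves <- function(object, parameters = NULL, ...) {
  df <- object
  if (!is.null(parameters)) df <- dplyr::filter(df, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(.data$volume_ml, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "VOI volume [ml]", y = "parameter value")
}

#' @rdname autoplot.volume_curves
#' @export
plot_volume_curves <- function(object, parameters = NULL, ...) {
  autoplot.volume_curves(object, parameters = parameters, ...)
}

#' Plot the reproducibility CV grid
#'
#' Replicate coefficient of variation per reconstruction setting and
#' acquisition time, one panel per parameter.
#'
#' @param object A `repro_report` tibble.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repro_report
#' @export
autoplot.repro_report <- function(object, parameters = NULL, ...) {
  df <- object
  if (!is.null(parameters)) df <- dplyr::filter(df, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$acq_time_s), 100 * .data$cv,
    fill = .data$setting
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 10, linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "acquisition time [s]", y = "replicate CV [%]")
}

#' @rdname autoplot.repro_report
#' @export
plot_reproducibility <- function(object, parameters = NULL, ...) {
  autoplot.repro_report(object, parameters = parameters, ...)
}

#' Plot sensitivity time profiles
#'
#' Feature value versus frame time over the dual-isotope dynamic series.
#'
#' @param object A `sensitivity_profiles` tibble.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_profiles
#' @export
autoplot.sensitivity_profiles <- function(object, parameters = NULL, ...) {
  df <- object
  if (!is.null(parameters)) df <- dplyr::filter(df, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "frame time [min]", y = "parameter value")
}

#' @rdname autoplot.sensitivity_profiles
#' @export
plot_sensitivity_profiles <- function(object, parameters = NULL, ...) {
  autoplot.sensitivity_profiles(object, parameters = parameters, ...)
}
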
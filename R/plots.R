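#' Plot a PSD matrix as a spectrogram
#'
#' @param object A `psd_matrix`.
#' @param ... Unused.
#' @return A ggplot: time on x, frequency on y, level as fill.
#' @method autoplot psd_matrix
#' @export
autoplot.psd_matrix <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$frame_time, .data$frequency,
                                 fill = .data$psd_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PSD\n(dB re 1 µPa²/Hz)") +
    ggplot2::labs(x = NULL, y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an occurrence grid
#'
#' Day x hour presence tiles shaded by light/dark, the standard seasonal /
#' diel occurrence display.
#'
#' @param object An `occurrence_grid`.
#' @param ... Unused.
#' @method autoplot occurrence_grid
#' @export
autoplot.occurrence_grid <- function(object, ...) {
  object |>
    ggplot2::ggplot(ggplot2::aes(.data$date, .data$hour)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$light == "dark"),
                       fill = "grey70", height = 1) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$presence),
                        size = 0.6, colour = "black") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.5, `FALSE` = 0),
                                guide = "none") +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Hour (UTC)") +
    ggplot2::theme_minimal()
}

#' Plot a detection-probability curve
#'
#' @param object A `detection_range_result`.
#' @param ... Unused.
#' @method autoplot detection_range_result
#' @export
autoplot.detection_range_result <- function(object, ...) {
  object$prob_curve |>
    ggplot2::ggplot(ggplot2::aes(.data$range_m / 1000, .data$probability,
                                 colour = factor(.data$radial))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = object$percentile_ranges,
      ggplot2::aes(xintercept = .data$range_m / 1000), linetype = 2,
      colour = "grey50"
    ) +
    ggplot2::labs(x = "Range (km)", y = "Probability of detection",
                  colour = "Radial") +
    ggplot2::theme_minimal()
}
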
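#' Tidy a detection-range result
#'
#' @param x A `detection_range_result` from [monte_carlo_detection()].
#' @param ... Unused.
#' @return `tidy()`: the percentile-range tibble (`radial`, `level`,
#'   `range_m`). `glance()`: a one-row tibble with the radial-1 percentile
#'   ranges spread into columns plus band and draw count.
#' @method tidy detection_range_result
#' @export
tidy.detection_range_result <- function(x, ...) {
  x$percentile_ranges
}

#' @rdname tidy.detection_range_result
#' @method glance detection_range_result
#' @export
glance.detection_range_result <- function(x, ...) {
  p1 <- x$percentile_ranges |> filter(.data$radial == 1)
  out <- as_tibble(setNames(as.list(p1$range_m),
                            sprintf("r_%g_m", p1$level)))
  out |> mutate(f_lo = x$band$f_lo, f_hi = x$band$f_hi, n_draws = x$n_draws)
}

#' Tidy a PSD matrix
#'
#' @param x A `psd_matrix`.
#' @param ... Unused.
#' @return A long tibble (`frame_time`, `frequency`, `psd_db`).
#' @method tidy psd_matrix
#' @export
tidy.psd_matrix <- function(x, ...) as_tibble(x)

#' @rdname tidy.psd_matrix
#' @method glance psd_matrix
#' @export
glance.psd_matrix <- function(x, ...) {
  tibble(
    n_frames = length(x$frame_times),
    n_bins = length(x$frequencies),
    f_max = max(x$frequencies),
    median_n_averages = median(x$n_averages),
    n_contaminated = sum(x$contamination_flags)
  )
}
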
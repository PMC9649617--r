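#' Bin detection events into an hourly occurrence grid
#'
#' Converts a detection-event log to the day x hour presence/absence grid
#' that seasonal and diel analyses work from: one row per deployment day,
#' UTC hour and signal class, with the recording-effort fraction implied by
#' the duty cycle and a light/dark label from the site's sunrise and sunset
#' times. Presence is binary (one or more events in the hour).
#'
#' @param events Tibble with columns `time` (POSIXct UTC) and `class`
#'   (signal class label). Events outside the deployment are dropped with a
#'   warning.
#' @param deployment A one-row deployment tibble (dates, coordinates, duty
#'   cycle).
#' @param classes Optional character vector of classes to grid (defaults to
#'   those present in `events`).
#' @return An `occurrence_grid` tibble: `date`, `hour`, `class`, `presence`,
#'   `effort` (fraction of the hour recorded), `light` (`"light"`/`"dark"`).
#' @export
bin_hourly <- function(events, deployment, classes = NULL) {
  start <- deployment$start_date[[1]]
  end <- deployment$end_date[[1]]
  days <- seq(start, max(start, end - 1), by = "day")
  classes <- classes %||% unique(events$class)
  if (length(classes) == 0L) classes <- "all"
  eff <- duty_fraction(deployment$duty_cycle[[1]])
  grid <- tidyr::expand_grid(date = days, hour = 0:23, class = classes)
  hour_start <- lubridate::force_tz(lubridate::as_datetime(grid$date), "UTC") +
    grid$hour * 3600
  light <- classify_light_dark(
    hour_start, deployment$latitude[[1]], deployment$longitude[[1]]
  )
  grid <- grid |> mutate(presence = FALSE, effort = eff, light = light)
  if (nrow(events) > 0) {
    ev_date <- as_date(events$time)
    inside <- ev_date >= start & ev_date <= max(start, end - 1)
    if (any(!inside)) {
      warn(sprintf("%d event(s) outside the deployment extent dropped", sum(!inside)))
    }
    ev <- events[inside, , drop = FALSE]
    if (nrow(ev) > 0) {
      hit <- tibble(date = as_date(ev$time),
                    hour = lubridate::hour(ev$time),
                    class = ev$class) |> distinct()
      grid <- grid |>
        left_join(hit |> mutate(.hit = TRUE),
                  by = c("date", "hour", "class")) |>
        mutate(presence = !is.na(.data$.hit)) |>
        select(-".hit")
    }
  }
  class(grid) <- c("occurrence_grid", class(grid))
  grid
}

#' Day/night contrast in acoustic presence
#'
#' Compares effort-normalized presence rates between dark and light hours
#' and attaches a within-day label-permutation test: for each day the
#' light/dark labels are shuffled across that day's hour cells, preserving
#' the daily presence pattern, and the two-sided p-value uses the add-one
#' correction. The test is an inference added by this package; field studies
#' typically report the diel pattern graphically without a named statistic.
#'
#' @param grid An `occurrence_grid` for a single class (filter first if
#'   needed).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation draws.
#' @return A one-row tibble: `night_rate`, `day_rate`, `rate_difference`
#'   (night minus day, per effort-hour), `p_value`, `n_permutations`,
#'   `method`.
#' @export
diel_contrast <- function(grid, n_permutations = 999, seed = 1L) {
  g <- grid |> filter(.data$effort > 0)
  if (!all(c("light", "dark") %in% unique(g$light))) {
    abort("grid needs both light and dark cells with effort")
  }
  pe <- g$presence * g$effort
  eff <- g$effort
  tot_pe <- sum(pe)
  tot_eff <- sum(eff)
  is_dark <- g$light == "dark"
  stat <- function(dark) {
    s_d <- sum(pe[dark]); e_d <- sum(eff[dark])
    s_d / e_d - (tot_pe - s_d) / (tot_eff - e_d)
  }
  stat_obs <- stat(is_dark)
  obs <- c(dark = sum(pe[is_dark]) / sum(eff[is_dark]),
           light = sum(pe[!is_dark]) / sum(eff[!is_dark]))
  if (!any(g$presence)) {
    p <- 1
  } else {
    p <- withr::with_seed(seed, {
      days <- split(seq_len(nrow(g)), g$date)
      exceed <- 0L
      for (b in seq_len(n_permutations)) {
        dark <- is_dark
        for (idx in days) dark[idx] <- is_dark[sample(idx)]
        if (abs(stat(dark)) >= abs(stat_obs) - 1e-12) exceed <- exceed + 1L
      }
      (1 + exceed) / (n_permutations + 1)
    })
  }
  tibble(
    night_rate = obs[["dark"]], day_rate = obs[["light"]],
    rate_difference = stat_obs, p_value = p,
    n_permutations = n_permutations,
    method = "within-day label permutation (package-added inference)"
  )
}

#' Presence proportion by period
#'
#' Aggregates an occurrence grid to the proportion of effort-hours with
#' presence per day, week or month. Periods with no recording effort are
#' missing, not zero.
#'
#' @param grid An `occurrence_grid`.
#' @param period `"day"`, `"week"` or `"month"`.
#' @return A tibble: `period_start`, `class`, `presence_hours`,
#'   `effort_hours`, `proportion`.
#' @export
seasonal_summary <- function(grid, period = c("day", "week", "month")) {
  period <- match.arg(period)
  if (nrow(grid) == 0L) abort("empty grid")
  grid |>
    mutate(period_start = lubridate::floor_date(.data$date, unit = period)) |>
    group_by(.data$period_start, .data$class) |>
    summarise(
      presence_hours = sum(.data$presence * .data$effort),
      effort_hours = sum(.data$effort),
      .groups = "drop"
    ) |>
    mutate(proportion = ifelse(.data$effort_hours > 0,
                               .data$presence_hours / .data$effort_hours,
                               NA_real_))
}
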
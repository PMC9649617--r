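#' Occupancy event-stream specification
#'
#' Parameters of a synthetic seasonal, diel-structured acoustic-presence
#' process: an inhomogeneous Poisson event stream with a flat hourly rate
#' inside seasonal day-of-year windows (zero outside) and a multiplicative
#' night bias during dark hours.
#'
#' @param seasonal_windows Data frame with columns `start_doy`, `end_doy`
#'   (day-of-year, 1-366). A window with `start_doy > end_doy` wraps the
#'   year end (e.g. Sep-Jan).
#' @param hourly_rate Mean events per recorded hour inside a window, >= 0.
#' @param diel_night_multiplier Rate multiplier during dark hours, >= 0
#'   (1 = no diel structure).
#' @param seed Integer seed.
#' @return An `occupancy_spec` object.
#' @export
occupancy_spec <- function(seasonal_windows, hourly_rate,
                           diel_night_multiplier = 1, seed = 1L) {
  sw <- as_tibble(seasonal_windows)
  stopifnot(all(c("start_doy", "end_doy") %in% names(sw)))
  if (any(sw$start_doy < 1 | sw$start_doy > 366 | sw$end_doy < 1 | sw$end_doy > 366)) {
    abort("seasonal windows must lie in [1, 366]")
  }
  if (hourly_rate < 0) abort("hourly_rate must be >= 0")
  if (diel_night_multiplier < 0) abort("diel_night_multiplier must be >= 0")
  structure(
    list(seasonal_windows = sw, hourly_rate = hourly_rate,
         diel_night_multiplier = diel_night_multiplier, seed = as.integer(seed)),
    class = "occupancy_spec"
  )
}

doy_in_windows <- function(doy, windows) {
  hit <- rep(FALSE, length(doy))
  for (k in seq_len(nrow(windows))) {
    s <- windows$start_doy[k]; e <- windows$end_doy[k]
    hit <- hit | if (s <= e) doy >= s & doy <= e else doy >= s | doy <= e
  }
  hit
}

#' Simulate a seasonal, diel-biased detection-event stream
#'
#' Draws an inhomogeneous Poisson event stream over the deployment: each UTC
#' hour inside a seasonal window has Poisson-distributed event count with
#' mean `hourly_rate`, multiplied by `diel_night_multiplier` when the hour
#' is dark at the deployment's coordinates (sunrise/sunset from
#' [solar_times()]); event times are uniform within the hour.
#'
#' @param spec An [occupancy_spec()].
#' @param deployment A one-row deployment tibble.
#' @param class_label Signal class written on the events.
#' @return A detection-event tibble: `time` (POSIXct UTC), `class`,
#'   `score_db` (`NA` for simulated events), `validated`.
#' @export
sim_occupancy <- function(spec, deployment, class_label = "sim") {
  stopifnot(inherits(spec, "occupancy_spec"))
  start <- deployment$start_date[[1]]
  end <- deployment$end_date[[1]]
  days <- seq(start, max(start, end - 1), by = "day")
  grid <- tidyr::expand_grid(date = days, hour = 0:23)
  hour_start <- lubridate::force_tz(lubridate::as_datetime(grid$date), "UTC") +
    grid$hour * 3600
  in_season <- doy_in_windows(yday(grid$date), spec$seasonal_windows)
  rate <- ifelse(in_season, spec$hourly_rate, 0)
  if (spec$diel_night_multiplier != 1 && any(rate > 0)) {
    light <- classify_light_dark(hour_start, deployment$latitude[[1]],
                                 deployment$longitude[[1]])
    rate <- rate * ifelse(light == "dark", spec$diel_night_multiplier, 1)
  }
  withr::with_seed(spec$seed, {
    n <- rpois(length(rate), rate)
    times <- hour_start[rep(seq_along(n), n)] + runif(sum(n)) * 3600
  })
  tibble(
    time = sort(times), class = class_label,
    score_db = NA_real_, validated = TRUE
  )
}

#' Environmental series specification
#'
#' Parameters of synthetic 8-day sea-surface-temperature and chlorophyll-a
#' series: SST is a seasonal sinusoid with Gaussian noise; chl-a is a
#' baseline plus Gaussian bloom peaks (spring/fall), with winter values
#' (Dec-Feb) dropped at random to mimic low-sun-angle satellite gaps.
#'
#' @param sst_mean,sst_amplitude Mean and seasonal amplitude of SST, deg C
#'   (`amplitude >= 0`).
#' @param sst_phase Day-of-year of the SST maximum.
#' @param sst_noise_sd Gaussian noise sd, deg C.
#' @param chla_baseline Baseline chl-a, mg/m^3.
#' @param blooms Data frame with columns `peak_doy`, `amplitude`, `width`
#'   (days) describing Gaussian chl-a bloom bumps.
#' @param winter_missing_probability Probability a winter chl-a composite is
#'   missing, in \[0, 1\].
#' @param seed Integer seed.
#' @return An `env_spec` object.
#' @export
env_spec <- function(sst_mean = 10, sst_amplitude = 4, sst_phase = 227,
                     sst_noise_sd = 0.3, chla_baseline = 0.6,
                     blooms = data.frame(peak_doy = c(120, 265),
                                         amplitude = c(3, 1.5),
                                         width = c(20, 15)),
                     winter_missing_probability = 0.5, seed = 1L) {
  if (sst_amplitude < 0) abort("amplitudes must be >= 0")
  blooms <- as_tibble(blooms)
  stopifnot(all(c("peak_doy", "amplitude", "width") %in% names(blooms)))
  if (any(blooms$amplitude < 0)) abort("amplitudes must be >= 0")
  if (winter_missing_probability < 0 || winter_missing_probability > 1) {
    abort("winter_missing_probability must be in [0, 1]")
  }
  structure(
    list(sst_mean = sst_mean, sst_amplitude = sst_amplitude,
         sst_phase = sst_phase, sst_noise_sd = sst_noise_sd,
         chla_baseline = chla_baseline, blooms = blooms,
         winter_missing_probability = winter_missing_probability,
         seed = as.integer(seed)),
    class = "env_spec"
  )
}

#' Simulate 8-day SST and chlorophyll-a series
#'
#' Generates one value per 8-day composite period (satellite convention:
#' periods start January 1 and restart each year) between two dates.
#'
#' @param spec An [env_spec()].
#' @param start_date,end_date Calendar dates, `end_date > start_date`.
#' @return A tibble: `composite_start`, `sst_c`, `chla_mg_m3` (`NA` where a
#'   winter composite was dropped).
#' @export
sim_env <- function(spec, start_date, end_date) {
  stopifnot(inherits(spec, "env_spec"))
  start_date <- as_date(start_date); end_date <- as_date(end_date)
  if (end_date <= start_date) abort("end_date must be after start_date")
  dates <- composite_calendar(start_date, end_date)$composite_start
  doy <- yday(dates)
  sst_det <- spec$sst_mean +
    spec$sst_amplitude * cos(2 * pi * (doy - spec$sst_phase) / 365.25)
  chla <- rep(spec$chla_baseline, length(doy))
  for (k in seq_len(nrow(spec$blooms))) {
    b <- spec$blooms[k, ]
    # nearest wrapped distance to the bloom peak
    d <- pmin(abs(doy - b$peak_doy), 365.25 - abs(doy - b$peak_doy))
    chla <- chla + b$amplitude * exp(-0.5 * (d / b$width)^2)
  }
  winter <- doy >= 335 | doy <= 59
  withr::with_seed(spec$seed, {
    sst <- sst_det + rnorm(length(doy), sd = spec$sst_noise_sd)
    drop <- winter & runif(length(doy)) < spec$winter_missing_probability
  })
  chla[drop] <- NA_real_
  tibble(composite_start = dates, sst_c = sst, chla_mg_m3 = chla)
}
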
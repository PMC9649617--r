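# NOAA solar calculator quantities. `jc` is the Julian century from J2000;
# all angles in degrees. Returns equation of time (minutes) and solar
# declination (degrees).
noaa_eot_decl <- function(jc) {
  d2r <- pi / 180
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(m * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * m * d2r) * 0.000289
  true_long <- l0 + ctr
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(obliq * d2r) * sin(app_long * d2r)) / d2r
  y <- tan(obliq / 2 * d2r)^2
  eot <- 4 / d2r * (y * sin(2 * l0 * d2r) - 2 * ecc * sin(m * d2r) +
                      4 * ecc * y * sin(m * d2r) * cos(2 * l0 * d2r) -
                      0.5 * y^2 * sin(4 * l0 * d2r) -
                      1.25 * ecc^2 * sin(2 * m * d2r))
  list(eot = eot, decl = decl)
}

julian_century <- function(time_utc) {
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  (jd - 2451545) / 36525
}

#' Sunrise and sunset times (NOAA solar calculator)
#'
#' Computes sunrise, sunset and solar noon in UTC for one or more dates
#' using the NOAA solar-position algorithm (Julian century, equation of
#' time, solar declination, hour angle at zenith 90.833 deg, i.e. including
#' standard refraction and the solar semidiameter). Event times are refined
#' by re-evaluating the ephemeris at the event itself. Polar day/night is
#' flagged when the sun never crosses the horizon.
#'
#' @param latitude,longitude Decimal degrees; east longitude positive.
#' @param dates Calendar dates.
#' @return A tibble with `date`, `sunrise`, `sunset`, `solar_noon` (POSIXct
#'   UTC; `NA` under a polar flag) and `polar_flag` (`"normal"`,
#'   `"all_day"`, `"all_night"`).
#' @export
#' @examples
#' solar_times(52.03, -131.2, as.Date("2018-06-21"))
solar_times <- function(latitude, longitude, dates) {
  if (abs(latitude) > 90 || abs(longitude) > 180) abort("invalid coordinates")
  dates <- as_date(dates)
  d2r <- pi / 180
  one <- function(date) {
    midnight <- lubridate::force_tz(lubridate::as_datetime(date), "UTC")
    event_minutes <- function(guess_min, rise) {
      # iterate: evaluate EoT/declination at the current event estimate
      t_min <- guess_min
      for (i in 1:3) {
        sp <- noaa_eot_decl(julian_century(midnight + t_min * 60))
        cos_ha <- cos(90.833 * d2r) / (cos(latitude * d2r) * cos(sp$decl * d2r)) -
          tan(latitude * d2r) * tan(sp$decl * d2r)
        if (cos_ha > 1) return(list(t = NA_real_, flag = "all_night"))
        if (cos_ha < -1) return(list(t = NA_real_, flag = "all_day"))
        ha <- acos(cos_ha) / d2r
        noon <- 720 - 4 * longitude - sp$eot
        t_min <- if (rise) noon - 4 * ha else noon + 4 * ha
      }
      list(t = t_min, flag = "normal")
    }
    guess <- 720 - 4 * longitude
    rise <- event_minutes(guess - 360, rise = TRUE)
    set <- event_minutes(guess + 360, rise = FALSE)
    sp_noon <- noaa_eot_decl(julian_century(midnight + guess * 60))
    noon_min <- 720 - 4 * longitude - sp_noon$eot
    flag <- if (rise$flag != "normal") rise$flag else set$flag
    tibble(
      date = date,
      sunrise = if (flag == "normal") midnight + rise$t * 60 else midnight + NA_real_,
      sunset = if (flag == "normal") midnight + set$t * 60 else midnight + NA_real_,
      solar_noon = midnight + noon_min * 60,
      polar_flag = flag
    )
  }
  bind_rows(lapply(dates, one))
}

#' Classify hour bins as light or dark
#'
#' Applies the convention that "light" hours lie between sunrise and sunset:
#' an hour is light iff its midpoint falls in `[sunrise, sunset)`; under a
#' polar flag the whole day is light (`all_day`) or dark (`all_night`).
#'
#' @param hour_start POSIXct (UTC) start of each hour bin.
#' @param latitude,longitude Site coordinates, decimal degrees.
#' @return Character vector, `"light"` or `"dark"`.
#' @export
classify_light_dark <- function(hour_start, latitude, longitude) {
  mid <- hour_start + 1800
  dates <- unique(as_date(mid))
  sol <- solar_times(latitude, longitude, dates)
  sol_idx <- match(as_date(mid), sol$date)
  out <- ifelse(
    sol$polar_flag[sol_idx] == "all_day", "light",
    ifelse(sol$polar_flag[sol_idx] == "all_night", "dark",
           ifelse(mid >= sol$sunrise[sol_idx] & mid < sol$sunset[sol_idx],
                  "light", "dark"))
  )
  unname(out)
}
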
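test_that("sunrise and sunset follow the solar geometry", {
  # equator at an equinox: close to 12 h of daylight
  s <- solar_times(0, 0, as.Date("2019-03-20"))
  daylight <- as.numeric(difftime(s$sunset, s$sunrise, units = "mins"))
  expect_lt(abs(daylight - 12 * 60), 10)

  # mid-northern latitude: June days longer than December days
  s2 <- solar_times(52.03, -131.2, as.Date(c("2018-06-21", "2018-12-21")))
  dl <- as.numeric(difftime(s2$sunset, s2$sunrise, units = "hours"))
  expect_gt(dl[1], dl[2])

  # agreement with the independently coded spreadsheet oracle within 2 min
  cases <- expand.grid(
    lat = c(-35, 0.5, 23.4, 52.03, 65),
    lon = c(-131.2, 0, 77.5),
    date = as.Date(c("2018-01-15", "2018-04-03", "2018-07-21", "2018-10-30"))
  )
  for (i in seq_len(nrow(cases))) {
    o <- noaa_spreadsheet_oracle(cases$lat[i], cases$lon[i], cases$date[i])
    got <- solar_times(cases$lat[i], cases$lon[i], cases$date[i])
    midnight <- lubridate::force_tz(lubridate::as_datetime(cases$date[i]), "UTC")
    rise_min <- as.numeric(difftime(got$sunrise, midnight, units = "mins"))
    set_min <- as.numeric(difftime(got$sunset, midnight, units = "mins"))
    expect_lt(abs(rise_min - o$sunrise), 2)
    expect_lt(abs(set_min - o$sunset), 2)
  }

  # consecutive sunrises drift slowly at mid-latitudes
  dates <- seq(as.Date("2018-01-01"), as.Date("2018-12-30"), by = "day")
  st <- solar_times(52.03, -131.2, dates)
  rise_min <- as.numeric(st$sunrise - lubridate::force_tz(
    lubridate::as_datetime(st$date), "UTC"), units = "mins")
  expect_lt(max(abs(diff(rise_min))), 5)

  # polar night above the Arctic circle in December
  sp <- solar_times(78, 15, as.Date("2018-12-21"))
  expect_identical(sp$polar_flag, "all_night")
  expect_identical(solar_times(78, 15, as.Date("2018-06-21"))$polar_flag,
                   "all_day")
  expect_error(solar_times(95, 0, Sys.Date()), "coordinates")
})

test_that("hour bins are labeled by the midpoint rule", {
  # 52 N in late September: sunrise ~14:10 UTC, sunset ~02:20 UTC next day
  lat <- 52.4; lon <- -131.7
  day <- as.Date("2018-09-25")
  sol <- solar_times(lat, lon, day)
  midnight <- lubridate::force_tz(lubridate::as_datetime(day), "UTC")
  labels <- classify_light_dark(midnight + (0:23) * 3600, lat, lon)
  rise_hr <- as.numeric(difftime(sol$sunrise, midnight, units = "hours"))
  # an hour wholly after sunrise and before sunset is light
  expect_identical(labels[ceiling(rise_hr) + 2], "light")
  # an hour wholly before sunrise is dark
  expect_identical(labels[floor(rise_hr) - 2], "dark")
  # the straddling hour follows its midpoint
  straddle <- floor(rise_hr) + 1
  mid <- midnight + (straddle - 0.5) * 3600
  expect_identical(labels[straddle],
                   if (mid >= sol$sunrise) "light" else "dark")
})

test_that("hourly binning produces presence, effort and labels", {
  dep <- test_deployment("2018-09-01", "2018-09-11",
                         record_s = 300, off_s = 3300)
  t0 <- lubridate::ymd_hms("2018-09-03 05:00:00", tz = "UTC")
  ev <- dplyr::tibble(
    time = c(t0 + c(60, 600, 1500), t0 + 86400),
    class = "fin"
  )
  g <- bin_hourly(ev, dep)
  expect_identical(nrow(g), 10L * 24L)
  # three events in one hour collapse to a single presence cell
  expect_identical(sum(g$presence), 2L)
  # duty cycle 5 min / 60 min: effort 1/12 everywhere
  expect_true(all(abs(g$effort - 1 / 12) < 1e-12))
  # presence only where effort > 0
  expect_true(all(g$effort[g$presence] > 0))
  # out-of-range events are dropped with a warning
  expect_warning(
    g2 <- bin_hourly(dplyr::tibble(time = t0 + 365 * 86400, class = "fin"), dep),
    "dropped"
  )
  expect_identical(sum(g2$presence), 0L)
  # empty event set still yields the full-effort grid
  g3 <- bin_hourly(ev[0, ], dep, classes = "fin")
  expect_identical(sum(g3$presence), 0L)
  expect_identical(nrow(g3), 10L * 24L)
})

test_that("diel contrast finds strong night bias and respects nulls", {
  dep <- test_deployment("2018-09-01", "2018-10-31")
  # strongly nocturnal fixture
  spn <- occupancy_spec(data.frame(start_doy = 1, end_doy = 366), 0.4,
                        diel_night_multiplier = 6, seed = 2)
  gn <- bin_hourly(sim_occupancy(spn, dep, "delphinid"), dep)
  dc <- diel_contrast(gn, n_permutations = 199, seed = 1)
  expect_gt(dc$night_rate, dc$day_rate)
  expect_lt(dc$p_value, 0.05)
  # all presence in dark cells: difference equals the dark rate
  gd <- gn |> dplyr::mutate(presence = presence & light == "dark")
  dcd <- diel_contrast(gd, n_permutations = 99, seed = 1)
  expect_equal(dcd$rate_difference, dcd$night_rate)
  # no presence at all: rates 0 and p = 1
  g0 <- gn |> dplyr::mutate(presence = FALSE)
  dc0 <- diel_contrast(g0, n_permutations = 99, seed = 1)
  expect_equal(c(dc0$night_rate, dc0$day_rate, dc0$p_value), c(0, 0, 1))
})

test_that("seasonal summaries recover the configured window", {
  dep <- test_deployment("2018-08-01", "2018-11-20")
  sp <- occupancy_spec(data.frame(start_doy = 244, end_doy = 288), 2, seed = 6)
  g <- bin_hourly(sim_occupancy(sp, dep, "blue"), dep)
  # constant presence gives proportion 1
  g1 <- g |> dplyr::mutate(presence = TRUE)
  s1 <- seasonal_summary(g1, "month")
  expect_true(all(s1$proportion == 1))
  # daily window edges within one day bin of the configured season
  sd <- seasonal_summary(g, "day") |>
    dplyr::filter(!is.na(proportion), proportion > 0)
  expect_lte(abs(lubridate::yday(min(sd$period_start)) - 244), 1)
  expect_lte(abs(lubridate::yday(max(sd$period_start)) - 288), 1)
  # a period with no effort is missing, not zero
  g_ne <- g |> dplyr::mutate(effort = ifelse(date < as.Date("2018-08-08"), 0,
                                             effort))
  sw <- seasonal_summary(g_ne, "week")
  expect_true(any(is.na(sw$proportion)))
  expect_false(any(sw$proportion[!is.na(sw$proportion)] < 0))
})
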
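# Independent oracles used across the suite. These deliberately do not call
# package internals: the solar oracle is a direct single-shot transcription
# of the NOAA spreadsheet cell formulas, and the Monte Carlo oracle is a
# plain triple loop over draws.

# NOAA spreadsheet sunrise/sunset, evaluated once at local noon (no
# refinement). Returns minutes past UTC midnight.
noaa_spreadsheet_oracle <- function(lat, lon, date) {
  rad <- function(x) x * pi / 180
  deg <- function(x) x * 180 / pi
  jd <- as.numeric(as.Date(date)) + 2440587.5 + 0.5 - lon / 360
  t <- (jd - 2451545) / 36525
  l0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  c <- sin(rad(m)) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(rad(2 * m)) * (0.019993 - 0.000101 * t) + sin(rad(3 * m)) * 0.000289
  lam <- l0 + c - 0.00569 - 0.00478 * sin(rad(125.04 - 1934.136 * t))
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(rad(125.04 - 1934.136 * t))
  decl <- deg(asin(sin(rad(eps)) * sin(rad(lam))))
  y <- tan(rad(eps / 2))^2
  eot <- 4 * deg(y * sin(2 * rad(l0)) - 2 * e * sin(rad(m)) +
                   4 * e * y * sin(rad(m)) * cos(2 * rad(l0)) -
                   0.5 * y^2 * sin(4 * rad(l0)) -
                   1.25 * e^2 * sin(2 * rad(m)))
  cos_ha <- cos(rad(90.833)) / (cos(rad(lat)) * cos(rad(decl))) -
    tan(rad(lat)) * tan(rad(decl))
  if (abs(cos_ha) > 1) return(list(sunrise = NA, sunset = NA))
  ha <- deg(acos(cos_ha))
  noon <- 720 - 4 * lon - eot
  list(sunrise = noon - 4 * ha, sunset = noon + 4 * ha)
}

# Brute-force Monte Carlo detection-range oracle: replays the documented
# per-iteration draw order (NL minute, SL draws, depth draws) under the same
# seed, then evaluates detectability draw by draw over the grid.
brute_force_mc <- function(nl_series, sl, depths, pl_model, config) {
  f <- sqrt(sl$band$f_lo * sl$band$f_hi)
  grid <- seq(config$range_step_m,
              min(config$max_range_m, pl_model$max_range_m),
              by = config$range_step_m)
  n_sup <- length(depths$depth_m)
  draws <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_iterations), function(i) {
      nl_i <- nl_series[[sample.int(length(nl_series), 1L)]]
      sl_i <- rnorm(config$n_sl_draws, sl$mean, sl$sd)
      d_i <- sample.int(n_sup, config$n_depth_draws, replace = TRUE,
                        prob = depths$weight)
      list(nl = nl_i, sl = sl_i, d = d_i)
    })
  })
  detect_count <- numeric(length(grid))
  total <- 0
  for (it in draws) {
    for (s in it$sl) {
      for (j in it$d) {
        pl <- pl_model$evaluate(f, depths$depth_m[j], grid, 1L)
        detect_count <- detect_count + as.numeric(s - pl >= it$nl + config$dt)
        total <- total + 1
      }
    }
  }
  prob <- detect_count / total
  ranges <- vapply(config$probability_levels, function(p) {
    ok <- which(prob >= p)
    if (length(ok) == 0L) 0 else grid[max(ok)]
  }, numeric(1))
  list(grid = grid, prob = prob,
       ranges = data.frame(level = config$probability_levels, range_m = ranges))
}

# flat-spectrum test wave
flat_noise_wave <- function(level_db = 60, duration = 60, fs = 256, seed = 1) {
  sp <- noise_spec(data.frame(frequency = c(1, fs / 2 * 0.98),
                              psd_db = c(level_db, level_db)), seed = seed)
  sim_ambient(sp, duration, fs)
}

# small synthetic deployment used by occurrence tests
test_deployment <- function(start = "2018-09-01", end = "2018-11-01",
                            record_s = 3600, off_s = NULL) {
  dc <- if (is.null(off_s)) {
    duty_cycle(record_s, "record", 256)
  } else {
    duty_cycle(c(record_s, off_s), c("record", "off"), c(256, NA))
  }
  deployment_record("TST", 52.4, -131.7, 100, "sim", start, end, duty_cycle = dc)
}
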
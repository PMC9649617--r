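test_that("sonar-equation primitives behave as definitions", {
  expect_equal(received_level(180, 60), 120)
  expect_equal(received_level(170, 0), 170)
  expect_true(is_detectable(100, 100, 0))    # equality detects
  expect_false(is_detectable(99.9, 100, 0))
  expect_true(is_detectable(110, 100, 10))
})

test_that("geometric spreading and Thorp absorption are well behaved", {
  m <- pl_geometric("spherical", absorption = "none")
  expect_equal(m$evaluate(20, 10, 1), 0)
  expect_equal(m$evaluate(20, 10, 1000), 60)
  expect_error(m$evaluate(20, 10, 0.5), "range")
  # absorption strictly increasing over 1-100 kHz
  f <- seq(1000, 100000, length.out = 50)
  expect_true(all(diff(thorp_absorption(f)) > 0))
  # hybrid transitions continuously to cylindrical slope
  h <- pl_geometric("hybrid", transition_range_m = 1000, absorption = "none")
  expect_equal(h$evaluate(20, 10, 1000), 60)
  expect_equal(h$evaluate(20, 10, 10000), 60 + 10)
})

test_that("single-draw detection range matches the closed form", {
  b <- freq_band(18, 28)
  m <- pl_geometric("spherical", absorption = "none")
  grid <- seq(10, 20000, by = 10)
  expect_equal(
    detection_range_single(180, 10, 100, b, m, range_grid = grid), 10000
  )
  # never detectable
  expect_equal(
    detection_range_single(90, 10, 100, b, m, range_grid = grid), 0
  )
  expect_error(detection_range_single(180, 10, 100, b, m,
                                      range_grid = numeric(0)), "empty")
})

test_that("non-monotone loss keeps the outermost detectable point", {
  # spherical loss with a 10-dB convergence-zone dip at 8-9 km
  wiggly <- structure(list(
    evaluate = function(frequency, source_depth, range_m, radial = 1L) {
      20 * log10(range_m) - 10 * (range_m >= 8000 & range_m <= 9000)
    },
    n_radials = 1L, max_range_m = Inf
  ), class = "pl_model")
  b <- freq_band(18, 28)
  grid <- seq(10, 20000, by = 10)
  # SL 175 / NL 100: plain detectable out to 10^(75/20) ~ 5623 m, but the
  # dip rebounds into detectability out to 9000 m
  got <- detection_range_single(175, 10, 100, b, wiggly, range_grid = grid)
  # exhaustive scan oracle
  ok <- 175 - wiggly$evaluate(sqrt(18 * 28), 10, grid) >= 100
  expect_equal(got, max(grid[ok]))
  expect_equal(got, 9000)
})

test_that("the final range is the per-band maximum with low-frequency ties", {
  br <- dplyr::tibble(f_lo = c(15, 100), f_hi = c(28, 200),
                      range_m = c(5000, 12000))
  out <- rmax_over_bands(br)
  expect_equal(out$r_max_m, 12000)
  expect_equal(out$f_lo, 100)
  one <- rmax_over_bands(br[1, ])
  expect_equal(one$r_max_m, 5000)
  tie <- rmax_over_bands(dplyr::tibble(f_lo = c(100, 15), f_hi = c(200, 28),
                                       range_m = c(7000, 7000)))
  expect_equal(tie$f_lo, 15)
  expect_error(rmax_over_bands(br[0, ]), "band")
})

test_that("degenerate Monte Carlo collapses to the closed form", {
  b <- freq_band(18, 28)
  m <- pl_geometric("spherical", absorption = "none")
  cfg <- mc_config(n_iterations = 50, n_sl_draws = 5, n_depth_draws = 5,
                   max_range_m = 20000, range_step_m = 10, seed = 1)
  r <- monte_carlo_detection(100, sl_spec(180, 0, b), depth_dist(10), m, cfg)
  expect_true(all(tidy(r)$range_m == 10000))
  # probability curve is a clean 0/1 step for the degenerate configuration
  expect_true(all(r$prob_curve$probability %in% c(0, 1)))
  expect_true(all(diff(r$prob_curve$probability) <= 0))
})

test_that("Monte Carlo matches brute-force enumeration draw for draw", {
  b <- freq_band(18, 28)
  m <- pl_geometric("spherical", absorption = "none")
  cfg <- mc_config(n_iterations = 100, n_sl_draws = 8, n_depth_draws = 6,
                   max_range_m = 30000, range_step_m = 100, seed = 42)
  sl <- sl_spec(175, 6, b)
  dd <- depth_dist(c(10, 50, 200), c(0.5, 0.3, 0.2))
  nl <- c(95, 100, 104, 110)
  r <- monte_carlo_detection(nl, sl, dd, m, cfg)
  bf <- brute_force_mc(nl, sl, dd, m, cfg)
  expect_equal(r$prob_curve$probability, bf$prob, tolerance = 1e-12)
  expect_equal(tidy(r)$range_m, bf$ranges$range_m)
  # percentile ordering: lower probability level, larger range
  expect_true(all(diff(tidy(r)$range_m) <= 0))
})

test_that("ranges move the right way under coupled-seed perturbations", {
  b <- freq_band(18, 28)
  m <- pl_geometric("spherical", absorption = "none")
  cfg <- mc_config(n_iterations = 300, n_sl_draws = 20, n_depth_draws = 10,
                   max_range_m = 50000, range_step_m = 50, seed = 7)
  sl <- sl_spec(175, 5, b)
  dd <- depth_dist(c(10, 100), c(0.6, 0.4))
  nl <- c(95, 100, 105)
  base <- tidy(monte_carlo_detection(nl, sl, dd, m, cfg))$range_m
  louder_noise <- tidy(monte_carlo_detection(nl + 20, sl, dd, m, cfg))$range_m
  expect_true(all(louder_noise <= base))
  louder_source <- tidy(monte_carlo_detection(nl, sl_spec(185, 5, b), dd, m,
                                              cfg))$range_m
  expect_true(all(louder_source >= base))
  cfg_dt <- cfg; cfg_dt$dt <- 6
  with_dt <- tidy(monte_carlo_detection(nl, sl, dd, m, cfg_dt))$range_m
  expect_true(all(with_dt <= base))
  # probability curve bounded and non-increasing under monotone loss
  pc <- monte_carlo_detection(nl, sl, dd, m, cfg)$prob_curve
  expect_true(all(pc$probability >= 0 & pc$probability <= 1))
  expect_true(all(diff(pc$probability) <= 1e-12))
  expect_error(monte_carlo_detection(numeric(0), sl, dd, m, cfg), "empty")
  expect_error(sl_spec(180, -1, b), "sd")
  expect_error(depth_dist(numeric(0)), "empty")
})

test_that("a tabulated loss grid interpolates and guards its domain", {
  # analytic PL = 20 log10(r) + 0.002 z over a modest grid
  g <- expand.grid(radial = 1L, frequency = c(25, 1000),
                   source_depth = c(10, 100, 400),
                   range_m = seq(500, 10000, by = 50))
  g$pl_db <- 20 * log10(g$range_m) + 0.002 * g$source_depth
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(g, path, row.names = FALSE)
  m <- load_pl_grid(path)
  # node exact
  expect_equal(m$evaluate(25, 100, 500), 20 * log10(500) + 0.2)
  # midpoints within 0.1 dB of the analytic surface (loss is smooth)
  mids <- seq(525, 9975, by = 50)
  expect_lt(max(abs(m$evaluate(25, 55, mids) -
                      (20 * log10(mids) + 0.002 * 55))), 0.1)
  expect_error(m$evaluate(25, 55, 20000), "domain")
  expect_error(m$evaluate(25, 600, 500), "domain")
  expect_error(m$evaluate(25, 55, 500, radial = 3L), "radial")
  # malformed file
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(g[, 1:4], bad, row.names = FALSE)
  expect_error(load_pl_grid(bad), "missing columns")
})
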
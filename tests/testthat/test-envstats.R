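test_that("the composite calendar restarts each January 1", {
  cal <- composite_calendar("2018-01-01", "2019-12-31")
  expect_identical(cal$composite_start[1], as.Date("2018-01-01"))
  expect_true(as.Date("2019-01-01") %in% cal$composite_start)
  # 46 periods per year; last period of a regular year has 5 days
  y18 <- cal[lubridate::year(cal$composite_start) == 2018, ]
  expect_identical(nrow(y18), 46L)
  expect_identical(y18$n_days, c(rep(8L, 45), 5L))
})

test_that("box averaging uses cells inside the square", {
  field <- tidyr::expand_grid(latitude = seq(51.9, 52.9, by = 0.04),
                              longitude = seq(-132.2, -130.8, by = 0.06)) |>
    dplyr::mutate(value = 7)
  expect_equal(box_average(field, 52.4, -131.5), 7)
  # half the cells missing: mean of the observed half
  f2 <- field |> dplyr::mutate(value = ifelse(dplyr::row_number() %% 2 == 0,
                                              NA, 5))
  expect_equal(box_average(f2, 52.4, -131.5), 5)
  # a box covering a single cell (centered on a grid node) returns it
  f3 <- field |> dplyr::mutate(value = dplyr::row_number())
  one <- box_average(f3, 52.38, -131.48, box_side_km = 4)
  node <- f3$value[abs(f3$latitude - 52.38) < 1e-9 &
                     abs(f3$longitude + 131.48) < 1e-9]
  expect_equal(one, node)
  expect_error(box_average(field, 10, 10), "cover")
})

test_that("8-day composites average presence over effort", {
  dep <- test_deployment("2018-01-01", "2018-02-01")
  g <- bin_hourly(dplyr::tibble(time = lubridate::ymd_hms("2018-01-02 01:00:00",
                                                          tz = "UTC"),
                                class = "fin")[0, ], dep, classes = "fin")
  # alternate-hour presence: proportion 0.5 per composite
  g5 <- g |> dplyr::mutate(presence = hour %% 2 == 0)
  c5 <- composite_8day(g5)
  expect_true(all(abs(c5$proportion - 0.5) < 1e-12))
  # days {0,0,0,0,1,1,1,1} average to 0.5
  g8 <- g |> dplyr::mutate(presence = date >= as.Date("2018-01-05") &
                             date <= as.Date("2018-01-08"))
  c8 <- composite_8day(g8)
  expect_equal(c8$proportion[c8$composite_start == as.Date("2018-01-01")], 0.5)
  # a deployment starting mid-window flags the partial composite
  dep2 <- test_deployment("2018-01-06", "2018-01-20")
  g2 <- bin_hourly(dplyr::tibble(time = lubridate::ymd_hms("2018-01-07 01:00:00",
                                                           tz = "UTC"),
                                 class = "fin"), dep2)
  c2 <- composite_8day(g2)
  first <- c2[c2$composite_start == as.Date("2018-01-01"), ]
  expect_true(first$partial)
  expect_identical(first$n_days_covered, 3L)
})

test_that("median imputation fills gaps without touching observations", {
  out <- impute_chla(c(1, NA, 3))
  expect_equal(out$value, c(1, 2, 3))
  expect_identical(out$imputed, c(FALSE, TRUE, FALSE))
  out2 <- impute_chla(c(2, 4, 6))
  expect_equal(out2$value, c(2, 4, 6))
  expect_false(any(out2$imputed))
  out3 <- impute_chla(c(1, 1, 1, 100, NA))
  expect_equal(out3$value[5], 1)   # median is robust to the outlier
  expect_error(impute_chla(c(NA_real_, NA_real_)), "missing")
})

test_that("Kruskal-Wallis H matches rank arithmetic", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_identical(kw$df, 2L)
  # all equal observations: H = 0
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5, 5)))$statistic, 0)
  # invariance under strictly monotone transforms
  g <- list(c(0.2, 1.4, 2.2), c(0.9, 3.1), c(2.8, 4.4, 5.0))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, exp))$statistic)
  # hand rank-arithmetic oracle on a small two-group case with ties
  a <- c(1, 2, 2, 5); b <- c(3, 3, 6)
  r <- rank(c(a, b)); n <- 7
  rs <- c(sum(r[1:4]), sum(r[5:7]))
  h_raw <- 12 / (n * (n + 1)) * sum(rs^2 / c(4, 3)) - 3 * (n + 1)
  ties <- table(c(a, b))
  h_hand <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(list(a, b))$statistic, h_hand)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Dunn Z statistics match brute-force rank arithmetic", {
  g <- list(sg = c(0.1, 0.4, 0.9), gs = c(0.5, 0.8, 1.2), ri = c(0.2, 0.3, 0.6))
  d <- dunn_test(g, adjustment = "none")
  # brute-force: pooled ranks, tie-corrected variance
  pooled <- unlist(g); r <- rank(pooled); n <- length(pooled)
  mr <- tapply(r, rep(1:3, each = 3), mean)
  ties <- table(pooled)
  v <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  z12 <- (mr[1] - mr[2]) / sqrt(v * (1 / 3 + 1 / 3))
  expect_equal(d$z[d$group1 == "sg" & d$group2 == "gs"], unname(z12))
  # antisymmetry under group swap
  gswap <- g[c(2, 1, 3)]
  dswap <- dunn_test(gswap, adjustment = "none")
  expect_equal(dswap$z[dswap$group1 == "gs" & dswap$group2 == "sg"],
               -d$z[d$group1 == "sg" & d$group2 == "gs"])
  # identical groups: Z = 0, p = 1
  d0 <- dunn_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_raw, 1)
  # Holm-adjusted p never below raw, never above 1
  dh <- dunn_test(g, adjustment = "holm")
  expect_true(all(dh$p_adjusted >= dh$p_raw - 1e-15))
  expect_true(all(dh$p_adjusted <= 1))
  expect_error(dunn_test(list(1:3)), "2 groups")
})

test_that("the model table couples occupancy to its environmental driver", {
  es <- env_spec(sst_noise_sd = 0.2, winter_missing_probability = 0.3, seed = 8)
  env <- sim_env(es, "2018-01-01", "2019-12-31")
  # occupancy proportion as a noisy monotone function of imputed chl-a
  chla <- impute_chla(env$chla_mg_m3)$value
  withr::with_seed(21, {
    prop <- plogis(scale(chla)[, 1] * 2 + rnorm(length(chla), sd = 0.4))
  })
  comp <- dplyr::tibble(composite_start = env$composite_start,
                        proportion = prop)
  out <- build_model_table(list(GS = comp), list(GS = env))
  expect_identical(nrow(out$table), nrow(comp))
  rho_chla <- out$spearman |>
    dplyr::filter(site == "GS", covariate == "chla_mg_m3")
  expect_gt(rho_chla$rho, 0)
  expect_lt(rho_chla$p_value, 0.05)
  # permuted covariate: association collapses
  env_perm <- env
  withr::with_seed(22, {
    env_perm$chla_mg_m3 <- sample(env$chla_mg_m3)
  })
  out_perm <- build_model_table(list(GS = comp), list(GS = env_perm))
  rho_perm <- out_perm$spearman |>
    dplyr::filter(site == "GS", covariate == "chla_mg_m3")
  expect_lt(abs(rho_perm$rho), abs(rho_chla$rho))
})
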
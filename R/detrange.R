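#' Sonar-equation primitives
#'
#' The passive sonar equation for a recorder: the received level of a
#' vocalization is the source level minus the propagation loss,
#' `RL = SL - PL`, and a call is detectable when the received level meets
#' the noise level plus the detection threshold in the same band,
#' `RL >= NL + DT` (equality detects).
#'
#' @param sl Source level, dB re 1 uPa at 1 m.
#' @param pl Propagation loss, dB re 1 m.
#' @param rl Received level, dB re 1 uPa.
#' @param nl Ambient noise level in the call's band, dB re 1 uPa.
#' @param dt Detection threshold (signal excess required by the detector,
#'   not the animal's hearing), dB.
#' @return `received_level()`: RL in dB; `is_detectable()`: logical.
#' @export
received_level <- function(sl, pl) sl - pl

#' @rdname received_level
#' @export
is_detectable <- function(rl, nl, dt = 0) rl >= nl + dt

#' Thorp volume absorption coefficient
#'
#' Classic Thorp seawater absorption, dB/km, as a function of frequency.
#'
#' @param frequency Hz.
#' @return Absorption, dB/km.
#' @export
thorp_absorption <- function(frequency) {
  f <- frequency / 1000  # kHz
  0.1 * f^2 / (1 + f^2) + 40 * f^2 / (4100 + f^2) + 2.75e-4 * f^2 + 0.003
}

#' Geometric spreading + absorption propagation-loss model
#'
#' A pluggable stand-in for full acoustic propagation modelling:
#' `PL = N log10(r) + alpha(f) r / 1000` with `N = 20` (spherical),
#' `N = 10` (cylindrical), or spherical out to a transition range and
#' cylindrical beyond (`20 log10(r_t) + 10 log10(r / r_t)`), plus Thorp
#' absorption. Depth- and azimuth-independent (one radial).
#'
#' @param spreading `"spherical"`, `"cylindrical"` or `"hybrid"`.
#' @param transition_range_m Transition range for `"hybrid"`, m.
#' @param max_range_m Largest range the model is valid to, m.
#' @param absorption `"thorp"` (default) or `"none"` for pure geometric
#'   spreading (absorption is negligible below ~100 Hz anyway).
#' @return A `pl_model`: list with `evaluate(frequency, source_depth,
#'   range_m, radial)`, `n_radials` and `max_range_m`.
#' @export
#' @examples
#' m <- pl_geometric("spherical", absorption = "none")
#' m$evaluate(100, 10, 1000)  # 60 dB
pl_geometric <- function(spreading = c("spherical", "cylindrical", "hybrid"),
                         transition_range_m = 1000, max_range_m = Inf,
                         absorption = c("thorp", "none")) {
  spreading <- match.arg(spreading)
  absorption <- match.arg(absorption)
  evaluate <- function(frequency, source_depth, range_m, radial = 1L) {
    if (any(range_m < 1)) abort("range must be >= 1 m")
    geo <- switch(spreading,
      spherical = 20 * log10(range_m),
      cylindrical = 10 * log10(range_m),
      hybrid = ifelse(range_m <= transition_range_m,
                      20 * log10(range_m),
                      20 * log10(transition_range_m) +
                        10 * log10(range_m / transition_range_m))
    )
    alpha <- if (absorption == "thorp") thorp_absorption(frequency) else 0
    geo + alpha * range_m / 1000
  }
  structure(
    list(evaluate = evaluate, n_radials = 1L, max_range_m = max_range_m),
    class = "pl_model"
  )
}

#' Propagation-loss model from an externally computed grid
#'
#' Reads a CSV of modelled propagation loss (columns `radial`, `frequency`,
#' `source_depth`, `range_m`, `pl_db`) — e.g. output of a parabolic-equation
#' or ray-trace run — and wraps it as a `pl_model` interpolating bilinearly
#' in (source depth, range), nearest in frequency, exact in radial.
#' Queries outside the grid error.
#'
#' @param file CSV path.
#' @return A `pl_model`.
#' @export
load_pl_grid <- function(file) {
  g <- utils::read.csv(file)
  need <- c("radial", "frequency", "source_depth", "range_m", "pl_db")
  if (!all(need %in% names(g))) abort("malformed PL grid: missing columns")
  if (anyNA(g[need])) abort("malformed PL grid: missing values")
  radials <- sort(unique(g$radial))
  freqs <- sort(unique(g$frequency))
  depths <- sort(unique(g$source_depth))
  ranges <- sort(unique(g$range_m))
  if (any(diff(ranges) <= 0)) abort("non-monotone range axis")
  # cube lookup per radial/frequency: depth x range matrix
  key <- function(rad, f) paste(rad, f, sep = "|")
  cubes <- list()
  for (rad in radials) for (f in freqs) {
    sub <- g[g$radial == rad & g$frequency == f, ]
    m <- matrix(NA_real_, length(depths), length(ranges))
    m[cbind(match(sub$source_depth, depths), match(sub$range_m, ranges))] <- sub$pl_db
    if (anyNA(m)) abort("malformed PL grid: incomplete depth x range block")
    cubes[[key(rad, f)]] <- m
  }
  evaluate <- function(frequency, source_depth, range_m, radial = 1L) {
    if (!radial %in% radials) abort("unknown radial")
    f <- freqs[which.min(abs(freqs - frequency))]
    m <- cubes[[key(radial, f)]]
    if (any(source_depth < depths[1] | source_depth > depths[length(depths)]) ||
        any(range_m < ranges[1] | range_m > ranges[length(ranges)])) {
      abort("query outside the PL grid domain")
    }
    di <- pmin(findInterval(source_depth, depths), length(depths) - 1L)
    ri <- pmin(findInterval(range_m, ranges), length(ranges) - 1L)
    if (length(depths) == 1L) di <- 1L
    wd <- if (length(depths) > 1) {
      (source_depth - depths[di]) / (depths[di + 1L] - depths[di])
    } else 0
    wr <- (range_m - ranges[ri]) / (ranges[ri + 1L] - ranges[ri])
    if (length(depths) > 1) {
      (1 - wd) * ((1 - wr) * m[cbind(di, ri)] + wr * m[cbind(di, ri + 1L)]) +
        wd * ((1 - wr) * m[cbind(di + 1L, ri)] + wr * m[cbind(di + 1L, ri + 1L)])
    } else {
      (1 - wr) * m[cbind(di, ri)] + wr * m[cbind(di, ri + 1L)]
    }
  }
  structure(
    list(evaluate = evaluate, n_radials = length(radials),
         max_range_m = max(ranges)),
    class = "pl_model"
  )
}

#' Deterministic detection range for one draw
#'
#' The largest grid range at which a call of the given source level and
#' depth is detectable above the noise level: the outermost grid point
#' where `SL - PL >= NL + DT`, or 0 when none is. PL is evaluated at the
#' band's geometric-center frequency. The outermost-point convention keeps
#' detectable shadow-zone rebounds under non-monotone PL.
#'
#' @inheritParams received_level
#' @param source_depth Calling depth, m.
#' @param band [freq_band()] of the call.
#' @param pl_model A `pl_model`.
#' @param radial Radial index.
#' @param range_grid Increasing vector of ranges, m (non-empty).
#' @return Range, m.
#' @export
detection_range_single <- function(sl, source_depth, nl, band, pl_model,
                                   radial = 1L,
                                   range_grid = seq(10, 100000, by = 10),
                                   dt = 0) {
  if (length(range_grid) == 0L) abort("empty range grid")
  f <- band_center(band)
  pl <- pl_model$evaluate(f, source_depth, range_grid, radial)
  ok <- is_detectable(received_level(sl, pl), nl, dt)
  if (!any(ok)) 0 else range_grid[max(which(ok))]
}

#' Final detection range across frequency bands
#'
#' `R_max = max_f R(f)`: the per-call detection range is the maximum of the
#' per-band ranges; exact ties report the lower-frequency band.
#'
#' @param band_ranges Tibble with columns `f_lo`, `f_hi`, `range_m`.
#' @return A one-row tibble: `r_max_m`, `f_lo`, `f_hi`.
#' @export
rmax_over_bands <- function(band_ranges) {
  if (nrow(band_ranges) == 0L) abort("need at least one band")
  br <- band_ranges |> arrange(.data$f_lo)
  i <- which.max(br$range_m)  # first max = lowest frequency on ties
  tibble(r_max_m = br$range_m[i], f_lo = br$f_lo[i], f_hi = br$f_hi[i])
}

#' Monte Carlo configuration for detection-range estimation
#'
#' @param n_iterations Monte Carlo iterations (default 10000); each samples
#'   one noise-level minute.
#' @param n_sl_draws Normal source-level draws per iteration (default 100).
#' @param n_depth_draws Depth draws per iteration from the calling-depth
#'   distribution (default 100).
#' @param dt Detection threshold, dB (default 0).
#' @param probability_levels Detection-probability levels for percentile
#'   ranges (default 0.1, 0.5, 0.9).
#' @param max_range_m,range_step_m Range grid (default 10 m steps to
#'   100 km).
#' @param seed Integer seed.
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_iterations = 10000, n_sl_draws = 100,
                      n_depth_draws = 100, dt = 0,
                      probability_levels = c(0.1, 0.5, 0.9),
                      max_range_m = 100000, range_step_m = 10, seed = 1L) {
  if (n_iterations <= 0 || n_sl_draws <= 0 || n_depth_draws <= 0) {
    abort("draw counts must be > 0")
  }
  if (any(probability_levels <= 0 | probability_levels >= 1)) {
    abort("probability levels must be in (0, 1)")
  }
  list(n_iterations = as.integer(n_iterations),
       n_sl_draws = as.integer(n_sl_draws),
       n_depth_draws = as.integer(n_depth_draws), dt = dt,
       probability_levels = probability_levels,
       max_range_m = max_range_m, range_step_m = range_step_m,
       seed = as.integer(seed))
}

#' Source-level distribution of a vocalization
#'
#' @param mean,sd Normal source-level mean and sd, dB re 1 uPa at 1 m
#'   (`sd >= 0`).
#' @param band [freq_band()] of the vocalization.
#' @return An `sl_spec` list.
#' @export
sl_spec <- function(mean, sd, band) {
  if (sd < 0) abort("sd must be >= 0")
  structure(list(mean = mean, sd = sd, band = band), class = "sl_spec")
}

#' Discrete calling-depth distribution
#'
#' @param depth_m Support depths, m (> 0, positive down).
#' @param weight Probabilities (normalized to sum to 1).
#' @return A `depth_dist` list.
#' @export
depth_dist <- function(depth_m, weight = rep(1, length(depth_m))) {
  if (length(depth_m) == 0L) abort("empty depth support")
  if (any(depth_m <= 0)) abort("depths must be > 0")
  if (any(weight < 0) || sum(weight) <= 0) abort("invalid weights")
  structure(list(depth_m = depth_m, weight = weight / sum(weight)),
            class = "depth_dist")
}

#' Monte Carlo detection-range estimation
#'
#' Propagates source-level, calling-depth and minute-to-minute noise-level
#' variability into a detection-probability-versus-range curve: each
#' iteration samples one noise-level minute, `n_sl_draws` Normal source
#' levels and `n_depth_draws` depths; the probability of detection at a
#' grid range is the fraction of all (SL, depth, NL) draws detectable
#' there (full SL x depth cross within an iteration, pooled over
#' iterations), and the percentile range `R_P` is the largest grid range
#' whose probability is at least `P` — so lower levels give the larger,
#' more permissive ranges (`R_0.1 >= R_0.5 >= R_0.9`). Draws are seeded and
#' the per-iteration order (NL, then SLs, then depths) is fixed, so a
#' brute-force replay of the RNG stream reproduces the result exactly.
#'
#' @param nl_series Numeric vector of per-minute band noise levels, dB re
#'   1 uPa (non-empty), or a data frame with an `nl_db` column.
#' @param sl An [sl_spec()].
#' @param depths A [depth_dist()].
#' @param pl_model A `pl_model`.
#' @param config An [mc_config()].
#' @return A `detection_range_result`: list with `prob_curve` (tibble
#'   `radial`, `range_m`, `probability`), `percentile_ranges` (tibble
#'   `radial`, `level`, `range_m`), `band`, `n_draws`, `config`.
#' @export
monte_carlo_detection <- function(nl_series, sl, depths, pl_model,
                                  config = mc_config()) {
  if (is.data.frame(nl_series)) nl_series <- nl_series$nl_db
  nl_series <- nl_series[!is.na(nl_series)]
  if (length(nl_series) == 0L) abort("empty noise-level series")
  stopifnot(inherits(sl, "sl_spec"), inherits(depths, "depth_dist"))
  f <- band_center(sl$band)
  max_r <- min(config$max_range_m, pl_model$max_range_m)
  grid <- seq(config$range_step_m, max_r, by = config$range_step_m)
  n_sup <- length(depths$depth_m)
  n_it <- config$n_iterations
  # sample all iterations: NL minute, SL draws, depth draws (fixed order)
  excess <- matrix(NA_real_, n_it, config$n_sl_draws)
  dcount <- matrix(0L, n_it, n_sup)
  withr::with_seed(config$seed, {
    for (i in seq_len(n_it)) {
      nl_i <- nl_series[[sample.int(length(nl_series), 1L)]]
      sl_i <- rnorm(config$n_sl_draws, sl$mean, sl$sd)
      d_i <- sample.int(n_sup, config$n_depth_draws, replace = TRUE,
                        prob = depths$weight)
      excess[i, ] <- sl_i - nl_i - config$dt
      dcount[i, ] <- tabulate(d_i, nbins = n_sup)
    }
  })
  e_flat <- as.vector(t(excess))                  # iteration-major, SLs contiguous
  ord <- order(e_flat)
  e_sorted <- e_flat[ord]
  total_draws <- n_it * config$n_sl_draws * config$n_depth_draws
  curves <- purrr::map_dfr(seq_len(pl_model$n_radials), function(rad) {
    detect_w <- numeric(length(grid))
    for (j in seq_len(n_sup)) {
      w_j <- rep(dcount[, j], each = config$n_sl_draws)[ord]
      cw <- cumsum(w_j)
      w_tot <- cw[length(cw)]
      if (w_tot == 0) next
      pl_j <- pl_model$evaluate(f, depths$depth_m[j], grid, rad)
      below <- findInterval(pl_j, e_sorted, left.open = TRUE)  # draws with E < PL
      detect_w <- detect_w + (w_tot - ifelse(below > 0, cw[pmax(below, 1L)], 0))
    }
    tibble(radial = rad, range_m = grid, probability = detect_w / total_draws)
  })
  range_at_levels <- function(range_m, probability, levels) {
    vapply(levels, function(p) {
      ok <- which(probability >= p)
      if (length(ok) == 0L) 0 else range_m[max(ok)]
    }, numeric(1))
  }
  pct <- curves |>
    group_by(.data$radial) |>
    reframe(
      level = config$probability_levels,
      range_m = range_at_levels(.data$range_m, .data$probability,
                                config$probability_levels)
    )
  structure(
    list(prob_curve = curves, percentile_ranges = pct, band = sl$band,
         n_draws = total_draws, config = config),
    class = "detection_range_result"
  )
}

#' @export
print.detection_range_result <- function(x, ...) {
  cat(sprintf("<detection_range_result> band %g-%g Hz, %s draws\n",
              x$band$f_lo, x$band$f_hi, format(x$n_draws, big.mark = ",")))
  print(as.data.frame(x$percentile_ranges))
  invisible(x)
}
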
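#' Frequency band
#'
#' @param f_lo,f_hi Band edges, Hz; `0 <= f_lo < f_hi`. Band integration is
#'   lower-inclusive, upper-exclusive on PSD bin centers.
#' @return A `freq_band` object.
#' @export
#' @examples
#' decaband_10_100 <- freq_band(10, 100)
#' decaband_20_40 <- freq_band(20, 40)
freq_band <- function(f_lo, f_hi) {
  if (!(f_lo >= 0 && f_lo < f_hi)) abort("need 0 <= f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "freq_band")
}

#' @export
print.freq_band <- function(x, ...) {
  cat(sprintf("<freq_band> %g-%g Hz\n", x$f_lo, x$f_hi)); invisible(x)
}

band_center <- function(band) sqrt(band$f_lo * band$f_hi)

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' One-minute averaged power spectral density
#'
#' Welch-style averaged PSD on a fixed 1-minute grid: each 60-s frame is cut
#' into 1-s Hamming-windowed segments hopped by 0.5 s, every segment whose
#' start lies inside the frame is used (the final, half-covered segment is
#' zero-padded), giving 120 averaged one-sided periodograms per full frame.
#' Normalization is such that the integrated PSD of white noise equals its
#' variance (Parseval), so levels are dB re 1 uPa^2/Hz at 1-Hz resolution.
#'
#' Frames shorter than 60 s at the end of a recording are computed from the
#' segments available and carry a reduced `n_averages`.
#'
#' @param wave A [cal_wave()] of at least 1 s.
#' @return A `psd_matrix`: list with `frame_times` (UTC, 1-min cadence),
#'   `frequencies` (Hz bin centers), `levels` (frames x frequencies, dB re
#'   1 uPa^2/Hz), `n_averages` and `contamination_flags` per frame. Convert
#'   to a long tibble with `as_tibble()`.
#' @export
compute_minute_psd <- function(wave) {
  stopifnot(inherits(wave, "cal_wave"))
  fs <- round(wave$sample_rate)
  if (fs < 2) abort("sample_rate must be >= 2 Hz")
  x <- wave$samples
  if (length(x) < fs) abort("need at least 1 s of data")
  nwin <- fs
  hop <- fs / 2
  w <- hamming_win(nwin)
  wpow <- sum(w^2)
  n_frames <- ceiling(length(x) / (60 * fs))
  nfreq <- floor(nwin / 2) + 1L
  levels <- matrix(NA_real_, n_frames, nfreq)
  n_avg <- integer(n_frames)
  for (fr in seq_len(n_frames)) {
    f0 <- (fr - 1L) * 60L * fs
    frame_len <- min(60L * fs, length(x) - f0)
    if (frame_len < 1L) break
    starts <- seq(0L, frame_len - 1L, by = hop)
    starts <- starts[starts < frame_len]
    acc <- numeric(nfreq)
    for (s in starts) {
      seg_len <- min(nwin, frame_len - s)
      seg <- x[(f0 + s + 1L):(f0 + s + seg_len)]
      if (seg_len < nwin) seg <- c(seg, numeric(nwin - seg_len))
      X <- fft(w * seg)[seq_len(nfreq)]
      p <- (Mod(X)^2) / (fs * wpow)
      # one-sided: double all bins except DC (and Nyquist when nwin even)
      dbl <- rep(2, nfreq); dbl[1] <- 1
      if (nwin %% 2L == 0L) dbl[nfreq] <- 1
      acc <- acc + p * dbl
    }
    levels[fr, ] <- 10 * log10(pmax(acc / length(starts), .Machine$double.xmin))
    n_avg[fr] <- length(starts)
  }
  structure(
    list(
      frame_times = wave$start_time + (seq_len(n_frames) - 1) * 60,
      frequencies = (seq_len(nfreq) - 1) * fs / nwin,
      levels = levels,
      n_averages = n_avg,
      contamination_flags = rep(FALSE, n_frames)
    ),
    class = "psd_matrix"
  )
}

#' @export
print.psd_matrix <- function(x, ...) {
  cat(sprintf(
    "<psd_matrix> %d frame(s) x %d bins (%g-%g Hz), n_averages %s\n",
    length(x$frame_times), length(x$frequencies),
    min(x$frequencies), max(x$frequencies),
    paste(unique(x$n_averages), collapse = "/")
  ))
  invisible(x)
}

#' @method as_tibble psd_matrix
#' @export
as_tibble.psd_matrix <- function(x, ...) {
  tidyr::expand_grid(
    frame_time = x$frame_times,
    frequency = x$frequencies
  ) |>
    mutate(psd_db = as.vector(t(x$levels)))
}

band_bins <- function(psd, band) {
  idx <- which(psd$frequencies >= band$f_lo & psd$frequencies < band$f_hi)
  if (length(idx) == 0L) abort("band contains no PSD bins")
  if (band$f_hi > max(psd$frequencies) + diff(psd$frequencies[1:2]) / 2 + 1e-9) {
    abort("band extends beyond the PSD frequency extent")
  }
  idx
}

#' Band-limited sound pressure level from a PSD
#'
#' Integrates linear-domain PSD over bins with `f_lo <= f < f_hi` and
#' returns `10 log10(sum PSD(f) df)` per frame, dB re 1 uPa.
#'
#' @param psd A `psd_matrix`.
#' @param band A [freq_band()] inside the PSD frequency extent.
#' @return A tibble with `frame_time` and `spl_db`.
#' @export
band_spl <- function(psd, band) {
  idx <- band_bins(psd, band)
  df <- diff(psd$frequencies[1:2])
  lin <- 10^(psd$levels[, idx, drop = FALSE] / 10)
  tibble(
    frame_time = psd$frame_times,
    spl_db = 10 * log10(rowSums(lin) * df)
  )
}

#' Root-mean-square sound pressure level
#'
#' For a waveform, `20 log10(rms pressure / 1 uPa)`. For a `psd_matrix`, the
#' band-integrated level (broadband by default), which agrees with the
#' time-domain value to within windowing tolerance.
#'
#' @param x A [cal_wave()] or `psd_matrix`.
#' @param band Optional [freq_band()] restricting the PSD-domain variant.
#' @return A single dB value for waveforms; a per-frame tibble for PSDs.
#' @export
rms_spl <- function(x, band = NULL) {
  if (inherits(x, "cal_wave")) {
    if (length(x$samples) == 0L) abort("empty input")
    if (!is.null(band)) {
      ny <- x$sample_rate / 2
      lo <- max(band$f_lo, 0) / ny
      hi <- min(band$f_hi, ny * 0.999) / ny
      bf <- signal::butter(4, c(max(lo, 1e-6), hi), type = "pass")
      x <- cal_wave(as.numeric(signal::filtfilt(bf, x$samples)),
                    x$sample_rate, x$start_time)
    }
    return(20 * log10(sqrt(mean(x$samples^2))))
  }
  if (inherits(x, "psd_matrix")) {
    band <- band %||%
      freq_band(0, max(x$frequencies) + diff(x$frequencies[1:2]) / 2)
    return(band_spl(x, band))
  }
  abort("`x` must be a cal_wave or psd_matrix")
}

#' Long-term spectral average
#'
#' Averages PSD frames into coarser time bins in the linear domain and
#' returns the grid in dB. Cells with no frames are missing.
#'
#' @param psd A `psd_matrix`.
#' @param time_bin Bin width, s; at least the 60-s frame cadence.
#' @return A long tibble (`bin_start`, `frequency`, `psd_db`, `n_frames`).
#' @export
assemble_ltsa <- function(psd, time_bin = 3600) {
  if (time_bin < 60) abort("time_bin must be >= the 1-min frame cadence")
  t0 <- min(psd$frame_times)
  bin_idx <- floor(as.numeric(difftime(psd$frame_times, t0, units = "secs")) / time_bin)
  tibble(
    bin_start = t0 + bin_idx * time_bin,
    frame = seq_along(psd$frame_times)
  ) |>
    group_by(.data$bin_start) |>
    reframe(
      frequency = psd$frequencies,
      psd_db = 10 * log10(colMeans(10^(psd$levels[.data$frame, , drop = FALSE] / 10))),
      n_frames = length(.data$frame)
    )
}

#' Band SPL elevation above a percentile baseline
#'
#' Quantifies how far a band SPL series rises above its quiet baseline,
#' e.g. the seasonal rise of a 20-40 Hz decaband when fin whale choruses
#' are present. The baseline is a low percentile of the series.
#'
#' @param spl_db Numeric per-frame band SPL series (dB); `NA`s allowed.
#' @param baseline_percentile Percentile used as baseline (default 10).
#' @return A list with `elevation_db` (series minus baseline) and
#'   `max_elevation_db`.
#' @export
band_elevation <- function(spl_db, baseline_percentile = 10) {
  if (all(is.na(spl_db))) abort("all-missing series")
  base <- quantile(spl_db, baseline_percentile / 100, na.rm = TRUE, names = FALSE)
  elev <- spl_db - base
  list(elevation_db = elev, max_elevation_db = max(elev, na.rm = TRUE))
}

#' Flag noise-contaminated PSD frames
#'
#' Marks frames whose band SPL exceeds the deployment median band SPL by
#' more than a threshold — a simple screen for mooring/flow-noise
#' contamination of low-frequency bands.
#'
#' @param psd A `psd_matrix`.
#' @param band Band screened, default 10-200 Hz.
#' @param threshold_db_above_median Trigger threshold, dB above the median.
#' @return The `psd_matrix` with `contamination_flags` set.
#' @export
flag_contamination <- function(psd, band = freq_band(10, 200),
                               threshold_db_above_median = 10) {
  spl <- band_spl(psd, band)$spl_db
  med <- median(spl, na.rm = TRUE)
  psd$contamination_flags <- !is.na(spl) & spl > med + threshold_db_above_median
  psd
}
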
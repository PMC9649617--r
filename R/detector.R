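#' Band-energy event detector
#'
#' A minimal, documented detector used to turn audio into event streams for
#' end-to-end exercises: the waveform is band-pass filtered, framed, and a
#' frame triggers when its in-band SPL exceeds a running-median background
#' estimate by the SNR threshold. Adjacent triggered frames merge into one
#' event reported at the peak frame. This is a deliberately simple stand-in
#' for the proprietary per-species detectors used operationally.
#'
#' @param wave A [cal_wave()].
#' @param band [freq_band()] of the target signal (below Nyquist).
#' @param frame_s Frame length, s (> 0; default 1).
#' @param snr_threshold Trigger threshold, dB above background (may be
#'   `-Inf`, in which case every frame triggers and merges to one event).
#' @param background_frames Running-median window, frames (default 60; made
#'   odd internally).
#' @param class_label Label written on the events.
#' @return A detection-event tibble: `time` (POSIXct UTC, frame start),
#'   `time_s` (s from recording start), `class`, `score_db` (SNR above
#'   background at the peak frame), `validated` (`FALSE`).
#' @export
band_energy_detect <- function(wave, band, frame_s = 1, snr_threshold = 10,
                               background_frames = 60, class_label = "event") {
  stopifnot(inherits(wave, "cal_wave"))
  if (length(wave$samples) == 0L) abort("empty series")
  if (frame_s <= 0) abort("frame_s must be > 0")
  fs <- wave$sample_rate
  if (band$f_hi > fs / 2) abort("band above Nyquist")
  bf <- signal::butter(4, c(max(band$f_lo, 1e-6), band$f_hi * 0.999) / (fs / 2),
                       type = "pass")
  xb <- as.numeric(signal::filtfilt(bf, wave$samples))
  spf <- round(frame_s * fs)
  n_frames <- floor(length(xb) / spf)
  if (n_frames < 1L) abort("series shorter than one frame")
  frames <- matrix(xb[seq_len(n_frames * spf)], nrow = spf)
  spl <- 10 * log10(pmax(colMeans(frames^2), .Machine$double.xmin))
  k <- min(background_frames, n_frames)
  if (k %% 2L == 0L) k <- k - 1L
  bg <- if (k >= 3) as.numeric(runmed(spl, k, endrule = "median")) else rep(median(spl), n_frames)
  score <- spl - bg
  trig <- score >= snr_threshold
  if (!any(trig)) {
    return(tibble(time = wave$start_time[0], time_s = numeric(0),
                  class = character(0), score_db = numeric(0),
                  validated = logical(0)))
  }
  runs <- rle(trig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- purrr::map_int(which(runs$values), function(r) {
    idx <- starts[r]:ends[r]
    idx[which.max(score[idx])]
  })
  tibble(
    time = wave$start_time + (peaks - 1L) * frame_s,
    time_s = (peaks - 1L) * frame_s,
    class = class_label,
    score_db = score[peaks],
    validated = FALSE
  )
}

#' Precision and recall against a ground-truth log
#'
#' Greedy earliest-first one-to-one matching of detected events to truth
#' entries by time: truths are visited in time order and each takes the
#' earliest unmatched event within the tolerance.
#'
#' @param events Detection-event tibble with a `time_s` column (s).
#' @param truth Truth tibble with a `time_s` column.
#' @param tolerance_s Match tolerance, s (>= 0).
#' @return A one-row tibble: `n_events`, `n_truth`, `n_matched`,
#'   `precision` (`NA` when there are no events), `recall` (`NA` when there
#'   is no truth).
#' @export
detector_performance <- function(events, truth, tolerance_s = 1) {
  if (tolerance_s < 0) abort("tolerance_s must be >= 0")
  ev <- sort(events$time_s)
  tr <- sort(truth$time_s)
  used <- rep(FALSE, length(ev))
  matched <- 0L
  for (t in tr) {
    cand <- which(!used & abs(ev - t) <= tolerance_s)
    if (length(cand) > 0) {
      used[cand[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  tibble(
    n_events = length(ev), n_truth = length(tr), n_matched = matched,
    precision = if (length(ev) > 0) matched / length(ev) else NA_real_,
    recall = if (length(tr) > 0) matched / length(tr) else NA_real_
  )
}
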
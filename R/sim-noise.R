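#' Shaped ambient-noise specification
#'
#' Describes synthetic ambient noise as a target one-sided PSD curve plus
#' optional low-frequency "mooring noise" contamination windows (extra
#' band-limited energy during tidal-current periods).
#'
#' @param target_psd_curve Data frame with columns `frequency` (Hz, strictly
#'   increasing) and `psd_db` (dB re 1 uPa^2/Hz, finite or `-Inf` for
#'   silence).
#' @param contamination_windows Optional data frame with columns `start_s`,
#'   `end_s`, `extra_db`, `f_lo`, `f_hi`: windows whose band level is raised
#'   by `extra_db` above the target.
#' @param seed Integer seed; identical spec and seed give identical samples.
#' @return A `noise_spec` object.
#' @export
#' @examples
#' spec <- noise_spec(data.frame(frequency = c(5, 100), psd_db = c(60, 60)))
#' w <- sim_ambient(spec, duration = 2, sample_rate = 512)
noise_spec <- function(target_psd_curve, contamination_windows = NULL, seed = 1L) {
  curve <- as_tibble(target_psd_curve)
  stopifnot(all(c("frequency", "psd_db") %in% names(curve)))
  if (any(diff(curve$frequency) <= 0)) abort("frequencies must be strictly increasing")
  if (any(is.na(curve$psd_db)) || any(curve$psd_db == Inf)) {
    abort("levels must be finite or -Inf")
  }
  if (!is.null(contamination_windows)) {
    contamination_windows <- as_tibble(contamination_windows)
    stopifnot(all(c("start_s", "end_s", "extra_db", "f_lo", "f_hi") %in%
                    names(contamination_windows)))
  }
  structure(
    list(target_psd_curve = curve,
         contamination_windows = contamination_windows,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

# target curve interpolated (dB, end levels held) at arbitrary frequencies
interp_curve_db <- function(curve, freq) {
  approx(curve$frequency, curve$psd_db, xout = freq, rule = 2)$y
}

#' Simulate shaped Gaussian ambient noise
#'
#' Filters white Gaussian noise with an FIR filter (designed with
#' `signal::fir2`) whose magnitude response follows the spec's target PSD
#' curve, so the measured 1-min PSD of the output matches the target; the
#' Parseval identity between time-domain variance and integrated PSD is the
#' test oracle. Contamination windows receive additional band-passed noise
#' sized so the window's band PSD sits `extra_db` above the target.
#'
#' @param spec A [noise_spec()].
#' @param duration Seconds of audio, > 0.
#' @param sample_rate Hz; must exceed twice the highest curve frequency.
#' @param start_time UTC start of the series.
#' @return A [cal_wave()] in uPa.
#' @export
sim_ambient <- function(spec, duration, sample_rate,
                        start_time = lubridate::ymd_hms("2000-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(spec, "noise_spec"))
  if (duration <= 0) abort("duration must be > 0")
  fmax <- max(spec$target_psd_curve$frequency)
  if (sample_rate <= 2 * fmax) abort("sample_rate must exceed 2 x max curve frequency")
  fs <- sample_rate
  n <- round(duration * fs)
  if (all(spec$target_psd_curve$psd_db == -Inf)) {
    return(cal_wave(numeric(n), fs, start_time))
  }
  withr::with_seed(spec$seed, {
    ntaps <- max(256L, min(4096L, as.integer(2^floor(log2(fs)))))
    fgrid <- seq(0, 1, length.out = 257)
    s_db <- interp_curve_db(spec$target_psd_curve, fgrid * fs / 2)
    mag <- sqrt(10^(s_db / 10) * fs / 2)   # white input has one-sided PSD 2/fs
    h <- signal::fir2(ntaps, fgrid, mag)
    x <- rnorm(n + ntaps)
    y <- signal::fftfilt(h, x)[(ntaps + 1):(n + ntaps)]
    if (!is.null(spec$contamination_windows)) {
      for (k in seq_len(nrow(spec$contamination_windows))) {
        cw <- spec$contamination_windows[k, ]
        if (cw$start_s < 0 || cw$end_s > duration || cw$end_s <= cw$start_s) {
          abort("contamination window outside generated duration")
        }
        i0 <- floor(cw$start_s * fs) + 1L
        i1 <- min(n, ceiling(cw$end_s * fs))
        fc <- sqrt(cw$f_lo * cw$f_hi)
        s_band <- 10^(interp_curve_db(spec$target_psd_curve, fc) / 10)
        s_add <- s_band * (10^(cw$extra_db / 10) - 1)
        bf <- signal::butter(4, c(cw$f_lo, cw$f_hi) / (fs / 2), type = "pass")
        z <- rnorm(i1 - i0 + 1L, sd = sqrt(s_add * fs / 2))
        y[i0:i1] <- y[i0:i1] + as.numeric(signal::filter(bf, z))
      }
    }
    cal_wave(y, fs, start_time)
  })
}

#' Synthetic call template
#'
#' Parametric stand-ins for the main mysticete/odontocete call shapes used
#' when exercising the detector: a linear tonal sweep (e.g. a fin whale
#' 20-Hz pulse), a harmonic stack (e.g. a blue whale B call whose third
#' harmonic near 38-55 Hz dominates), and an exponentially damped broadband
#' click. These are signal-processing stand-ins, not acoustic replicas of
#' real vocalizations.
#'
#' @param class_label Label carried into truth logs (e.g. `"fin_20Hz"`).
#' @param band [freq_band()] the call occupies (must be below Nyquist at
#'   render time).
#' @param duration Call duration, s (> 0).
#' @param shape One of `"tonal_sweep"`, `"harmonic_stack"`,
#'   `"transient_click"`.
#' @param f_start,f_end Sweep start/end frequency, Hz (tonal shapes).
#' @param harmonic_weights Relative amplitudes of harmonics 1..K
#'   (`harmonic_stack`).
#' @param decay_s Exponential decay constant, s (`transient_click`).
#' @return A `call_template` object.
#' @export
#' @examples
#' fin <- call_template("fin_20Hz", freq_band(15, 28), 1,
#'   shape = "tonal_sweep", f_start = 23, f_end = 18)
call_template <- function(class_label, band, duration,
                          shape = c("tonal_sweep", "harmonic_stack", "transient_click"),
                          f_start = band$f_lo, f_end = band$f_hi,
                          harmonic_weights = 1, decay_s = duration / 5) {
  shape <- match.arg(shape)
  if (duration <= 0) abort("duration must be > 0")
  structure(
    list(class_label = class_label, band = band, duration = duration,
         shape = shape, f_start = f_start, f_end = f_end,
         harmonic_weights = harmonic_weights, decay_s = decay_s),
    class = "call_template"
  )
}

#' Render a call template to a unit-RMS waveform
#'
#' @param template A [call_template()].
#' @param sample_rate Hz; the template band must lie below Nyquist.
#' @return Numeric waveform of length `duration * sample_rate`, RMS 1.
#' @export
render_template <- function(template, sample_rate) {
  if (template$band$f_hi > sample_rate / 2) abort("template band above Nyquist")
  fs <- sample_rate
  n <- max(2L, round(template$duration * fs))
  t <- (seq_len(n) - 1) / fs
  dur <- template$duration
  y <- switch(template$shape,
    tonal_sweep = {
      phase <- 2 * pi * (template$f_start * t +
                           (template$f_end - template$f_start) * t^2 / (2 * dur))
      sin(phase) * sin(pi * t / dur)^2   # Hann^1 envelope, zero at ends
    },
    harmonic_stack = {
      w <- template$harmonic_weights
      inst <- template$f_start + (template$f_end - template$f_start) * t / dur
      ph <- 2 * pi * cumsum(inst) / fs
      rowSums(vapply(seq_along(w), function(k) w[k] * sin(k * ph),
                     numeric(n))) * sin(pi * t / dur)^2
    },
    transient_click = {
      fc <- band_center(template$band)
      exp(-t / template$decay_s) * sin(2 * pi * fc * t)
    }
  )
  y / sqrt(mean(y^2))
}

#' Inject scaled call templates into a background recording
#'
#' Adds copies of a rendered template at the requested times, each scaled so
#' its in-band level exceeds the background's in-band level (measured over
#' the injection window) by `in_band_snr` dB, and returns the mixed waveform
#' together with a ground-truth log.
#'
#' @param background A [cal_wave()].
#' @param template A [call_template()].
#' @param times Injection onset times, s from the start of `background`;
#'   every `time + duration` must fit inside the recording.
#' @param in_band_snr Target in-band SNR, dB.
#' @return A list with `wave` (mixed [cal_wave()]) and `truth` (tibble
#'   `time_utc`, `time_s`, `class`, `snr_db`).
#' @export
inject_calls <- function(background, template, times, in_band_snr = 15) {
  stopifnot(inherits(background, "cal_wave"), inherits(template, "call_template"))
  if (length(times) == 0L) {
    return(list(
      wave = background,
      truth = tibble(time_utc = background$start_time[0], time_s = numeric(0),
                     class = character(0), snr_db = numeric(0))
    ))
  }
  fs <- background$sample_rate
  ext <- duration(background)
  if (any(times < 0 | times + template$duration > ext)) {
    abort("injection extends beyond the background extent")
  }
  tpl <- render_template(template, fs)
  bf <- signal::butter(4, c(max(template$band$f_lo, 1e-6), template$band$f_hi) /
                         (fs / 2), type = "pass")
  y <- background$samples
  for (tt in times) {
    i0 <- round(tt * fs) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    bg_band <- as.numeric(signal::filtfilt(bf, background$samples[idx]))
    rms_bg <- sqrt(mean(bg_band^2))
    y[idx] <- y[idx] + tpl * rms_bg * 10^(in_band_snr / 20)
  }
  list(
    wave = cal_wave(y, fs, background$start_time),
    truth = tibble(
      time_utc = background$start_time + times,
      time_s = as.numeric(times),
      class = template$class_label,
      snr_db = in_band_snr
    )
  )
}
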
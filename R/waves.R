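#' Calibrated pressure time series
#'
#' A lightweight container for a calibrated hydrophone waveform: sound
#' pressure in micropascals (uPa) at a fixed sample rate, anchored to a UTC
#' start time. All soundscape and detector functions consume this object.
#'
#' @param samples Numeric vector of sound pressure, uPa.
#' @param sample_rate Sampling frequency, Hz. Must be positive.
#' @param start_time UTC timestamp of the first sample (`POSIXct`).
#'
#' @return An object of class `cal_wave`: a list with elements `samples`,
#'   `sample_rate` and `start_time`.
#' @export
#' @examples
#' w <- cal_wave(sin(2 * pi * 50 * seq(0, 1, by = 1 / 1000)), 1000)
#' duration(w)
cal_wave <- function(samples, sample_rate,
                     start_time = lubridate::ymd_hms("2000-01-01 00:00:00", tz = "UTC")) {
  if (!is.numeric(samples)) abort("`samples` must be numeric")
  if (anyNA(samples) || any(!is.finite(samples))) abort("`samples` must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = as.numeric(sample_rate),
      start_time = lubridate::with_tz(start_time, "UTC")
    ),
    class = "cal_wave"
  )
}

#' @export
print.cal_wave <- function(x, ...) {
  cat(sprintf(
    "<cal_wave> %d samples @ %g Hz (%.2f s) starting %s UTC\n",
    length(x$samples), x$sample_rate, duration(x),
    format(x$start_time, "%Y-%m-%d %H:%M:%S")
  ))
  invisible(x)
}

#' @rdname cal_wave
#' @param x A `cal_wave`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "cal_wave"))
  length(x$samples) / x$sample_rate
}

#' @method as_tibble cal_wave
#' @export
as_tibble.cal_wave <- function(x, ...) {
  tibble(
    time = x$start_time + (seq_along(x$samples) - 1) / x$sample_rate,
    pressure_upa = x$samples
  )
}

# ---- PCM WAV I/O ------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer for integer PCM, 16- or 24-bit, mono.
# Raw integer counts are returned untouched; calibration to pressure is a
# separate, explicit step (see calibrate_waveform()).

#' Read or write integer PCM WAV files
#'
#' `read_wav()` parses a mono PCM RIFF/WAVE file (16- or 24-bit) and returns
#' the raw integer counts plus the sample rate and bit depth; it performs no
#' calibration. `write_wav()` writes integer counts back out.
#'
#' @param path File path.
#' @return `read_wav()`: a list with `counts` (integer counts), `sample_rate`
#'   and `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file")
  sample_rate <- NULL; bit_depth <- NULL; n_channels <- NULL; counts <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) abort("only integer PCM WAV is supported")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bit_depth <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bit_depth)) abort("malformed WAV: data before fmt chunk")
      if (bit_depth == 16L) {
        counts <- readBin(con, "integer", size %/% 2L, size = 2,
                          signed = TRUE, endian = "little")
      } else if (bit_depth == 24L) {
        raw <- readBin(con, "raw", size)
        n <- length(raw) %/% 3L
        b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        counts <- as.integer(ifelse(v >= 8388608, v - 16777216, v))
      } else {
        abort("unsupported bit depth (16 or 24 only)")
      }
      if (size %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(counts) && !is.null(sample_rate)) break
  }
  if (is.null(counts)) abort("malformed WAV: no data chunk")
  if (!is.null(n_channels) && n_channels != 1L) abort("only mono WAV is supported")
  list(counts = counts, sample_rate = sample_rate, bit_depth = bit_depth)
}

#' @rdname read_wav
#' @param counts Integer sample counts (within the signed range of
#'   `bit_depth`).
#' @param sample_rate Sampling frequency, Hz.
#' @param bit_depth 16 or 24.
#' @export
write_wav <- function(counts, sample_rate, path, bit_depth = 16L) {
  if (!bit_depth %in% c(16L, 24L)) abort("unsupported bit depth (16 or 24 only)")
  counts <- as.integer(round(counts))
  half <- 2^(bit_depth - 1)
  if (any(counts < -half | counts > half - 1)) abort("counts exceed bit depth range")
  bytes_per <- bit_depth %/% 8L
  data_size <- length(counts) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16L) {
    writeBin(counts, con, size = 2, endian = "little")
  } else {
    v <- ifelse(counts < 0, counts + 16777216, counts)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
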
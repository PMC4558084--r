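#' PCG audio signal
#'
#' A `pcg_audio` object is a uniformly sampled single-channel amplitude
#' sequence with its sample rate.  Amplitudes are dimensionless with nominal
#' range \[-1, 1\] (full scale of the recording ADC).
#'
#' @param samples Numeric vector of finite amplitudes, length >= 1.
#' @param sample_rate_hz Positive sampling rate in samples per second.
#'
#' @return A `pcg_audio` object (list with elements `samples` and
#'   `sample_rate_hz`).
#' @examples
#' a <- pcg_audio(sin(2 * pi * 100 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(a)
#' @export
pcg_audio <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) {
    abort_parameter("`samples` must contain at least one value.")
  }
  if (!all(is.finite(samples))) {
    abort_parameter("`samples` must be finite.")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    abort_parameter("`sample_rate_hz` must be a single positive number.")
  }
  structure(
    list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "pcg_audio"
  )
}

#' @export
print.pcg_audio <- function(x, ...) {
  cat(sprintf(
    "<pcg_audio: %d samples @ %g Hz (%.3f s)>\n",
    length(x$samples), x$sample_rate_hz, duration(x)
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#'
#' @param audio A [pcg_audio()] object.
#' @return Duration in seconds.
#' @export
duration <- function(audio) {
  stopifnot(inherits(audio, "pcg_audio"))
  length(audio$samples) / audio$sample_rate_hz
}

#' @export
as_tibble.pcg_audio <- function(x, ...) {
  tibble(
    time_s = (seq_along(x$samples) - 1) / x$sample_rate_hz,
    amplitude = x$samples
  )
}

# ---- WAV I/O --------------------------------------------------------------

read_uint <- function(con, n_bytes) {
  # sizes 1-2 are read unsigned; size 4 must be read signed (R limitation),
  # which is fine for the chunk sizes that occur in practice
  readBin(con, "integer", n = 1L, size = n_bytes, signed = n_bytes >= 4,
          endian = "little")
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE audio.  Integer PCM at 8, 16, 24 or 32 bits and IEEE
#' float at 32 or 64 bits are accepted; multi-channel input is averaged to a
#' single channel (the sensor is a single microphone, so channel averaging
#' gives deterministic behaviour on arbitrary files).  Samples are scaled to
#' \[-1, 1\]; the sample rate is taken from the file header.
#'
#' @param path Path to a WAV file.
#' @return A [pcg_audio()] object.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort_format(sprintf("WAV file not found: %s", path))
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- rawToChar(readBin(con, "raw", 4))
  invisible(read_uint(con, 4))
  wave <- rawToChar(readBin(con, "raw", 4))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_format(sprintf("Not a RIFF/WAVE file: %s", path))
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    chunk_id <- rawToChar(id_raw)
    chunk_size <- read_uint(con, 4)
    if (chunk_id == "fmt ") {
      body <- readBin(con, "raw", chunk_size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        channels     = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
      # WAVE_FORMAT_EXTENSIBLE: actual format is in the first two bytes of
      # the 16-byte sub-format GUID at offset 24.
      if (fmt$audio_format == 65534 && chunk_size >= 26) {
        fmt$audio_format <- sum(as.integer(body[25:26]) * c(1, 256))
      }
    } else if (chunk_id == "data") {
      data_raw <- readBin(con, "raw", chunk_size)
    } else {
      invisible(readBin(con, "raw", chunk_size))
    }
    if (chunk_size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort_format(sprintf("Missing fmt/data chunk in WAV file: %s", path))
  }
  if (length(data_raw) == 0) {
    abort_parameter(sprintf("WAV file contains no audio samples: %s", path))
  }

  x <- decode_pcm(data_raw, fmt$audio_format, fmt$bits)
  if (fmt$channels > 1) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- rowMeans(matrix(x[seq_len(n)], ncol = fmt$channels, byrow = TRUE))
  }
  if (length(x) == 0) {
    abort_parameter(sprintf("WAV file contains no audio samples: %s", path))
  }
  pcg_audio(x, fmt$sample_rate)
}

decode_pcm <- function(raw, audio_format, bits) {
  n <- length(raw)
  if (audio_format == 3) {          # IEEE float
    size <- bits / 8
    if (!size %in% c(4, 8)) abort_format("Unsupported float WAV bit depth.")
    return(readBin(raw, "numeric", n = n %/% size, size = size,
                   endian = "little"))
  }
  if (audio_format != 1) {
    abort_format(sprintf("Unsupported WAV audio format code %d.", audio_format))
  }
  switch(
    as.character(bits),
    "8"  = (as.integer(raw) - 128) / 128,
    "16" = readBin(raw, "integer", n = n %/% 2, size = 2, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(raw[seq_len((n %/% 3) * 3)]), nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = readBin(raw, "integer", n = n %/% 4, size = 4,
                   endian = "little") / 2147483648,
    abort_format(sprintf("Unsupported PCM bit depth %d.", bits))
  )
}

#' Write 16-bit PCM WAV
#'
#' Writes a mono 16-bit PCM RIFF/WAVE file.  Samples are quantized with
#' the same full-scale convention the reader uses (x * 32768, clipped to
#' the 16-bit range), so a write/read round trip stays within half a
#' quantization step.
#'
#' @param audio A [pcg_audio()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "pcg_audio"))
  x <- pmin(1, pmax(-1, audio$samples))
  q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- length(q) * 2L
  fs <- as.integer(round(audio$sample_rate_hz))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")       # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

# ---- Preprocessing --------------------------------------------------------

# Zero-phase Butterworth low-pass.  Order and corner are designed per call
# with buttord so that the passband (up to 0.9 * cutoff) stays within about
# 0.8 dB and the stopband (from 2 * cutoff) is attenuated by > 40 dB after
# forward-backward filtering (filtfilt doubles both specs).
lowpass_zero_phase <- function(x, cutoff_hz, fs) {
  nyq <- fs / 2
  des <- signal::buttord(
    Wp = 0.9 * cutoff_hz / nyq, Ws = min(2 * cutoff_hz, 0.99 * nyq) / nyq,
    Rp = 0.4, Rs = 22
  )
  signal::filtfilt(signal::butter(des), x)
}

bandpass_zero_phase <- function(x, low_hz, high_hz, fs, order = 2) {
  nyq <- fs / 2
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

#' Band-limit and resample a PCG recording
#'
#' Resamples the signal to the analysis rate (polyphase, band-limited
#' interpolation) and removes content above `cutoff_hz` with a zero-phase
#' (forward-backward) Butterworth low-pass, so heart sound event times are
#' not shifted by filtering.  Heart sound energy lies below 1000 Hz, and the
#' analysis rate defaults to 32 kHz, giving the canonical 1,600,000 samples
#' for a 50 s recording.
#'
#' @param audio A [pcg_audio()] object.
#' @param cutoff_hz Low-pass cutoff (Hz), default 1000.  Must be below the
#'   Nyquist frequency of the analysis rate.
#' @param analysis_rate_hz Target sample rate (Hz), default 32000.
#' @param highpass_hz Optional high-pass corner (Hz).  Default `NULL` applies
#'   no high-pass: the useful PCG band extends into the infrasonic range and
#'   the S1-identification step relies on infrasonic content.
#' @return A [pcg_audio()] object at `analysis_rate_hz`.
#' @examples
#' a <- pcg_audio(rnorm(16000), 16000)
#' p <- preprocess(a, cutoff_hz = 1000, analysis_rate_hz = 16000)
#' @export
preprocess <- function(audio, cutoff_hz = 1000, analysis_rate_hz = 32000,
                       highpass_hz = NULL) {
  stopifnot(inherits(audio, "pcg_audio"))
  if (cutoff_hz >= analysis_rate_hz / 2) {
    abort_parameter(
      "`cutoff_hz` must be below the Nyquist frequency of `analysis_rate_hz`."
    )
  }
  x <- audio$samples
  fs <- audio$sample_rate_hz
  if (abs(fs - analysis_rate_hz) > 1e-9) {
    rr <- rational_rate(analysis_rate_hz, fs)
    x <- as.numeric(signal::resample(x, rr$p, rr$q))
    fs <- analysis_rate_hz
  }
  x <- lowpass_zero_phase(x, cutoff_hz, fs)
  if (!is.null(highpass_hz)) {
    hf <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
    x <- signal::filtfilt(hf, x)
  }
  pcg_audio(x, fs)
}

# Smallest integer ratio p/q approximating to_rate/from_rate.
rational_rate <- function(to_rate, from_rate) {
  p <- round(to_rate)
  q <- round(from_rate)
  if (abs(to_rate - p) > 1e-6 || abs(from_rate - q) > 1e-6) {
    # Non-integer rates: use a bounded continued-fraction style approximation.
    frac <- to_rate / from_rate
    best <- c(1, 1)
    err <- Inf
    for (den in 1:1000) {
      num <- round(frac * den)
      e <- abs(frac - num / den)
      if (e < err) {
        err <- e
        best <- c(num, den)
      }
    }
    return(list(p = best[1], q = best[2]))
  }
  g <- gcd_int(p, q)
  list(p = p %/% g, q = q %/% g)
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
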
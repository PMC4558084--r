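#' Short-time band power frames
#'
#' Slides a window of `N = round(window_fraction * sample_rate)` samples
#' (1/8 s by default, i.e. N = 4000 at the 32 kHz analysis rate) in hops of
#' `floor(N/2)` (half-window overlap), tapers each window (Hann), transforms
#' it, and sums spectral power into `n_bands` contiguous linear bands
#' spanning 0 to `band_max_hz` (20 bands of 50 Hz by default; preprocessing
#' removes content above 1000 Hz, so linear 50 Hz bands cover the whole
#' useful PCG spectrum).
#'
#' @param audio A [pcg_audio()] object.
#' @param window_fraction Window length as a fraction of the sample rate in
#'   seconds (default 1/8 s).
#' @param overlap_fraction Fractional overlap of consecutive windows
#'   (default 1/2, i.e. the hop is half the window).
#' @param n_bands Number of linear frequency bands (default 20).
#' @param band_max_hz Upper edge of the highest band (default 1000 Hz).
#' @param compression Band power scale: `"log"` (default) stores power as
#'   dB above a floor 80 dB below the record maximum, the convention of
#'   the music beat-tracking envelope this pipeline adopts; an onset then
#'   registers by its level relative to the background, not by its
#'   absolute energy, so a soft S2 produces spectral flux comparable to a
#'   loud S1 instead of being quartically suppressed.  `"linear"` stores
#'   raw power per band.  Both scales are non-negative and the resulting
#'   onset envelope is invariant to overall signal polarity; the `"log"`
#'   scale is additionally invariant to overall signal scale.
#' @return A `pcg_frames` object: list with `band_power` (n_frames x
#'   n_bands matrix, power per band on the chosen scale), `frame_times`
#'   (window centres, seconds), `window_len_samples`, `hop_samples` and
#'   `sample_rate_hz`.
#' @examples
#' a <- pcg_audio(sin(2 * pi * 125 * seq(0, 1, by = 1 / 8000)), 8000)
#' f <- spectral_frames(a)
#' dim(f$band_power)
#' @export
spectral_frames <- function(audio, window_fraction = 1 / 8,
                            overlap_fraction = 1 / 2,
                            n_bands = 20, band_max_hz = 1000,
                            compression = c("log", "linear")) {
  stopifnot(inherits(audio, "pcg_audio"))
  compression <- match.arg(compression)
  if (window_fraction <= 0 || overlap_fraction < 0 || overlap_fraction >= 1) {
    abort_parameter("Invalid window/overlap fractions.")
  }
  x <- audio$samples
  fs <- audio$sample_rate_hz
  N <- as.integer(round(window_fraction * fs))
  hop <- as.integer(floor(N * (1 - overlap_fraction)))
  if (length(x) < N) {
    abort_insufficient(sprintf(
      "Signal (%d samples) is shorter than one analysis window (%d samples).",
      length(x), N
    ))
  }
  starts <- seq.int(0L, length(x) - N, by = hop)
  K <- length(starts)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(N - 1)) / (N - 1))

  frames <- matrix(x[outer(seq_len(N), starts, `+`)], nrow = N, ncol = K)
  frames <- frames * taper
  spec <- stats::mvfft(frames)
  n_bins <- N %/% 2 + 1
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2

  freqs <- (seq_len(n_bins) - 1) * fs / N
  band_width <- band_max_hz / n_bands
  band <- pmin(n_bands, floor(freqs / band_width) + 1)
  keep <- freqs <= band_max_hz
  band_power <- t(rowsum(power[keep, , drop = FALSE], group = band[keep]))
  dimnames(band_power) <- NULL

  if (compression == "log" && max(band_power) > 0) {
    # dB above a floor 80 dB below the record maximum; values stay >= 0
    # and the scale is independent of the overall recording level.
    ref <- max(band_power)
    band_power <- pmax(10 * log10(band_power / ref + 1e-12) + 80, 0)
  }

  structure(
    list(
      band_power = band_power,
      frame_times = (starts + N / 2) / fs,
      window_len_samples = N,
      hop_samples = hop,
      sample_rate_hz = fs
    ),
    class = "pcg_frames"
  )
}

#' @export
print.pcg_frames <- function(x, ...) {
  cat(sprintf(
    "<pcg_frames: %d frames x %d bands, window %d, hop %d @ %g Hz>\n",
    nrow(x$band_power), ncol(x$band_power),
    x$window_len_samples, x$hop_samples, x$sample_rate_hz
  ))
  invisible(x)
}

#' Construct an onset strength envelope from raw values
#'
#' Mostly useful for tests and for driving [track_beats()] with synthetic
#' envelopes; [onset_strength()] builds one from audio frames.
#'
#' @param strength Non-negative per-frame onset strengths.
#' @param frame_rate_hz Frames per second.
#' @param t0 Time of the first frame (seconds).
#' @return A `pcg_onset` tibble with columns `time_s` and `strength` and
#'   attribute `frame_rate_hz`.
#' @export
onset_envelope <- function(strength, frame_rate_hz, t0 = 0) {
  strength <- as.numeric(strength)
  if (any(!is.finite(strength)) || any(strength < 0)) {
    abort_parameter("`strength` must be finite and non-negative.")
  }
  out <- tibble(
    time_s = t0 + (seq_along(strength) - 1) / frame_rate_hz,
    strength = strength
  )
  attr(out, "frame_rate_hz") <- frame_rate_hz
  class(out) <- c("pcg_onset", class(out))
  out
}

#' Onset strength envelope (spectral flux)
#'
#' The onset strength at step k is the total squared change in band power
#' between consecutive frames:
#' \deqn{\Gamma(k) = \sum_{m=1}^{20} | S_m(k) - S_m(k-1) |^2}
#' It peaks where the spectral content changes, i.e. at the onset of an
#' acoustic event, independently of the waveform amplitude itself.  The
#' value is timestamped at the later frame k, so envelope peaks coincide
#' with the onsets of high-energy regions.
#'
#' @param frames A `pcg_frames` object from [spectral_frames()].
#' @param normalize Scale the envelope to unit maximum (default `TRUE`).
#'   Normalization makes the beat-tracker configuration record-independent;
#'   set `FALSE` to obtain the raw quartic-scale values.
#' @return A `pcg_onset` tibble (columns `time_s`, `strength`; attribute
#'   `frame_rate_hz`) with `n_frames - 1` rows.
#' @export
onset_strength <- function(frames, normalize = TRUE) {
  stopifnot(inherits(frames, "pcg_frames"))
  K <- nrow(frames$band_power)
  if (K < 2) {
    abort_insufficient("At least 2 frames are required for onset strength.")
  }
  d <- diff(frames$band_power)
  strength <- rowSums(d^2)
  if (normalize && max(strength) > 0) {
    strength <- strength / max(strength)
  }
  out <- tibble(time_s = frames$frame_times[-1], strength = strength)
  attr(out, "frame_rate_hz") <- frames$sample_rate_hz / frames$hop_samples
  class(out) <- c("pcg_onset", class(out))
  out
}

#' Construct an energy envelope from raw values
#'
#' @param values Non-negative envelope values.
#' @param frame_times Times of the envelope samples (seconds), uniformly
#'   spaced.
#' @return A `pcg_envelope` tibble with columns `time_s`, `value` and
#'   attribute `hop_s`.
#' @export
energy_envelope <- function(values, frame_times) {
  values <- as.numeric(values)
  if (length(values) != length(frame_times)) {
    abort_parameter("`values` and `frame_times` must have equal length.")
  }
  out <- tibble(time_s = as.numeric(frame_times), value = values)
  attr(out, "hop_s") <- if (length(frame_times) > 1) {
    frame_times[2] - frame_times[1]
  } else {
    NA_real_
  }
  class(out) <- c("pcg_envelope", class(out))
  out
}

#' Shannon energy envelope
#'
#' The Shannon energy of a unit-normalized sample x is -x^2 log(x^2) (with
#' the convention 0 log 0 = 0); it emphasises mid-amplitude components and
#' de-emphasises both low-level noise and the strongest peaks.  The envelope
#' is the per-window mean of the Shannon energy, normalized to unit maximum.
#' Heart sound widths T1/T2 are measured on this envelope, not on the onset
#' strength envelope.
#'
#' @param audio A [pcg_audio()] object.
#' @param window_s Averaging window in seconds (default 0.02).
#' @param hop_s Hop between window starts in seconds (default 0.01).
#' @param normalize_input Scale the signal to unit peak absolute amplitude
#'   before computing Shannon energy (default `TRUE`).  Disable to evaluate
#'   the raw formula on an already-scaled signal.
#' @param normalize Scale the output envelope to unit maximum (default
#'   `TRUE`); disable to obtain the raw per-window mean Shannon energy.
#' @return A `pcg_envelope` tibble (columns `time_s`, `value`; attributes
#'   `hop_s`, `window_s`), values in \[0, 1\].
#' @export
shannon_energy_envelope <- function(audio, window_s = 0.02, hop_s = 0.01,
                                    normalize_input = TRUE,
                                    normalize = TRUE) {
  stopifnot(inherits(audio, "pcg_audio"))
  if (window_s <= 0 || hop_s <= 0) {
    abort_parameter("`window_s` and `hop_s` must be positive.")
  }
  x <- audio$samples
  fs <- audio$sample_rate_hz
  if (normalize_input && max(abs(x)) > 0) {
    x <- x / max(abs(x))
  }
  x2 <- x^2
  se <- ifelse(x2 > 0, -x2 * log(x2), 0)

  w <- max(1L, as.integer(round(window_s * fs)))
  h <- max(1L, as.integer(round(hop_s * fs)))
  if (length(se) < w) {
    abort_insufficient("Signal shorter than one Shannon-energy window.")
  }
  cs <- c(0, cumsum(se))
  starts <- seq.int(0L, length(se) - w, by = h)
  values <- (cs[starts + w + 1] - cs[starts + 1]) / w
  if (normalize && max(values) > 0) values <- values / max(values)

  out <- energy_envelope(values, (starts + w / 2) / fs)
  attr(out, "window_s") <- w / fs
  attr(out, "hop_s") <- h / fs
  out
}
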
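# Shared fixtures and independent oracles, all generated in code.

tone_audio <- function(freq_hz, duration_s = 1, fs = 8000, amp = 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  pcg_audio(amp * sin(2 * pi * freq_hz * t), fs)
}

# Fraction of `truth` events matched by a detection within `tol` seconds.
match_frac <- function(detected, truth, tol = 0.05) {
  detected <- if (is.data.frame(detected)) detected$beat_time_s else detected
  mean(vapply(truth, function(tt) min(abs(detected - tt)) <= tol,
              logical(1)))
}

# Independent exhaustive maximizer of the beat-tracking objective
#   sum(strength[idx]) - tightness * sum((log(diff(idx) / period))^2)
# over all strictly increasing frame subsets (n <= 12 frames).
brute_force_beats <- function(strength, period_frames, tightness) {
  n <- length(strength)
  stopifnot(n <= 12)
  best_score <- -Inf
  best <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    score <- sum(strength[idx])
    if (length(idx) > 1) {
      score <- score -
        tightness * sum((log(diff(idx) / period_frames))^2)
    }
    if (score > best_score) {
      best_score <- score
      best <- idx
    }
  }
  list(idx = best, score = best_score)
}

# Independent interval-matching oracle for S1/S2 pairing: each S1 keeps the
# single S2 strictly between it and the next S1; zero or multiple
# candidates drop the S1.
pair_oracle <- function(s1, s2) {
  kept_s1 <- c()
  kept_s2 <- c()
  for (i in seq_along(s1)) {
    upper <- if (i < length(s1)) s1[i + 1] else Inf
    cand <- s2[s2 > s1[i] & s2 < upper]
    if (length(cand) == 1) {
      kept_s1 <- c(kept_s1, s1[i])
      kept_s2 <- c(kept_s2, cand)
    }
  }
  list(s1 = kept_s1, s2 = kept_s2)
}

# Literal re-evaluation of the flux definition, element by element.
flux_oracle <- function(band_power) {
  K <- nrow(band_power)
  out <- numeric(K - 1)
  for (k in 2:K) {
    acc <- 0
    for (m in seq_len(ncol(band_power))) {
      acc <- acc + abs(band_power[k, m] - band_power[k - 1, m])^2
    }
    out[k - 1] <- acc
  }
  out
}

# pcg_frames object from a raw band-power matrix (for driving
# onset_strength directly).
frames_from_matrix <- function(band_power, frame_step_s = 0.0625,
                               fs = 32000) {
  structure(
    list(
      band_power = band_power,
      frame_times = frame_step_s * (seq_len(nrow(band_power)) + 1),
      window_len_samples = as.integer(2 * frame_step_s * fs),
      hop_samples = as.integer(frame_step_s * fs),
      sample_rate_hz = fs
    ),
    class = "pcg_frames"
  )
}
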
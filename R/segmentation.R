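#' Segmentation configuration
#'
#' Parameters of the two-pass S1/S2 extraction and labeling stage.
#'
#' @param sigma_s Temporal width (seconds) of the Gaussian troughs in the
#'   suppression weighting function (default 0.1 s, about the analysis
#'   window).  The spectral-flux signature of one heart sound spans the
#'   sound duration plus one analysis window (about 0.2 s at the default
#'   parameters), so the trough must cover most of that blob; a much
#'   narrower trough leaves the flanks of the first-pass sounds standing
#'   and the second pass re-detects them instead of the interleaved
#'   sequence, while a much wider trough erodes the neighbouring sound at
#'   the short systolic gaps of exercise heart rates.
#' @param suppression_depth Trough depth coefficient (default 0.8): the
#'   weighting function falls to `1 - suppression_depth` at an isolated
#'   detected beat.
#' @param min_s1_separation_s Hard lower bound on the separation of
#'   consecutive beats in a candidate S1 sequence (default 0.22 s).
#' @param max_separation_factor Upper bound on separations as a multiple of
#'   the sequence's median separation (default 1.3).
#' @param screen_min_fraction Minimum fraction of separations that must
#'   satisfy the upper bound for a sequence to pass the timing screen
#'   (default 0.9).  The lower bound is absolute (a refractory limit); the
#'   upper bound tolerates occasional gaps from missed beats, which the
#'   pipeline discards rather than repairs.
#' @param infrasonic_band_hz Band (Hz) used for the S1-identification
#'   variance test (default 2-20 Hz: below the audibility floor, above DC
#'   drift).
#' @param width_threshold Fraction of the local Shannon-envelope peak
#'   defining the heart sound width region (default 0.2).
#' @param width_search_s Half-width (seconds) of the window in which the
#'   Shannon-envelope peak nearest an event is sought (default 0.1).
#' @param refine_window_s Half-width (seconds) of the window used to snap
#'   tracked beat times (which are quantized to the onset-envelope frame
#'   grid) to the nearest Shannon-envelope peak (default 0.1).
#' @param min_s1_s2_gap_s Optional hard lower bound on the S1-to-S2 gap
#'   applied during pairing (default `NULL`, off).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(sigma_s = 0.1,
                                suppression_depth = 0.8,
                                min_s1_separation_s = 0.22,
                                max_separation_factor = 1.3,
                                screen_min_fraction = 0.9,
                                infrasonic_band_hz = c(2, 20),
                                width_threshold = 0.2,
                                width_search_s = 0.1,
                                refine_window_s = 0.1,
                                min_s1_s2_gap_s = NULL) {
  if (sigma_s <= 0) abort_parameter("`sigma_s` must be positive.")
  if (suppression_depth <= 0 || suppression_depth >= 1) {
    abort_parameter("`suppression_depth` must be in (0, 1).")
  }
  if (min_s1_separation_s <= 0) {
    abort_parameter("`min_s1_separation_s` must be positive.")
  }
  structure(
    list(
      sigma_s = sigma_s,
      suppression_depth = suppression_depth,
      min_s1_separation_s = min_s1_separation_s,
      max_separation_factor = max_separation_factor,
      screen_min_fraction = screen_min_fraction,
      infrasonic_band_hz = infrasonic_band_hz,
      width_threshold = width_threshold,
      width_search_s = width_search_s,
      refine_window_s = refine_window_s,
      min_s1_s2_gap_s = min_s1_s2_gap_s
    ),
    class = "segmentation_config"
  )
}

#' Beat suppression weighting function
#'
#' \deqn{W(t) = \max(0,\; 1 - \sum_i 0.8 \exp(-(t - \mu_i)^2 / 2\sigma^2))}
#' equals 1 far from all detected beats and dips to `1 - suppression_depth`
#' (0.2 by default) at each isolated beat time.  The clamp at zero guards
#' against pathological beat overlaps closer than about 2 sigma, where the
#' unclamped sum would go negative and invert the envelope.
#'
#' @param t Numeric vector of times (seconds).
#' @param beats A `pcg_beats` tibble or numeric vector of beat times.
#' @param cfg A [segmentation_config()].
#' @return Weights in \[0, 1\], same length as `t`.  An empty beat list
#'   gives constant 1.
#' @export
weighting_function <- function(t, beats, cfg = segmentation_config()) {
  mu <- beat_times(beats)
  if (length(mu) == 0) {
    return(rep(1, length(t)))
  }
  if (is.unsorted(mu, strictly = TRUE)) {
    abort_parameter("Beat times must be strictly increasing.")
  }
  dips <- vapply(t, function(ti) {
    sum(cfg$suppression_depth * exp(-(ti - mu)^2 / (2 * cfg$sigma_s^2)))
  }, numeric(1))
  pmax(0, 1 - dips)
}

beat_times <- function(beats) {
  if (inherits(beats, "pcg_beats") || is.data.frame(beats)) {
    as.numeric(beats$beat_time_s)
  } else {
    as.numeric(beats)
  }
}

#' Suppress detected beats in an onset envelope
#'
#' Multiplies the onset strength pointwise by [weighting_function()]
#' evaluated at the frame times, practically removing the signature of an
#' already-detected beat sequence so that a second tracking pass recovers
#' the interleaved sequence.
#'
#' @inheritParams weighting_function
#' @param ose A `pcg_onset` envelope.
#' @return A `pcg_onset` envelope with the same frame times.
#' @export
suppress_beats <- function(ose, beats, cfg = segmentation_config()) {
  stopifnot(inherits(ose, "pcg_onset"))
  w <- weighting_function(ose$time_s, beats, cfg)
  out <- ose
  out$strength <- ose$strength * w
  out
}

#' Snap beat times to Shannon-envelope peaks
#'
#' Tracked beat times are quantized to the (interpolated) onset-envelope
#' frame grid and carry a systematic offset between flux timestamps and
#' sound centres.  This refinement moves each beat to a local maximum of
#' the Shannon energy envelope within `refine_window_s` (parabolic
#' interpolation around the peak), recovering heart sound timing at and
#' below the envelope hop resolution (10 ms).  Methods:
#' * `"phase"` (default) — snap to the nearest qualifying peak, estimate
#'   the sequence's median offset, then re-snap around the offset-corrected
#'   times: beats whose individual nearest peak belongs to the neighbouring
#'   sound are pulled back to the majority phase.
#' * `"viterbi"` — joint assignment over candidate peaks maximizing peak
#'   height minus a penalty on deviations of refined intervals from the
#'   tracked intervals.
#' * `"nearest"` — independent per-beat nearest-peak snap.
#'
#' Refinements that would bring two beats closer than half of
#' `min_s1_separation_s` are reverted, so the output remains strictly
#' increasing.
#'
#' @param beats A `pcg_beats` tibble.
#' @param see A `pcg_envelope` from [shannon_energy_envelope()].
#' @param cfg A [segmentation_config()].
#' @param method Refinement strategy (see above).
#' @param exclude_times Optional times of already-assigned events (e.g.
#'   the refined first-pass sequence when refining the second pass):
#'   envelope peaks within `refine_window_s / 2` of one of these are not
#'   used as snap targets, so the two sequences cannot collapse onto the
#'   same sounds.
#' @return A `pcg_beats` tibble with refined times.
#' @export
refine_beat_times <- function(beats, see, cfg = segmentation_config(),
                              method = c("phase", "viterbi", "nearest"),
                              exclude_times = NULL) {
  stopifnot(inherits(see, "pcg_envelope"))
  method <- match.arg(method)
  times <- beat_times(beats)
  n <- length(times)
  if (n == 0) return(beats)
  see <- smooth_envelope(see)
  excl_radius <- cfg$refine_window_s / 2
  drop_excluded <- function(p) {
    if (is.null(exclude_times) || nrow(p) == 0) return(p)
    keep <- vapply(p[, 1], function(tp) {
      all(abs(exclude_times - tp) > excl_radius)
    }, logical(1))
    p[keep, , drop = FALSE]
  }

  if (method %in% c("phase", "nearest")) {
    snap <- function(targets) {
      vapply(targets, function(t0) {
        p <- drop_excluded(envelope_peaks(see, t0, cfg$refine_window_s))
        if (nrow(p) == 0) return(NA_real_)
        p[which.min(abs(p[, 1] - t0)), 1]
      }, numeric(1))
    }
    first_pass <- snap(times)
    if (method == "phase" && any(!is.na(first_pass))) {
      # The tracker lands at a roughly constant offset from the sound
      # centres (flux timestamping plus grid quantization).  Correcting
      # the sequence's median offset first, then re-snapping, keeps beats
      # whose individual nearest peak belongs to the neighbouring sound
      # with the majority phase.  A beat the corrected window fails to
      # cover falls back to its first-round snap, then to its raw time.
      delta <- median(first_pass - times, na.rm = TRUE)
      refined <- snap(times + delta)
      refined <- ifelse(!is.na(refined), refined,
                        ifelse(!is.na(first_pass), first_pass, times))
    } else {
      refined <- ifelse(!is.na(first_pass), first_pass, times)
    }
    if (n > 1) {
      for (i in 2:n) {
        if (refined[i] - refined[i - 1] < cfg$min_s1_separation_s / 2) {
          refined[i] <- times[i]
        }
      }
      refined <- refined[!duplicated(refined)]
    }
    return(new_beats(sort(refined), attr(beats, "tempo_bpm"),
                     attr(beats, "objective"), attr(beats, "frame_rate_hz")))
  }

  # Candidate envelope peaks per beat (the unrefined time is always a
  # fallback candidate).  When heart sounds sit close together, the
  # nearest peak to a quantized beat can belong to the wrong sound, so the
  # assignment is made jointly: a small Viterbi pass rewards peak height
  # but penalizes refined inter-beat intervals that deviate from the
  # tracked intervals, keeping the whole sequence locked on one sound.
  cands <- lapply(times, function(t0) {
    p <- drop_excluded(envelope_peaks(see, t0, cfg$refine_window_s))
    rbind(p, c(t0, 0))
  })
  sep_floor <- cfg$min_s1_separation_s / 2
  # Interval deviation (s) costing one unit of peak height: somewhat above
  # the interpolated frame-grid quantization of the tracked intervals, so
  # quantization-scale corrections are cheap while sound-swapping jumps
  # (about one systolic interval) stay expensive.
  int_scale <- 0.05

  prev_score <- cands[[1]][, 2] - 0.5 * (abs(cands[[1]][, 1] - times[1]) /
                                           cfg$refine_window_s)^2
  back <- vector("list", n)
  for (i in seq_len(n)[-1]) {
    ci <- cands[[i]]
    d_raw <- times[i] - times[i - 1]
    sc <- numeric(nrow(ci))
    bk <- integer(nrow(ci))
    for (j in seq_len(nrow(ci))) {
      dt <- ci[j, 1] - cands[[i - 1]][, 1]
      pen <- ((dt - d_raw) / int_scale)^2
      pen[dt < sep_floor] <- Inf
      tot <- prev_score - pen
      bk[j] <- which.max(tot)
      sc[j] <- ci[j, 2] + tot[bk[j]]
    }
    back[[i]] <- bk
    prev_score <- sc
  }
  pick <- integer(n)
  pick[n] <- which.max(prev_score)
  if (n > 1) {
    for (i in seq.int(n, 2)) pick[i - 1] <- back[[i]][pick[i]]
  }
  refined <- vapply(seq_len(n), function(i) cands[[i]][pick[i], 1],
                    numeric(1))

  # Guard: enforce strict increase (revert any residual collisions).
  if (n > 1) {
    for (i in 2:n) {
      if (refined[i] - refined[i - 1] < sep_floor) refined[i] <- times[i]
    }
    refined <- refined[!duplicated(refined)]
  }
  new_beats(sort(refined), attr(beats, "tempo_bpm"),
            attr(beats, "objective"), attr(beats, "frame_rate_hz"))
}

# Local envelope maxima within +/- window_s of t0, as a matrix with
# columns (time, height); times parabolic-interpolated.  Maxima below
# `min_rel` times the window maximum are excluded so that noise-floor
# micro-peaks cannot act as refinement targets.  Zero rows when no local
# Three-point moving average of an energy envelope.  The Shannon envelope
# of a clean tone burst carries ripple at the tone period (the averaging
# window spans only a couple of cycles), which splits one sound into twin
# peaks 10-20 ms apart; light smoothing merges them so peak snapping is
# stable.  Used for beat refinement only — width measurement keeps the
# envelope as defined.
smooth_envelope <- function(see) {
  v <- see$value
  n <- length(v)
  if (n < 3) return(see)
  sm <- (c(v[-1], v[n]) + v + c(v[1], v[-n])) / 3
  out <- see
  out$value <- sm
  out
}

# maximum lies in the window.  Two floors apply: `min_rel` of the window
# maximum (suppresses side-bumps next to a real sound) and `min_abs` of
# the global envelope maximum (a window containing no sound at all has
# only noise-floor bumps, and its local maximum must not qualify).
envelope_peaks <- function(see, t0, window_s, min_rel = 0.25,
                           min_abs = 0.3) {
  v <- see$value
  t <- see$time_s
  n <- length(v)
  empty <- matrix(numeric(0), ncol = 2)
  idx <- which(abs(t - t0) <= window_s)
  if (length(idx) == 0) return(empty)
  floor_v <- max(min_rel * max(v[idx]), min_abs * max(v))
  is_peak <- vapply(idx, function(i) {
    left <- if (i > 1) v[i - 1] else -Inf
    right <- if (i < n) v[i + 1] else -Inf
    v[i] >= left && v[i] >= right && v[i] > 0 && v[i] >= floor_v
  }, logical(1))
  peaks <- idx[is_peak]
  if (length(peaks) == 0) return(empty)
  hop <- attr(see, "hop_s") %||% (if (n > 1) t[2] - t[1] else 0)
  out <- t(vapply(peaks, function(p) {
    tp <- t[p]
    if (p > 1 && p < n) {
      denom <- v[p - 1] - 2 * v[p] + v[p + 1]
      if (is.finite(denom) && denom < 0) {
        delta <- 0.5 * (v[p - 1] - v[p + 1]) / denom
        if (abs(delta) <= 0.5) tp <- t[p] + delta * hop
      }
    }
    c(tp, v[p])
  }, numeric(2)))
  out
}

#' Two-pass extraction of the interleaved heart sound sequences
#'
#' Runs the beat tracker on the onset strength envelope of a preprocessed
#' recording to obtain the first (stronger) heart sound sequence, removes
#' its signature by multiplying the envelope with the suppression weighting
#' function, and tracks again to obtain the interleaved second sequence.
#' Beat times of both passes are then refined to Shannon-envelope peaks
#' (see [refine_beat_times()]).  The sequences are returned unlabeled; use
#' [identify_s1()] to decide which is S1.
#'
#' @param audio A preprocessed [pcg_audio()] (band-limited below 1000 Hz).
#' @param tracker_cfg A [tracker_config()].
#' @param seg_cfg A [segmentation_config()].
#' @param refine Snap beat times to Shannon-envelope peaks (default `TRUE`).
#' @param reestimate_tempo Re-estimate the global tempo on the suppressed
#'   envelope before the second pass (default `FALSE`: both heart sound
#'   sequences share the cycle period, and autocorrelation estimates on a
#'   suppressed envelope are prone to half-tempo aliasing, so the
#'   first-pass tempo is reused).
#' @return A list with `first` and `second` (`pcg_beats`), `see` (the
#'   Shannon energy envelope), `ose`, `ose_suppressed`, and `raw` (the
#'   unrefined beat sequences of both passes).
#' @export
extract_two_sequences <- function(audio,
                                  tracker_cfg = tracker_config(),
                                  seg_cfg = segmentation_config(),
                                  refine = TRUE,
                                  reestimate_tempo = FALSE) {
  stopifnot(inherits(audio, "pcg_audio"))
  frames <- spectral_frames(audio)
  ose <- onset_strength(frames)

  ose_fine <- interp_onset(ose, tracker_cfg$interp_factor %||% 1L)
  tempo1 <- estimate_tempo(ose, tracker_cfg)
  b1 <- track_beats(ose_fine, tempo1, tracker_cfg)
  if (nrow(b1) < 3) {
    abort_insufficient(
      sprintf("Fewer than 3 beats found in the first tracking pass (%d).",
              nrow(b1)),
      pass = "first"
    )
  }

  see <- shannon_energy_envelope(audio)
  # Refining the first-pass beats before suppression centres the weighting
  # troughs on the actual sounds rather than on frame-grid-quantized beat
  # times.  Suppression uses the union of the raw (flux-grid) and refined
  # (sound-centre) estimates of each first-pass beat: their overlapping
  # troughs sum, nulling the whole flux signature of the sound — centre
  # and flanks — so the second pass cannot re-detect its edges.
  r1 <- if (refine) refine_beat_times(b1, see, seg_cfg) else b1
  mu1 <- sort(unique(round(c(beat_times(b1), beat_times(r1)), 6)))
  ose2 <- suppress_beats(ose, mu1, seg_cfg)
  ose2_fine <- suppress_beats(ose_fine, mu1, seg_cfg)
  tempo2 <- if (reestimate_tempo) {
    tryCatch(estimate_tempo(ose2, tracker_cfg), error = function(e) tempo1)
  } else {
    tempo1
  }
  b2 <- track_beats(ose2_fine, tempo2, tracker_cfg)
  if (nrow(b2) < 3) {
    abort_insufficient(
      sprintf("Fewer than 3 beats found in the second tracking pass (%d).",
              nrow(b2)),
      pass = "second"
    )
  }

  r2 <- if (refine) {
    refine_beat_times(b2, see, seg_cfg, exclude_times = beat_times(r1))
  } else {
    b2
  }
  if (refine) {
    r1 <- fill_sequence_gaps(r1, see, seg_cfg, exclude_times = beat_times(r2))
    r2 <- fill_sequence_gaps(r2, see, seg_cfg, exclude_times = beat_times(r1))
  }
  list(first = r1, second = r2, see = see, ose = ose, ose_suppressed = ose2,
       raw = list(first = b1, second = b2))
}

# Repair isolated dropped cycles in a refined beat sequence: a gap close
# to twice the local beat interval, with a qualifying Shannon-envelope
# peak near its midpoint (and not claimed by the other sequence), gets
# that peak inserted.  The tracker proposes, the envelope confirms; gaps
# without a confirming sound are left alone (missed beats are dropped
# downstream, never invented).
fill_sequence_gaps <- function(beats, see, cfg, exclude_times = NULL) {
  times <- beat_times(beats)
  if (length(times) < 5) return(beats)
  see <- smooth_envelope(see)
  excl_radius <- cfg$refine_window_s / 2
  repeat {
    gaps <- diff(times)
    inserted <- FALSE
    for (i in seq_along(gaps)) {
      lo <- max(1, i - 3)
      hi <- min(length(gaps), i + 3)
      local_med <- median(gaps[setdiff(lo:hi, i)])
      if (!is.finite(local_med) || local_med <= 0) next
      if (gaps[i] < 1.6 * local_med || gaps[i] > 2.4 * local_med) next
      expected <- times[i] + gaps[i] / 2
      p <- envelope_peaks(see, expected, cfg$refine_window_s)
      if (!is.null(exclude_times) && nrow(p) > 0) {
        keep <- vapply(p[, 1], function(tp) {
          all(abs(exclude_times - tp) > excl_radius)
        }, logical(1))
        p <- p[keep, , drop = FALSE]
      }
      if (nrow(p) == 0) next
      cand <- p[which.min(abs(p[, 1] - expected)), 1]
      if (cand - times[i] < cfg$min_s1_separation_s ||
          times[i + 1] - cand < cfg$min_s1_separation_s) next
      times <- sort(c(times, cand))
      inserted <- TRUE
      break
    }
    if (!inserted) break
  }
  new_beats(times, attr(beats, "tempo_bpm"), attr(beats, "objective"),
            attr(beats, "frame_rate_hz"))
}

#' Identify which extracted sequence is S1
#'
#' Applies two rules.  (a) Timing screen: separations between consecutive
#' beats of a plausible S1 sequence may not fall below
#' `min_s1_separation_s` (0.22 s, an absolute refractory limit) and should
#' not exceed `max_separation_factor` (1.3) times the sequence's median
#' separation; a sequence fails the screen if any separation violates the
#' lower bound or more than `1 - screen_min_fraction` of separations exceed
#' the upper bound.  If exactly one sequence fails, the other is S1
#' regardless of rule (b).  (b) Infrasonic variance: the systolic segment
#' (S1 to the following S2) carries higher infrasonic-band variance than
#' the diastolic segment, so the sequence whose forward intervals have the
#' larger mean variance of the 2-20 Hz band-passed signal is S1.
#'
#' @param seq_a,seq_b `pcg_beats` sequences from the two tracking passes
#'   (order irrelevant), each with at least 3 beats.
#' @param audio The preprocessed [pcg_audio()] the sequences came from.
#' @param cfg A [segmentation_config()].
#' @return A `pcg_labeled` object: list with `s1_times`, `s2_times`,
#'   `label_confidence` (normalized margin of the variance test, in
#'   \[0, 1\]) and `s1_source` (`"a"` or `"b"`).
#' @export
identify_s1 <- function(seq_a, seq_b, audio, cfg = segmentation_config()) {
  stopifnot(inherits(audio, "pcg_audio"))
  a <- beat_times(seq_a)
  b <- beat_times(seq_b)
  if (length(a) < 3 || length(b) < 3) {
    abort_insufficient("Both sequences need at least 3 beats to label S1.")
  }

  elig_a <- timing_screen(a, cfg)
  elig_b <- timing_screen(b, cfg)
  if (!elig_a && !elig_b) {
    abort_unlabelable(
      "Both beat sequences fail the S1 timing screen; beats left unlabeled."
    )
  }

  xf <- bandpass_zero_phase(audio$samples, cfg$infrasonic_band_hz[1],
                            cfg$infrasonic_band_hz[2], audio$sample_rate_hz)
  # Pre-whitening by first difference: ambient and locomotion rumble pile
  # up at the bottom of the infrasonic band (roughly 1/f), while the
  # systolic vibration signature sits higher in it; differencing weights
  # power by frequency squared and so suppresses the rumble background
  # without moving the analysis band.
  xd <- c(0, diff(xf))
  v_ab <- interval_variances(xd, audio$sample_rate_hz, a, b)
  v_ba <- interval_variances(xd, audio$sample_rate_hz, b, a)
  # Paired per-cycle comparison: broadband low-frequency interference
  # (e.g. footfall rumble) varies slowly, so comparing each forward
  # interval with the immediately adjacent backward interval cancels it;
  # the margin is the excess fraction of cycles voting A over B.
  k <- min(length(v_ab), length(v_ba))
  pair_ok <- is.finite(v_ab[seq_len(k)]) & is.finite(v_ba[seq_len(k)])
  confidence <- 0
  vote_a <- NA
  if (any(pair_ok)) {
    diffs <- v_ab[seq_len(k)][pair_ok] - v_ba[seq_len(k)][pair_ok]
    diffs <- diffs[diffs != 0]
    if (length(diffs) > 0) {
      # Wilcoxon signed-rank statistic on the paired differences:
      # magnitude-aware (large systolic excesses count more) yet robust to
      # the occasional mis-tracked interval.
      rk <- rank(abs(diffs))
      vote_a <- sum(rk[diffs > 0]) / sum(rk)
      confidence <- abs(2 * vote_a - 1)
    }
  }

  a_is_s1 <- if (elig_a && !elig_b) {
    TRUE
  } else if (!elig_a && elig_b) {
    FALSE
  } else if (!is.na(vote_a)) {
    vote_a >= 0.5
  } else {
    mean(v_ab, na.rm = TRUE) >= mean(v_ba, na.rm = TRUE)
  }

  structure(
    list(
      s1_times = if (a_is_s1) a else b,
      s2_times = if (a_is_s1) b else a,
      label_confidence = confidence,
      s1_source = if (a_is_s1) "a" else "b"
    ),
    class = "pcg_labeled"
  )
}

timing_screen <- function(times, cfg) {
  seps <- diff(times)
  if (length(seps) == 0) return(FALSE)
  if (any(seps < cfg$min_s1_separation_s)) return(FALSE)
  upper_ok <- mean(seps <= cfg$max_separation_factor * median(seps))
  upper_ok >= cfg$screen_min_fraction
}

# Variance of x over the forward interval from each `from` event to the
# next `to` event, aligned to `from` (NA where no valid interval exists,
# i.e. another `from` event intervenes or the segment is degenerate).
interval_variances <- function(x, fs, from, to) {
  vapply(seq_along(from), function(i) {
    nxt <- to[to > from[i]]
    if (length(nxt) == 0) return(NA_real_)
    upper <- if (i < length(from)) from[i + 1] else Inf
    if (nxt[1] >= upper) return(NA_real_)
    i0 <- max(1L, as.integer(floor(from[i] * fs)) + 1L)
    i1 <- min(length(x), as.integer(ceiling(nxt[1] * fs)))
    if (i1 - i0 < 8) return(NA_real_)
    var(x[i0:i1])
  }, numeric(1))
}

#' @export
print.pcg_labeled <- function(x, ...) {
  cat(sprintf(
    "<pcg_labeled: %d S1, %d S2, confidence %.3f>\n",
    length(x$s1_times), length(x$s2_times), x$label_confidence
  ))
  invisible(x)
}

#' @export
as_tibble.pcg_labeled <- function(x, ...) {
  out <- dplyr::arrange(dplyr::bind_rows(
    tibble(time_s = x$s1_times, sound = "s1"),
    tibble(time_s = x$s2_times, sound = "s2")
  ), .data$time_s)
  out
}

#' Pair labeled S1/S2 beats into heart cycles
#'
#' Each S1 pairs with the single S2 that falls after it and before the next
#' S1.  An S1 with zero or two-or-more intervening S2 candidates is dropped
#' (undetected or ambiguous beats are discarded, not repaired), and
#' unmatched S2 beats are dropped.  For each retained cycle the systolic
#' interval `t12_s = s2 - s1` is computed; the heartbeat interval `t11_s`
#' (and hence the diastolic interval `t21_s = t11_s - t12_s`) is attached
#' only when the immediately following S1 also survived pairing.  Heart
#' sound widths T1/T2 are measured on the Shannon energy envelope at each
#' retained event (see [measure_width()]).
#'
#' @param labeled A `pcg_labeled` object from [identify_s1()].
#' @param see A `pcg_envelope` from [shannon_energy_envelope()], or `NULL`
#'   to skip width measurement.
#' @param cfg A [segmentation_config()].
#' @return A `pcg_cycles` tibble with columns `s1_time_s`, `s2_time_s`,
#'   `t11_s`, `t12_s`, `t21_s`, `t1_width_s`, `t2_width_s` (`NA` for absent
#'   values).  Empty input yields an empty table.
#' @export
pair_beats <- function(labeled, see = NULL, cfg = segmentation_config()) {
  s1 <- labeled$s1_times
  s2 <- labeled$s2_times
  if (is.unsorted(s1, strictly = TRUE) || is.unsorted(s2, strictly = TRUE)) {
    abort_parameter("Labeled sequences must be strictly increasing.")
  }

  n <- length(s1)
  paired_s2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    upper <- if (i < n) s1[i + 1] else Inf
    cand <- s2[s2 > s1[i] & s2 < upper]
    if (!is.null(cfg$min_s1_s2_gap_s)) {
      cand <- cand[cand - s1[i] >= cfg$min_s1_s2_gap_s]
    }
    if (length(cand) == 1) paired_s2[i] <- cand
  }
  retained <- which(!is.na(paired_s2))

  t11 <- rep(NA_real_, length(retained))
  for (k in seq_along(retained)) {
    i <- retained[k]
    if ((i + 1) %in% retained) t11[k] <- s1[i + 1] - s1[i]
  }

  cyc <- tibble(
    s1_time_s = s1[retained],
    s2_time_s = paired_s2[retained],
    t11_s = t11,
    t12_s = paired_s2[retained] - s1[retained],
    t21_s = t11 - (paired_s2[retained] - s1[retained]),
    t1_width_s = NA_real_,
    t2_width_s = NA_real_
  )
  if (!is.null(see) && nrow(cyc) > 0) {
    cyc$t1_width_s <- vapply(cyc$s1_time_s, measure_width, numeric(1),
                             see = see, cfg = cfg)
    cyc$t2_width_s <- vapply(cyc$s2_time_s, measure_width, numeric(1),
                             see = see, cfg = cfg)
  }
  class(cyc) <- c("pcg_cycles", class(cyc))
  cyc
}

#' Heart sound width on the Shannon energy envelope
#'
#' Locates the envelope peak nearest `event_time` (within
#' `width_search_s`) and returns the length of the maximal contiguous
#' region around that peak where the envelope stays at or above
#' `width_threshold` (20%) of the local peak value.  The widths T1 and T2
#' are measured this way on the Shannon energy envelope, not on the onset
#' strength envelope.
#'
#' @param see A `pcg_envelope`.
#' @param event_time Event time in seconds (must lie within the envelope
#'   span).
#' @param cfg A [segmentation_config()].
#' @return Width in seconds, or `NA` when no envelope peak lies within the
#'   search window (the cycle is retained with the width absent).
#' @export
measure_width <- function(see, event_time, cfg = segmentation_config()) {
  stopifnot(inherits(see, "pcg_envelope"))
  v <- see$value
  t <- see$time_s
  n <- length(v)
  if (event_time < t[1] - cfg$width_search_s ||
      event_time > t[n] + cfg$width_search_s) {
    abort_parameter("`event_time` lies outside the envelope span.")
  }
  idx <- which(abs(t - event_time) <= cfg$width_search_s)
  if (length(idx) == 0) return(NA_real_)
  floor_v <- 0.25 * max(v[idx])
  is_peak <- vapply(idx, function(i) {
    left <- if (i > 1) v[i - 1] else -Inf
    right <- if (i < n) v[i + 1] else -Inf
    v[i] >= left && v[i] >= right && v[i] > 0 && v[i] >= floor_v
  }, logical(1))
  peaks <- idx[is_peak]
  if (length(peaks) == 0) return(NA_real_)
  p <- peaks[which.min(abs(t[peaks] - event_time))]

  thr <- cfg$width_threshold * v[p]
  i1 <- p
  while (i1 > 1 && v[i1 - 1] >= thr) i1 <- i1 - 1
  i2 <- p
  while (i2 < n && v[i2 + 1] >= thr) i2 <- i2 + 1
  hop <- attr(see, "hop_s") %||% (t[2] - t[1])
  (i2 - i1 + 1) * hop
}
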
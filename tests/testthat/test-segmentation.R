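test_that("weighting function matches its closed forms", {
  cfg <- segmentation_config(sigma_s = 0.05)

  # single beat, evaluated at the beat time
  expect_equal(weighting_function(1.0, 1.0, cfg), 0.2, tolerance = 1e-12)

  # far from all beats the weight is 1 within a Gaussian tail
  w_far <- weighting_function(1.0 + 6 * 0.05, 1.0, cfg)
  expect_gte(w_far, 1 - 0.8 * exp(-18))
  expect_lte(abs(w_far - 1), 1e-7)

  # two beats 0.5 s apart, midpoint
  w_mid <- weighting_function(0.25, c(0, 0.5), cfg)
  expect_equal(w_mid, 1 - 1.6 * exp(-12.5), tolerance = 1e-12)

  # empty beat list: constant one
  expect_equal(weighting_function(c(0, 1, 2), numeric(0), cfg),
               rep(1, 3))
})

test_that("suppression dips to the trough depth and leaves far frames alone", {
  fr <- 16
  s <- rep(0.5, 200)
  ose <- onset_envelope(s, fr)
  beat <- ose$time_s[100]
  sup <- suppress_beats(ose, beat)

  expect_equal(sup$strength[100], 0.2 * 0.5, tolerance = 1e-9)
  far <- abs(ose$time_s - beat) > 6 * segmentation_config()$sigma_s
  expect_lt(max(abs(sup$strength[far] / ose$strength[far] - 1)), 1e-6)
})

test_that("suppressing the first sequence lets tracking recover the second", {
  withr::local_seed(123)
  hits <- vapply(1:8, function(k) {
    fr <- 16
    s <- numeric(40 * fr)
    onA <- seq(4, length(s) - 2, by = 14)
    onB <- onA + 5
    s[onA] <- 1
    s[onB] <- 0.7
    ose <- onset_envelope(s, fr)
    tempo <- 60 * fr / 14
    bA <- track_beats(ose, tempo)
    sup <- suppress_beats(ose, bA)
    bB <- track_beats(sup, tempo)
    idxB <- round((bB$beat_time_s - ose$time_s[1]) * fr) + 1
    mean(vapply(onB, function(i) any(abs(idxB - i) <= 1), logical(1)))
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("two-pass extraction returns both sequences on clean audio", {
  sim <- synthesize(synthetic_spec(duration_s = 50,
                                   hr_profile = hr_constant(72),
                                   noise_snr_db = 30, seed = 77))
  pre <- preprocess(sim$audio)
  seqs <- extract_two_sequences(pre)
  n_true <- length(sim$truth$s1_times)
  expect_gte(nrow(seqs$first), n_true - 2)
  expect_lte(nrow(seqs$first), n_true + 2)
  expect_gte(nrow(seqs$second), n_true - 2)
  expect_lte(nrow(seqs$second), n_true + 2)
})

test_that("a pure tone yields an insufficient-beats error", {
  expect_error(
    extract_two_sequences(preprocess(tone_audio(200, 12, fs = 32000))),
    class = "phonoseg_insufficient_data_error"
  )
})

test_that("with a louder S2 the first pass captures the S2 sequence", {
  spec <- synthetic_spec(
    duration_s = 40, hr_profile = hr_constant(70),
    s1_burst = list(center_freq_hz = 80, width_s = 0.10, amplitude = 0.6),
    s2_burst = list(center_freq_hz = 150, width_s = 0.07, amplitude = 1.0),
    noise_snr_db = 25, seed = 21
  )
  sim <- synthesize(spec)
  seqs <- extract_two_sequences(preprocess(sim$audio))
  close <- vapply(seqs$first$beat_time_s, function(t) {
    min(abs(sim$truth$s2_times - t)) <= 0.03
  }, logical(1))
  expect_gte(mean(close), 0.95)
})

test_that("infrasonic energy in forward intervals decides the S1 label", {
  fs <- 2000
  dur <- 12
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  a_times <- seq(0.5, dur - 1, by = 0.9)
  b_times <- a_times + 0.3
  for (i in seq_along(a_times)) {
    seg <- t >= a_times[i] & t <= b_times[i]
    x[seg] <- x[seg] + 0.3 * sin(2 * pi * 10 * t[seg])
    x <- x + 0.2 * exp(-(t - a_times[i])^2 / (2 * 0.01^2)) +
      0.2 * exp(-(t - b_times[i])^2 / (2 * 0.01^2))
  }
  audio <- pcg_audio(x, fs)
  lab <- identify_s1(a_times, b_times, audio)
  expect_identical(lab$s1_source, "a")
  expect_identical(lab$s1_times, a_times)
  expect_gte(lab$label_confidence, 0.5)
})

test_that("a sub-refractory separation disqualifies a sequence as S1", {
  fs <- 2000
  dur <- 12
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  a_times <- seq(0.5, dur - 1, by = 0.9)
  b_times <- a_times + 0.3
  b_times[5] <- b_times[4] + 0.15      # violates the 0.22 s floor
  for (i in seq_along(b_times)) {
    seg <- t >= b_times[i] & t <= b_times[i] + 0.4
    x[seg] <- x[seg] + 0.3 * sin(2 * pi * 10 * t[seg])
  }
  # infrasonic energy favours B, but B's timing disqualifies it
  lab <- identify_s1(a_times, sort(b_times), pcg_audio(x, fs))
  expect_identical(lab$s1_source, "a")
})

test_that("both sequences failing the screen is an unlabelable error", {
  bad1 <- c(0.5, 0.6, 0.7, 0.8)       # all separations below 0.22 s
  bad2 <- c(1.0, 1.1, 1.2, 1.3)
  audio <- pcg_audio(rnorm(32000, sd = 0.1), 8000)
  expect_error(identify_s1(bad1, bad2, audio),
               class = "phonoseg_unlabelable_error")
})

test_that("pairing keeps bijective interleaves and drops unpaired beats", {
  s1 <- seq(0.5, 20, by = 0.8)
  s2 <- s1 + 0.3
  lab <- structure(list(s1_times = s1, s2_times = s2,
                        label_confidence = 1), class = "pcg_labeled")
  cyc <- pair_beats(lab)
  expect_identical(nrow(cyc), length(s1))
  expect_equal(cyc$t12_s, rep(0.3, length(s1)), tolerance = 1e-12)

  # dropping one middle S2 drops exactly that S1
  lab2 <- lab
  lab2$s2_times <- s2[-10]
  cyc2 <- pair_beats(lab2)
  expect_identical(nrow(cyc2), length(s1) - 1L)
  expect_false(s1[10] %in% cyc2$s1_time_s)
})

test_that("pairing with random deletions equals the interval-matching oracle", {
  withr::local_seed(31)
  for (rep in 1:10) {
    s1 <- seq(0.5, 30, by = 0.85) + rnorm(35, 0, 0.01)[1:35]
    s1 <- sort(s1[!is.na(s1)])
    s2 <- s1 + 0.3
    keep1 <- runif(length(s1)) > 0.1
    keep2 <- runif(length(s2)) > 0.1
    lab <- structure(list(s1_times = s1[keep1], s2_times = s2[keep2],
                          label_confidence = 1), class = "pcg_labeled")
    cyc <- pair_beats(lab)
    oracle <- pair_oracle(s1[keep1], s2[keep2])
    expect_equal(cyc$s1_time_s, oracle$s1)
    expect_equal(cyc$s2_time_s, oracle$s2)
  }
})

test_that("t21 equals t11 minus t12 exactly wherever t11 exists", {
  sim <- synthesize(synthetic_spec(duration_s = 30, seed = 8))
  rep <- analyze(sim$audio)
  cyc <- rep$cycles
  ok <- !is.na(cyc$t11_s)
  expect_gt(sum(ok), 10)
  expect_identical(cyc$t21_s[ok], cyc$t11_s[ok] - cyc$t12_s[ok])
})

test_that("width measurement matches the Gaussian 20% crossing", {
  hop <- 0.01
  tt <- seq(0, 2, by = hop)
  s <- 0.04
  env <- energy_envelope(exp(-(tt - 1)^2 / (2 * s^2)), tt)
  w <- measure_width(env, 1.0)
  expect_lt(abs(w - 2 * s * sqrt(2 * log(5))), hop + 1e-9)
})

test_that("width of a rectangular burst is its duration within one window", {
  hop <- 0.01
  tt <- seq(0, 2, by = hop)
  v <- as.numeric(tt >= 0.8 & tt <= 1.2)
  env <- energy_envelope(v, tt)
  expect_lt(abs(measure_width(env, 1.0) - 0.4), 0.021)
})

test_that("width regions do not bridge two separate bursts", {
  hop <- 0.01
  tt <- seq(0, 2, by = hop)
  s <- 0.03
  v <- exp(-(tt - 0.8)^2 / (2 * s^2)) + exp(-(tt - 1.2)^2 / (2 * s^2))
  env <- energy_envelope(v, tt)
  w <- measure_width(env, 0.8)
  expect_lt(w, 0.3)
  expect_lt(abs(w - 2 * s * sqrt(2 * log(5))), 2 * hop)
})

test_that("events without a nearby envelope peak give an absent width", {
  hop <- 0.01
  tt <- seq(0, 2, by = hop)
  v <- exp(-(tt - 0.3)^2 / (2 * 0.03^2))
  env <- energy_envelope(v, tt)
  expect_true(is.na(measure_width(env, 1.5)))
  expect_error(measure_width(env, 5), class = "phonoseg_parameter_error")
})
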
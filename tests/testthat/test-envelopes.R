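test_that("frame geometry follows the eighth-second window rule", {
  a <- pcg_audio(rnorm(32000), 32000)
  f <- spectral_frames(a)
  expect_identical(f$window_len_samples, 4000L)
  expect_identical(f$hop_samples, 2000L)
  expect_identical(ncol(f$band_power), 20L)
  expect_true(all(diff(f$frame_times) == f$hop_samples / 32000))

  expect_error(spectral_frames(pcg_audio(rnorm(1000), 32000)),
               class = "phonoseg_insufficient_data_error")
})

test_that("an all-zero signal yields zero band power and zero flux", {
  a <- pcg_audio(numeric(32000) , 32000)
  f <- spectral_frames(a)
  expect_true(all(f$band_power == 0))
  expect_true(all(onset_strength(f)$strength == 0))
})

test_that("a 125 Hz tone concentrates its power in the 100-150 Hz band", {
  a <- tone_audio(125, duration_s = 1, fs = 32000)
  f <- spectral_frames(a, compression = "linear")
  total <- colSums(t(f$band_power))
  expect_gte(sum(f$band_power[, 3]) / sum(f$band_power), 0.95)
  expect_length(total, nrow(f$band_power))
})

test_that("onset strength equals a literal re-evaluation of the flux sum", {
  withr::local_seed(42)
  for (rep in 1:10) {
    m <- matrix(runif(5 * 20, 0, 3), nrow = 5)
    got <- onset_strength(frames_from_matrix(m), normalize = FALSE)
    # summation order differs between the vectorized path and the literal
    # loop, so agreement is to machine precision rather than bit-for-bit
    expect_equal(got$strength, flux_oracle(m), tolerance = 1e-14)
  }
})

test_that("single-band two-frame difference d gives flux d^2", {
  m <- matrix(1, nrow = 2, ncol = 20)
  m[2, 7] <- 1 + 0.37
  got <- onset_strength(frames_from_matrix(m), normalize = FALSE)
  expect_equal(got$strength, 0.37^2)

  # stationary spectrum: identical frames give zero everywhere
  m0 <- matrix(runif(20), nrow = 4, ncol = 20, byrow = TRUE)
  expect_true(all(
    onset_strength(frames_from_matrix(m0), normalize = FALSE)$strength == 0
  ))
})

test_that("flux is polarity-invariant and scales as the fourth power", {
  sim <- synthesize(synthetic_spec(duration_s = 5, seed = 3))
  x <- sim$audio
  neg <- pcg_audio(-x$samples, x$sample_rate_hz)
  f_pos <- spectral_frames(x, compression = "linear")
  f_neg <- spectral_frames(neg, compression = "linear")
  expect_equal(f_pos$band_power, f_neg$band_power)

  g1 <- onset_strength(f_pos, normalize = FALSE)$strength
  scaled <- pcg_audio(2 * x$samples, x$sample_rate_hz)
  g2 <- onset_strength(spectral_frames(scaled, compression = "linear"),
                       normalize = FALSE)$strength
  expect_equal(g2, 2^4 * g1, tolerance = 1e-9)

  # the normalized log-scale envelope is invariant to overall gain
  n1 <- onset_strength(spectral_frames(x))$strength
  n2 <- onset_strength(spectral_frames(scaled))$strength
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("Shannon energy closed forms hold", {
  fs <- 1000
  zero <- pcg_audio(numeric(fs), fs)
  expect_true(all(shannon_energy_envelope(zero)$value == 0))

  ones <- pcg_audio(rep(1, fs), fs)
  see1 <- shannon_energy_envelope(ones, normalize_input = FALSE,
                                  normalize = FALSE)
  expect_true(all(abs(see1$value) < 1e-12))

  const <- pcg_audio(rep(exp(-0.5), fs), fs)
  see <- shannon_energy_envelope(const, normalize_input = FALSE,
                                 normalize = FALSE)
  expect_equal(see$value, rep(1 / exp(1), length(see$value)),
               tolerance = 1e-12)

  expect_error(shannon_energy_envelope(ones, window_s = 0),
               class = "phonoseg_parameter_error")
})

test_that("the Shannon envelope of one clean burst has a single main peak", {
  fs <- 4000
  t <- seq(0, 1, by = 1 / fs)
  x <- exp(-(t - 0.5)^2 / (2 * 0.03^2)) * sin(2 * pi * 300 * t)
  see <- shannon_energy_envelope(pcg_audio(x, fs))
  v <- see$value
  # One contiguous main lobe centred on the burst.  (Strict single-peak
  # unimodality cannot hold for a peak-normalized burst: the Shannon
  # function -x^2 log x^2 is maximal at |x| = exp(-1/2), so full-scale
  # sample values dimple the lobe's very top.)
  lobe <- which(v >= 0.3)
  expect_true(all(diff(lobe) == 1))
  expect_lte(abs(see$time_s[which.max(v)] - 0.5), 0.021)
  expect_lt(max(v[see$time_s < 0.3 | see$time_s > 0.7]), 0.05)
})
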
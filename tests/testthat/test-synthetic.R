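test_that("a 50 s record at a constant 72 bpm holds 60 cycles", {
  spec <- synthetic_spec(duration_s = 50, hr_profile = hr_constant(72),
                         beat_jitter_s = 0, seed = 1)
  sim <- synthesize(spec)
  expect_identical(length(sim$truth$s1_times), 60L)
  expect_identical(length(sim$truth$s2_times), 60L)
})

test_that("constant rates from 66 to 120 bpm give 55 to 100 cycles", {
  for (bpm in c(66, 80, 100, 120)) {
    spec <- synthetic_spec(duration_s = 50, hr_profile = hr_constant(bpm),
                           beat_jitter_s = 0, seed = 2)
    n <- length(synthesize(spec)$truth$s1_times)
    expect_gte(n, 55)
    expect_lte(n, 100)
  }
})

test_that("the same seed reproduces audio and truth bit for bit", {
  spec <- synthetic_spec(duration_s = 10, noise_snr_db = 10, seed = 33)
  a <- synthesize(spec)
  b <- synthesize(spec)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_identical(a$truth, b$truth)

  other <- synthesize(synthetic_spec(duration_s = 10, noise_snr_db = 10,
                                     seed = 34))
  expect_false(identical(a$audio$samples, other$audio$samples))
})

test_that("synthesis does not disturb the caller's random stream", {
  set.seed(500)
  before <- runif(1)
  set.seed(500)
  invisible(synthesize(synthetic_spec(duration_s = 5, seed = 77)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("truth respects the configured systolic fraction and interleaves", {
  spec <- synthetic_spec(duration_s = 30, systolic_fraction = 0.32,
                         seed = 12)
  tr <- synthesize(spec)$truth
  n <- length(tr$t11_series)
  frac <- tr$t12_series[seq_len(n)] / tr$t11_series
  expect_lt(max(abs(frac - 0.32)), 1e-9)
  inter <- head(tr$s2_times, n) > head(tr$s1_times, n) &
    head(tr$s2_times, n) < tr$s1_times[-1]
  expect_true(all(inter))
})

test_that("generated audio is already band-limited below the cutoff", {
  sim <- synthesize(synthetic_spec(duration_s = 10, noise_snr_db = 10,
                                   seed = 3))
  pre <- preprocess(sim$audio)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(pre$samples) / rms(sim$audio$samples) - 1), 0.02)
})

test_that("invalid specs report the violated bounds", {
  expect_error(synthetic_spec(duration_s = -1),
               class = "phonoseg_parameter_error")
  expect_error(synthetic_spec(systolic_fraction = 0.6),
               class = "phonoseg_parameter_error")
  expect_error(synthetic_spec(hr_profile = hr_constant(300)),
               regexp = "40-220", class = "phonoseg_parameter_error")
})

test_that("detection scoring matches its counting identities", {
  truth <- structure(list(
    s1_times = seq(1, 20, by = 1), s2_times = seq(1.3, 20.3, by = 1)
  ), class = "pcg_truth")

  same <- list(s1_times = truth$s1_times, s2_times = truth$s2_times)
  m <- evaluate_detection(truth, same)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$timing_rmse_s, 0)

  # every 10th event removed: recall 0.9, precision 1
  dec <- list(s1_times = truth$s1_times[-seq(10, 20, by = 10)],
              s2_times = truth$s2_times[-seq(10, 20, by = 10)])
  m2 <- evaluate_detection(truth, dec)
  expect_equal(m2$recall, 0.9)
  expect_equal(m2$precision, 1)

  # a uniform 20 ms shift stays matched with that exact RMSE
  sh <- list(s1_times = truth$s1_times + 0.02,
             s2_times = truth$s2_times + 0.02)
  m3 <- evaluate_detection(truth, sh)
  expect_equal(m3$recall, 1)
  expect_equal(m3$timing_rmse_s, 0.02, tolerance = 1e-12)

  expect_error(evaluate_detection(truth, same, tolerance_s = 0),
               class = "phonoseg_parameter_error")
})

test_that("truth tables round-trip through CSV", {
  sim <- synthesize(synthetic_spec(duration_s = 10, seed = 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(sim$truth, path)
  back <- read_truth_csv(path)
  expect_equal(back$s1_times, sim$truth$s1_times, tolerance = 1e-6)
  expect_equal(back$s2_times, sim$truth$s2_times, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(event = "s1", wrong = 1), bad,
                   row.names = FALSE)
  expect_error(read_truth_csv(bad), regexp = "time_s",
               class = "phonoseg_format_error")
})

test_that("benchmark conditions are deterministic in their seed", {
  a <- benchmark_spec("rest", 5)
  b <- benchmark_spec("rest", 5)
  expect_identical(attr(a$hr_profile, "params"), attr(b$hr_profile, "params"))
  expect_identical(a$systolic_fraction, b$systolic_fraction)
  expect_identical(a$noise_snr_db, 15)
  ex <- benchmark_spec("exercise", 5)
  expect_identical(attr(ex$hr_profile, "type"), "linear")
  expect_identical(ex$noise_snr_db, 6)
  expect_true(is.finite(ex$rumble_snr_db))
})
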
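test_that("instantaneous heart rate is the reciprocal interval", {
  expect_equal(instantaneous_hr(1.0), 60)
  expect_equal(instantaneous_hr(0.5), 120)
  expect_equal(instantaneous_hr(0.857), 60 / 0.857, tolerance = 1e-9)
  expect_error(instantaneous_hr(0), class = "phonoseg_parameter_error")
})

test_that("systole/diastole ratio matches its closed forms", {
  expect_identical(systole_diastole_ratio(1.0, 0.5), 1)
  expect_equal(systole_diastole_ratio(1.0, 0.3), 0.3 / 0.7,
               tolerance = 1e-12)
  expect_lt(systole_diastole_ratio(1.0, 1e-6), 2e-6)
  expect_error(systole_diastole_ratio(1.0, 1.0),
               class = "phonoseg_parameter_error")
})

test_that("the ratio is monotone in t12 and crosses 1 at half the interval", {
  withr::local_seed(2)
  for (rep in 1:20) {
    t11 <- runif(1, 0.4, 1.2)
    t12 <- sort(runif(5, 0.05 * t11, 0.95 * t11))
    r <- systole_diastole_ratio(t11, t12)
    expect_true(all(diff(r) > 0))
    expect_identical(r < 1, t12 < t11 / 2)
  }
})

test_that("success rate counts detected beats against the expected total", {
  expect_equal(success_rate(50, 50, 1.0), 1.0)
  expect_equal(success_rate(95, 50, 0.5), 0.95)
  expect_equal(success_rate(0, 50, 1.0), 0)
  expect_lte(success_rate(200, 50, 1.0), 1)
  expect_error(success_rate(10, 0, 1), class = "phonoseg_parameter_error")

  # monotone non-decreasing in the detected count
  rates <- vapply(0:60, success_rate, numeric(1),
                  duration_s = 50, mean_interval_s = 1)
  expect_true(all(diff(rates) >= 0))
})

test_that("a single-cycle report composes the scalar operations", {
  cyc <- tibble::tibble(
    s1_time_s = 1, s2_time_s = 1.3, t11_s = 1.0, t12_s = 0.3,
    t21_s = 0.7, t1_width_s = 0.1, t2_width_s = 0.08
  )
  rep <- build_report(cyc, duration_s = 2)
  expect_identical(nrow(rep$t12_vs_t11), 1L)
  expect_identical(nrow(rep$width_t2_vs_t1), 1L)
  expect_identical(nrow(rep$ratio_series), 1L)
  expect_equal(rep$ratio_series$r, 0.3 / 0.7, tolerance = 1e-9)
  expect_equal(rep$mean_hr_bpm, 60)

  td <- tidy(rep)
  expect_equal(td$r[1], 0.3 / 0.7, tolerance = 1e-9)
  gl <- glance(rep)
  expect_identical(gl$n_cycles, 1L)
})

test_that("empty cycles give an empty report with zero success rate", {
  empty <- tibble::tibble(
    s1_time_s = numeric(0), s2_time_s = numeric(0), t11_s = numeric(0),
    t12_s = numeric(0), t21_s = numeric(0), t1_width_s = numeric(0),
    t2_width_s = numeric(0)
  )
  rep <- build_report(empty, duration_s = 50)
  expect_identical(rep$success_rate, 0)
  expect_identical(nrow(rep$ratio_series), 0L)
})

test_that("nominal regions are closed: boundary points flag as inside", {
  b <- nominal_bounds(
    ellipse = list(center_t11_s = 0.8, center_t12_s = 0.3,
                   semi_t11_s = 0.2, semi_t12_s = 0.05, angle_deg = 0),
    widths_rect = list(t1_min_s = 0.05, t1_max_s = 0.15,
                       t2_min_s = 0.04, t2_max_s = 0.12)
  )
  cyc <- tibble::tibble(
    s1_time_s = c(1, 2), s2_time_s = c(1.3, 2.4),
    t11_s = c(1.0, 0.3), t12_s = c(0.3, 0.25),
    t21_s = c(0.7, 0.05),
    t1_width_s = c(0.15, 0.3), t2_width_s = c(0.12, 0.3)
  )
  rep <- build_report(cyc, 3, bounds = b)
  # first point: t11 exactly on the ellipse boundary (0.8 + 0.2)
  expect_true(rep$t12_vs_t11$in_nominal[1])
  expect_false(rep$t12_vs_t11$in_nominal[2])
  expect_true(rep$width_t2_vs_t1$in_nominal[1])    # on the rectangle edge
  expect_false(rep$width_t2_vs_t1$in_nominal[2])
})

test_that("a recovery profile yields lengthening heartbeat intervals", {
  spec <- synthetic_spec(
    duration_s = 50,
    hr_profile = hr_recovery(150, 70, tau_s = 20),
    systolic_fraction = 0.4, noise_snr_db = 20, seed = 9
  )
  sim <- synthesize(spec)
  rep <- analyze(sim$audio)
  cyc <- rep$cycles[!is.na(rep$cycles$t11_s), ]
  expect_gt(nrow(cyc), 30)
  fit <- stats::lm(t11_s ~ s1_time_s, data = cyc)
  expect_gt(stats::coef(fit)[2], 0)
  early <- mean(cyc$t11_s[cyc$s1_time_s < 15])
  late <- mean(cyc$t11_s[cyc$s1_time_s > 35])
  expect_gt(late, early)
})

test_that("report series lengths follow the cycles that carry each field", {
  sim <- synthesize(synthetic_spec(duration_s = 20, seed = 4))
  rep <- analyze(sim$audio)
  cyc <- rep$cycles
  expect_identical(nrow(rep$t12_vs_t11), sum(!is.na(cyc$t11_s)))
  expect_identical(nrow(rep$ratio_series), sum(!is.na(cyc$t11_s)))
  expect_identical(nrow(rep$width_t2_vs_t1),
                   sum(!is.na(cyc$t1_width_s) & !is.na(cyc$t2_width_s)))
})

test_that("autoplot returns ggplot objects for every view", {
  sim <- synthesize(synthetic_spec(duration_s = 15, seed = 6))
  rep <- analyze(sim$audio)
  for (type in c("intervals", "t12_t11", "widths", "ratio")) {
    expect_s3_class(autoplot(rep, type = type), "ggplot")
  }
})
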
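#' Instantaneous heart rate from the heartbeat interval
#'
#' The inverse of the S1-to-S1 interval T11, expressed in beats per minute.
#'
#' @param t11_s Heartbeat interval(s) in seconds, positive.
#' @return Heart rate(s) in bpm.
#' @examples
#' instantaneous_hr(1.0)   # 60
#' instantaneous_hr(0.5)   # 120
#' @export
instantaneous_hr <- function(t11_s) {
  if (any(!is.finite(t11_s)) || any(t11_s <= 0)) {
    abort_parameter("`t11_s` must be positive and finite.")
  }
  60 / t11_s
}

#' Systole/diastole ratio
#'
#' \deqn{r = \mathrm{systole} / \mathrm{diastole} = T12 / (T11 - T12)}
#' A ratio below 1 means the systolic interval is shorter than the
#' diastolic interval (T12 < T11 / 2); a reversal above 1 may indicate
#' compromised cardiac filling.
#'
#' @param t11_s Heartbeat interval(s), seconds.
#' @param t12_s Systolic interval(s), seconds, with `0 < t12_s < t11_s`.
#' @return The ratio r (dimensionless, positive).
#' @examples
#' systole_diastole_ratio(1.0, 0.5)  # 1
#' systole_diastole_ratio(1.0, 0.3)  # 0.4286
#' @export
systole_diastole_ratio <- function(t11_s, t12_s) {
  if (any(!is.finite(t11_s)) || any(!is.finite(t12_s)) || any(t12_s <= 0)) {
    abort_parameter("`t11_s` and `t12_s` must be finite with t12_s > 0.")
  }
  if (any(t12_s >= t11_s)) {
    abort_parameter("`t12_s` must be smaller than `t11_s` (diastole > 0).")
  }
  t12_s / (t11_s - t12_s)
}

#' Beat detection success rate
#'
#' The ratio of detected beats to the total number of beats in the record,
#' where the total is inferred from the record duration and the average
#' heartbeat interval (there being no independent beat count), capped at 1.
#'
#' @param detected_count Number of detected beats (non-negative integer).
#' @param duration_s Record duration, seconds, positive.
#' @param mean_interval_s Average heartbeat interval, seconds, positive.
#' @return Success rate in \[0, 1\].
#' @examples
#' success_rate(95, 50, 0.5)  # 0.95
#' @export
success_rate <- function(detected_count, duration_s, mean_interval_s) {
  if (length(detected_count) != 1 || !is.finite(detected_count) ||
      detected_count < 0) {
    abort_parameter("`detected_count` must be a non-negative number.")
  }
  if (!is.finite(duration_s) || duration_s <= 0 ||
      !is.finite(mean_interval_s) || mean_interval_s <= 0) {
    abort_parameter("`duration_s` and `mean_interval_s` must be positive.")
  }
  expected <- max(1, round(duration_s / mean_interval_s))
  min(1, detected_count / expected)
}

#' Nominal parameter regions
#'
#' Describes the reference regions drawn on the diagnostic plots: a tilted
#' ellipse in the (T11, T12) plane and a rectangle in the (T1, T2) width
#' plane.  These are user configuration for visual reference only — they
#' are not validated medical ranges, and no defaults are hard-coded beyond
#' this explicitly user-supplied structure.  Points exactly on a boundary
#' count as inside (closed regions).
#'
#' @param ellipse Named list or vector with `center_t11_s`, `center_t12_s`,
#'   `semi_t11_s`, `semi_t12_s`, `angle_deg` (rotation of the T11
#'   semi-axis, counter-clockwise).
#' @param widths_rect Named list or vector with `t1_min_s`, `t1_max_s`,
#'   `t2_min_s`, `t2_max_s`.
#' @return A `nominal_bounds` list.
#' @seealso [read_nominal_bounds()] for loading from YAML; an example file
#'   ships in `system.file("extdata", "nominal_bounds.yaml", package =
#'   "phonoseg")`.
#' @export
nominal_bounds <- function(ellipse = NULL, widths_rect = NULL) {
  if (!is.null(ellipse)) {
    ellipse <- as.list(ellipse)
    need <- c("center_t11_s", "center_t12_s", "semi_t11_s", "semi_t12_s",
              "angle_deg")
    missing <- setdiff(need, names(ellipse))
    if (length(missing) > 0) {
      abort_parameter(sprintf("`ellipse` is missing fields: %s",
                              paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(widths_rect)) {
    widths_rect <- as.list(widths_rect)
    need <- c("t1_min_s", "t1_max_s", "t2_min_s", "t2_max_s")
    missing <- setdiff(need, names(widths_rect))
    if (length(missing) > 0) {
      abort_parameter(sprintf("`widths_rect` is missing fields: %s",
                              paste(missing, collapse = ", ")))
    }
  }
  structure(list(ellipse = ellipse, widths_rect = widths_rect),
            class = "nominal_bounds")
}

#' Read nominal bounds from a YAML file
#'
#' @param path Path to a YAML file with top-level keys `ellipse` and/or
#'   `widths_rect` matching the fields of [nominal_bounds()].
#' @return A `nominal_bounds` list.
#' @export
read_nominal_bounds <- function(path) {
  if (!file.exists(path)) {
    abort_format(sprintf("Nominal bounds file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  extra <- setdiff(names(y), c("ellipse", "widths_rect"))
  if (length(extra) > 0) {
    abort_format(sprintf("Unknown keys in nominal bounds file: %s",
                         paste(extra, collapse = ", ")))
  }
  nominal_bounds(ellipse = y$ellipse, widths_rect = y$widths_rect)
}

# TRUE when (t11, t12) lies inside or on the configured ellipse.
inside_ellipse <- function(t11, t12, e) {
  th <- e$angle_deg * pi / 180
  dx <- t11 - e$center_t11_s
  dy <- t12 - e$center_t12_s
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / e$semi_t11_s)^2 + (v / e$semi_t12_s)^2 <= 1 + 1e-12
}

inside_rect <- function(t1, t2, r) {
  t1 >= r$t1_min_s & t1 <= r$t1_max_s & t2 >= r$t2_min_s & t2 <= r$t2_max_s
}

#' Build a diagnostic report from heart cycles
#'
#' Assembles the display series of the diagnostic parameters: systolic
#' duration T12 versus heartbeat interval T11, S2 width T2 versus S1 width
#' T1, and the systole/diastole ratio r as a time series; plus the mean
#' heart rate (from the median T11, robust to missed beats) and the beat
#' detection [success_rate()] computed from the cycle count, the record
#' duration and the median detected T11.  When `bounds` are supplied, each
#' point is flagged inside/outside the nominal region (closed regions:
#' boundary points count as inside).
#'
#' @param cycles A `pcg_cycles` tibble from [pair_beats()] (may be empty).
#' @param duration_s Record duration in seconds.
#' @param bounds Optional [nominal_bounds()].
#' @return A `pcg_report` object: list with `cycles`, `t12_vs_t11`,
#'   `width_t2_vs_t1`, `ratio_series`, `mean_hr_bpm`, `success_rate`,
#'   `duration_s` and `bounds`.  Empty cycles yield an empty report with
#'   success rate 0.
#' @export
build_report <- function(cycles, duration_s, bounds = NULL) {
  stopifnot(is.data.frame(cycles))
  has_t11 <- !is.na(cycles$t11_s)

  t12_vs_t11 <- tibble(
    t11_s = cycles$t11_s[has_t11],
    t12_s = cycles$t12_s[has_t11],
    in_nominal = NA
  )
  if (!is.null(bounds) && !is.null(bounds$ellipse) && nrow(t12_vs_t11) > 0) {
    t12_vs_t11$in_nominal <- inside_ellipse(
      t12_vs_t11$t11_s, t12_vs_t11$t12_s, bounds$ellipse
    )
  }

  has_w <- !is.na(cycles$t1_width_s) & !is.na(cycles$t2_width_s)
  width_t2_vs_t1 <- tibble(
    t1_width_s = cycles$t1_width_s[has_w],
    t2_width_s = cycles$t2_width_s[has_w],
    in_nominal = NA
  )
  if (!is.null(bounds) && !is.null(bounds$widths_rect) &&
      nrow(width_t2_vs_t1) > 0) {
    width_t2_vs_t1$in_nominal <- inside_rect(
      width_t2_vs_t1$t1_width_s, width_t2_vs_t1$t2_width_s,
      bounds$widths_rect
    )
  }

  ratio_series <- tibble(
    time_s = cycles$s1_time_s[has_t11],
    r = if (any(has_t11)) {
      systole_diastole_ratio(cycles$t11_s[has_t11], cycles$t12_s[has_t11])
    } else {
      numeric(0)
    }
  )

  med_t11 <- median(cycles$t11_s, na.rm = TRUE)
  mean_hr <- if (is.finite(med_t11)) instantaneous_hr(med_t11) else NA_real_
  rate <- if (nrow(cycles) > 0 && is.finite(med_t11)) {
    success_rate(nrow(cycles), duration_s, med_t11)
  } else {
    0
  }

  structure(
    list(
      cycles = cycles,
      t12_vs_t11 = t12_vs_t11,
      width_t2_vs_t1 = width_t2_vs_t1,
      ratio_series = ratio_series,
      mean_hr_bpm = mean_hr,
      success_rate = rate,
      duration_s = duration_s,
      bounds = bounds
    ),
    class = "pcg_report"
  )
}

#' @export
print.pcg_report <- function(x, ...) {
  cat(sprintf(
    paste0("<pcg_report: %d cycles over %.1f s, mean HR %.1f bpm, ",
           "success rate %.3f>\n"),
    nrow(x$cycles), x$duration_s, x$mean_hr_bpm, x$success_rate
  ))
  invisible(x)
}

#' Tidy a diagnostic report into a per-cycle tibble
#'
#' @param x A `pcg_report`.
#' @param ... Unused.
#' @return The cycle table with the instantaneous heart rate (`hr_bpm`) and
#'   systole/diastole ratio (`r`) added for cycles that carry T11.
#' @export
tidy.pcg_report <- function(x, ...) {
  cyc <- as_tibble(x$cycles)
  ok <- !is.na(cyc$t11_s)
  cyc$hr_bpm <- ifelse(ok, 60 / cyc$t11_s, NA_real_)
  cyc$r <- ifelse(ok, cyc$t12_s / (cyc$t11_s - cyc$t12_s), NA_real_)
  cyc
}

#' One-row summary of a diagnostic report
#'
#' @param x A `pcg_report`.
#' @param ... Unused.
#' @return A one-row tibble: cycle count, mean heart rate, median T11, T12,
#'   T21, widths, mean ratio, and success rate.
#' @export
glance.pcg_report <- function(x, ...) {
  cyc <- x$cycles
  tibble(
    n_cycles = nrow(cyc),
    mean_hr_bpm = x$mean_hr_bpm,
    median_t11_s = median(cyc$t11_s, na.rm = TRUE),
    median_t12_s = median(cyc$t12_s, na.rm = TRUE),
    median_t21_s = median(cyc$t21_s, na.rm = TRUE),
    median_t1_width_s = median(cyc$t1_width_s, na.rm = TRUE),
    median_t2_width_s = median(cyc$t2_width_s, na.rm = TRUE),
    mean_ratio = if (nrow(x$ratio_series) > 0) mean(x$ratio_series$r)
                 else NA_real_,
    success_rate = x$success_rate
  )
}
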
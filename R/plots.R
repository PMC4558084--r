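#' Plot a diagnostic report
#'
#' Optional display artifacts mirroring the standard presentation of the
#' diagnostic parameters:
#' * `"intervals"` — T11 and T12 versus time (trend view; in a recovery
#'   recording both rise as the heart rate falls);
#' * `"t12_t11"` — systolic duration T12 against heartbeat interval T11,
#'   with the nominal ellipse when bounds are configured;
#' * `"widths"` — S2 width T2 against S1 width T1, with the nominal
#'   rectangle when configured;
#' * `"ratio"` — the systole/diastole ratio r over time.
#'
#' @param object A `pcg_report`.
#' @param type Which view to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcg_report <- function(object,
                                type = c("intervals", "t12_t11", "widths",
                                         "ratio"),
                                ...) {
  type <- match.arg(type)
  cyc <- object$cycles
  switch(
    type,
    intervals = {
      ok <- !is.na(cyc$t11_s)
      df <- dplyr::bind_rows(
        tibble(time_s = cyc$s1_time_s[ok], value_s = cyc$t11_s[ok],
               interval = "T11 (heartbeat)"),
        tibble(time_s = cyc$s1_time_s, value_s = cyc$t12_s,
               interval = "T12 (systole)")
      )
      ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value_s,
                                       colour = .data$interval)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "time (s)", y = "interval (s)", colour = NULL) +
        ggplot2::theme_minimal()
    },
    t12_t11 = {
      p <- ggplot2::ggplot(object$t12_vs_t11,
                           ggplot2::aes(.data$t11_s, .data$t12_s)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "T11, heartbeat interval (s)",
                      y = "T12, systolic duration (s)") +
        ggplot2::theme_minimal()
      e <- object$bounds$ellipse
      if (!is.null(e)) {
        p <- p + ggplot2::geom_path(data = ellipse_path(e),
                                    ggplot2::aes(.data$t11_s, .data$t12_s),
                                    linetype = 2, colour = "grey40")
      }
      p
    },
    widths = {
      p <- ggplot2::ggplot(object$width_t2_vs_t1,
                           ggplot2::aes(.data$t1_width_s, .data$t2_width_s)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "T1, S1 width (s)", y = "T2, S2 width (s)") +
        ggplot2::theme_minimal()
      r <- object$bounds$widths_rect
      if (!is.null(r)) {
        p <- p + ggplot2::annotate(
          "rect", xmin = r$t1_min_s, xmax = r$t1_max_s,
          ymin = r$t2_min_s, ymax = r$t2_max_s,
          fill = NA, colour = "grey40", linetype = 2
        )
      }
      p
    },
    ratio = {
      ggplot2::ggplot(object$ratio_series,
                      ggplot2::aes(.data$time_s, .data$r)) +
        ggplot2::geom_line(colour = "grey70") +
        ggplot2::geom_point(size = 1) +
        ggplot2::geom_hline(yintercept = 1, linetype = 3) +
        ggplot2::labs(x = "time (s)", y = "r = T12 / (T11 - T12)") +
        ggplot2::theme_minimal()
    }
  )
}

ellipse_path <- function(e, n = 181) {
  th <- e$angle_deg * pi / 180
  phi <- seq(0, 2 * pi, length.out = n)
  u <- e$semi_t11_s * cos(phi)
  v <- e$semi_t12_s * sin(phi)
  tibble(
    t11_s = e$center_t11_s + u * cos(th) - v * sin(th),
    t12_s = e$center_t12_s + u * sin(th) + v * cos(th)
  )
}

#' Plot an onset strength envelope with optional beats
#'
#' @param object A `pcg_onset` envelope.
#' @param beats Optional `pcg_beats` to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcg_onset <- function(object, beats = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$time_s, .data$strength)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "onset strength") +
    ggplot2::theme_minimal()
  if (!is.null(beats)) {
    p <- p + ggplot2::geom_vline(xintercept = beat_times(beats),
                                 colour = "red", alpha = 0.5)
  }
  p
}
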
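#' Pipeline configuration
#'
#' Aggregates the stage configurations of the full analysis pipeline:
#' preprocessing -> onset strength envelope -> two-pass beat extraction ->
#' S1 identification -> pairing -> report.
#'
#' @param cutoff_hz Low-pass cutoff of the preprocessing stage (default
#'   1000 Hz).
#' @param analysis_rate_hz Analysis sample rate (default 32000 Hz).
#' @param highpass_hz Optional high-pass corner (default `NULL`, off).
#' @param tracker A [tracker_config()].
#' @param segmentation A [segmentation_config()].
#' @param bounds Optional [nominal_bounds()] for report flagging.
#' @param refine Snap beat times to Shannon-envelope peaks (default `TRUE`).
#' @param reestimate_tempo Re-estimate tempo before the second pass
#'   (default `FALSE`; see [extract_two_sequences()]).
#' @param tolerance_s Event-matching tolerance used by
#'   [evaluate_recording()] (default 0.05 s).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cutoff_hz = 1000,
                            analysis_rate_hz = 32000,
                            highpass_hz = NULL,
                            tracker = tracker_config(),
                            segmentation = segmentation_config(),
                            bounds = NULL,
                            refine = TRUE,
                            reestimate_tempo = FALSE,
                            tolerance_s = 0.05) {
  structure(
    list(
      cutoff_hz = cutoff_hz, analysis_rate_hz = analysis_rate_hz,
      highpass_hz = highpass_hz, tracker = tracker,
      segmentation = segmentation, bounds = bounds, refine = refine,
      reestimate_tempo = reestimate_tempo, tolerance_s = tolerance_s
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `cutoff_hz`, `analysis_rate_hz`,
#' `highpass_hz`, `tracker`, `segmentation`, `bounds`, `refine`,
#' `reestimate_tempo`, `tolerance_s`; nested keys must match the arguments
#' of [tracker_config()], [segmentation_config()] and [nominal_bounds()].
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_format(sprintf("Config file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  known <- c("cutoff_hz", "analysis_rate_hz", "highpass_hz", "tracker",
             "segmentation", "bounds", "refine", "reestimate_tempo",
             "tolerance_s")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0) {
    abort_format(sprintf("Unknown config keys: %s",
                         paste(extra, collapse = ", ")))
  }
  check_sub <- function(sub, fn, label) {
    if (is.null(sub)) return(NULL)
    extra <- setdiff(names(sub), names(formals(fn)))
    if (length(extra) > 0) {
      abort_format(sprintf("Unknown %s config keys: %s", label,
                           paste(extra, collapse = ", ")))
    }
    do.call(fn, sub)
  }
  args <- y
  args$tracker <- check_sub(y$tracker, tracker_config, "tracker")
  args$segmentation <- check_sub(y$segmentation, segmentation_config,
                                 "segmentation")
  args$bounds <- if (!is.null(y$bounds)) {
    nominal_bounds(ellipse = y$bounds$ellipse,
                   widths_rect = y$bounds$widths_rect)
  }
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(pipeline_config, args)
}

#' Analyze a PCG recording end to end
#'
#' Runs the full pipeline: preprocessing (resample + 1000 Hz low-pass),
#' onset strength envelope, two-pass beat extraction with suppression of
#' the first sequence, S1 identification, pairing into heart cycles, and
#' report building.  The pipeline contains no unseeded randomness: a fixed
#' input and configuration always produce identical output.
#'
#' @param input A WAV file path or a [pcg_audio()] object.
#' @param config A [pipeline_config()].
#' @param report_json,cycles_csv Optional output paths; when given, the
#'   report and the per-cycle table are written there.
#' @return A `pcg_report` (see [build_report()]) with additional elements
#'   `labeled` (the `pcg_labeled` beats), `sequences` (both extracted
#'   sequences) and `tempo_bpm` (first-pass global tempo).
#' @export
analyze <- function(input, config = pipeline_config(),
                    report_json = NULL, cycles_csv = NULL) {
  audio <- if (inherits(input, "pcg_audio")) input else read_wav(input)
  pre <- preprocess(audio, cutoff_hz = config$cutoff_hz,
                    analysis_rate_hz = config$analysis_rate_hz,
                    highpass_hz = config$highpass_hz)
  seqs <- extract_two_sequences(
    pre, tracker_cfg = config$tracker, seg_cfg = config$segmentation,
    refine = config$refine, reestimate_tempo = config$reestimate_tempo
  )
  labeled <- identify_s1(seqs$first, seqs$second, pre, config$segmentation)
  cycles <- pair_beats(labeled, seqs$see, config$segmentation)
  report <- build_report(cycles, duration(pre), config$bounds)
  report$labeled <- labeled
  report$sequences <- seqs[c("first", "second")]
  report$tempo_bpm <- attr(seqs$raw$first, "tempo_bpm")

  if (!is.null(cycles_csv)) write_cycles_csv(cycles, cycles_csv)
  if (!is.null(report_json)) write_report_json(report, report_json)
  report
}

#' Analyze a recording and score it against ground truth
#'
#' @param input A WAV file path or [pcg_audio()].
#' @param truth A `pcg_truth` or a truth CSV path (see [read_truth_csv()]).
#' @param config A [pipeline_config()].
#' @return A one-row tibble from [evaluate_detection()] with the median
#'   absolute T11 and T12 errors of matched cycles appended
#'   (`t11_mae_s`, `t12_mae_s`).
#' @export
evaluate_recording <- function(input, truth, config = pipeline_config()) {
  if (is.character(truth)) truth <- read_truth_csv(truth)
  report <- analyze(input, config)
  metrics <- evaluate_detection(truth, report$labeled, config$tolerance_s)

  cyc <- report$cycles
  truth_t11 <- interval_lookup(truth$s1_times, truth$t11_series,
                               cyc$s1_time_s, config$tolerance_s)
  truth_t12 <- interval_lookup(truth$s1_times, truth$t12_series,
                               cyc$s1_time_s, config$tolerance_s)
  metrics$t11_mae_s <- median(abs(cyc$t11_s - truth_t11), na.rm = TRUE)
  metrics$t12_mae_s <- median(abs(cyc$t12_s - truth_t12), na.rm = TRUE)
  metrics$success_rate <- report$success_rate
  metrics
}

# True interval value for each detected S1 (NA when no true S1 within tol).
interval_lookup <- function(truth_s1, truth_vals, detected_s1, tol) {
  vapply(detected_s1, function(t0) {
    j <- which.min(abs(truth_s1 - t0))
    if (length(j) == 0 || abs(truth_s1[j] - t0) > tol ||
        j > length(truth_vals)) {
      NA_real_
    } else {
      truth_vals[j]
    }
  }, numeric(1))
}

#' Write the per-cycle table as CSV
#'
#' Columns `s1_time_s`, `s2_time_s`, `t11_s`, `t12_s`, `t21_s`,
#' `t1_width_s`, `t2_width_s`; times in seconds with six decimal places;
#' absent values as empty cells.
#'
#' @param cycles A `pcg_cycles` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  df <- as.data.frame(cycles)
  for (col in names(df)) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.6f", df[[col]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a diagnostic report as JSON
#'
#' Scalars plus the per-cycle table; all times fixed to six decimal
#' places, so identical runs produce byte-identical files.
#'
#' @param report A `pcg_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  r6 <- function(x) ifelse(is.na(x), NA, as.numeric(sprintf("%.6f", x)))
  cyc <- report$cycles
  payload <- list(
    duration_s = r6(report$duration_s),
    n_cycles = nrow(cyc),
    mean_hr_bpm = r6(report$mean_hr_bpm),
    success_rate = r6(report$success_rate),
    tempo_bpm = r6(report$tempo_bpm %||% NA_real_),
    label_confidence = r6(report$labeled$label_confidence %||% NA_real_),
    cycles = lapply(seq_len(nrow(cyc)), function(i) {
      lapply(as.list(cyc[i, ]), r6)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
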
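#' Calibrate the detection threshold from a baseline segment
#'
#' The threshold is the largest excursion of the detector's statistic during
#' an annotated undistracted segment (usually the drive's first segment
#' without a side task): anything the accumulated variance change did while
#' the driver was demonstrably attentive must not count as distraction
#' later. A perfectly regular baseline yields 0, meaning any later rise in
#' gaze-gap variance triggers.
#'
#' @param trace A trace from [compute_tdgv()] covering the baseline.
#' @param baseline A single segment (one-row data frame or list with
#'   `start_s`, `end_s`); samples in `[start_s, end_s)` are used.
#' @param statistic Which per-sample statistic to maximise: the accumulated
#'   change `"cum"` (default; the quantity the detector thresholds, keeping
#'   calibration and detection on one scale) or the raw derivative
#'   `"delta"`.
#' @return Threshold value (>= 0).
#' @export
calibrate_threshold <- function(trace, baseline, statistic = c("cum", "delta")) {
  statistic <- match.arg(statistic)
  idx <- baseline_rows(trace, baseline)
  max(0, max(trace[[statistic]][idx]))
}

#' Baseline-quality z-score
#'
#' How extreme the baseline's largest accumulated variance change is
#' relative to the whole drive:
#' `z = (max baseline cum - mean(cum)) / population sd(cum)`, with mean and
#' SD over every sample of the drive. High values mean the calibration
#' segment itself was irregular (a distracted or inherently irregular
#' baseline), which inflates the threshold and costs sensitivity — so
#' higher z indicates lower baseline quality.
#'
#' @param trace Whole-drive trace from [compute_tdgv()].
#' @param baseline The calibration segment (as in [calibrate_threshold()]).
#' @return The z-score (dimensionless).
#' @export
baseline_quality <- function(trace, baseline) {
  idx <- baseline_rows(trace, baseline)
  cum <- trace$cum
  s <- sqrt(sum((cum - mean(cum))^2) / length(cum))
  if (s == 0) {
    abort("whole-drive accumulator is constant; baseline quality is undefined",
          class = "tdgv_degenerate_error")
  }
  (max(cum[idx]) - mean(cum)) / s
}

#' Calibrate threshold and baseline quality in one step
#'
#' @inheritParams baseline_quality
#' @param statistic Passed to [calibrate_threshold()].
#' @return A one-row tibble with `threshold`, `quality_z`, and the baseline
#'   interval `start_s`, `end_s`.
#' @export
calibrate <- function(trace, baseline, statistic = c("cum", "delta")) {
  tibble(threshold = calibrate_threshold(trace, baseline, statistic),
         quality_z = baseline_quality(trace, baseline),
         start_s = as.numeric(baseline$start_s)[1],
         end_s = as.numeric(baseline$end_s)[1])
}

baseline_rows <- function(trace, baseline) {
  if (is.null(baseline$start_s) || is.null(baseline$end_s)) {
    stop_usage("`baseline` needs `start_s` and `end_s`")
  }
  a <- as.numeric(baseline$start_s)[1]
  b <- as.numeric(baseline$end_s)[1]
  if (!is.finite(a) || !is.finite(b) || a >= b) {
    stop_usage("baseline must satisfy start_s < end_s")
  }
  idx <- which(trace$t >= a & trace$t < b)
  if (length(idx) == 0) {
    abort("baseline interval contains no trace samples",
          class = "tdgv_calibration_error")
  }
  idx
}
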
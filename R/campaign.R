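#' Analyse one drive end to end
#'
#' The full pipeline on a gaze stream with segment annotations: compute the
#' variance-change trace, calibrate the threshold (and baseline-quality
#' z-score) on the designated baseline segment, flag distraction, and score
#' the remaining segments. The baseline segment is the first segment whose
#' condition is `"baseline"`, or, failing that, the first `"no_task"`
#' segment; it is excluded from scoring.
#'
#' @param gaze A [gaze_stream()].
#' @param segments Segment annotations (see [segment_table()]).
#' @param config A [detector_config()]; its `threshold` is ignored and
#'   re-calibrated from the baseline.
#' @param positive_conditions Labels scored as truly distracted.
#' @return One-row tibble: `threshold`, `quality_z`, `n_events`, the four
#'   confusion counts and the three performance percentages.
#' @export
analyze_drive <- function(gaze, segments, config = detector_config(),
                          positive_conditions = "cognitive_task") {
  segments <- segment_table(segments)
  ib <- which(segments$condition == "baseline")[1]
  if (is.na(ib)) ib <- which(segments$condition == "no_task")[1]
  if (is.na(ib)) stop_usage("no baseline or no_task segment to calibrate on")
  baseline <- segments[ib, ]

  trace <- compute_tdgv(gaze, config)
  cal <- calibrate(trace, baseline, statistic = config$threshold_statistic)
  det <- detect_events(trace, cal$threshold)
  counts <- score_segments(det$events, segments[-ib, ],
                           positive_conditions = positive_conditions)
  dplyr::bind_cols(tibble(threshold = cal$threshold, quality_z = cal$quality_z,
                          n_events = nrow(det$events)),
                   counts, performance(counts))
}

#' Simulation campaign over seeds
#'
#' Repeats the default simulated study ([make_study2_default()]) across
#' seeds, running [analyze_drive()] on each realization. This is how the
#' detector's segment-level operating characteristics are measured on
#' synthetic ground truth.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param distraction_sd_multiplier Gap-SD inflation under distraction.
#' @param distracted_baseline Contaminate the calibration segment (see
#'   [make_study2_default()]).
#' @param config A [detector_config()].
#' @param rate_hz Sampling frequency.
#' @return A tibble with one row per seed: the [analyze_drive()] columns
#'   plus `seed` and `multiplier`.
#' @export
run_campaign <- function(seeds, distraction_sd_multiplier = 6,
                         distracted_baseline = FALSE,
                         config = detector_config(), rate_hz = 60) {
  purrr::map_dfr(seeds, function(s) {
    preset <- make_study2_default(distraction_sd_multiplier, seed = s,
                                  distracted_baseline = distracted_baseline,
                                  rate_hz = rate_hz)
    sim <- simulate_preset(preset)
    res <- analyze_drive(sim$gaze, sim$segments, config = config)
    dplyr::bind_cols(tibble(seed = s, multiplier = distraction_sd_multiplier), res)
  })
}
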
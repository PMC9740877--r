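#' Glance renewal model
#'
#' Parameters of the alternating renewal process the simulator draws gaze
#' behaviour from: off-dashboard gaps and on-dashboard dwells are sampled
#' from truncated normal distributions. Attentive driving means regular
#' dashboard checks (small `gap_sd_s`); cognitive distraction is modelled
#' as inflated gap variance — the glances still happen at roughly the same
#' rate, but their timing loses regularity.
#'
#' @param gap_mean_s Mean off-dashboard gap in seconds (> 0).
#' @param gap_sd_s Standard deviation of the gap (>= 0).
#' @param glance_dur_mean_s,glance_dur_sd_s Mean / SD of the on-dashboard
#'   dwell in seconds.
#' @param gap_floor_s Lower truncation of gaps (default 0.2 s): negative or
#'   near-zero gaps are physically impossible.
#' @param dwell_floor_s Lower truncation of dwells (default 0.05 s).
#' @return A list of class `glance_model`.
#' @export
glance_model <- function(gap_mean_s = 4.0, gap_sd_s = 0.4,
                         glance_dur_mean_s = 0.6, glance_dur_sd_s = 0.1,
                         gap_floor_s = 0.2, dwell_floor_s = 0.05) {
  if (gap_mean_s <= 0 || glance_dur_mean_s <= 0) stop_config("means must be positive")
  if (gap_sd_s < 0 || glance_dur_sd_s < 0) stop_config("SDs must be non-negative")
  if (gap_floor_s <= 0 || dwell_floor_s <= 0) stop_config("truncation floors must be positive")
  structure(list(gap_mean_s = gap_mean_s, gap_sd_s = gap_sd_s,
                 glance_dur_mean_s = glance_dur_mean_s,
                 glance_dur_sd_s = glance_dur_sd_s,
                 gap_floor_s = gap_floor_s, dwell_floor_s = dwell_floor_s),
            class = "glance_model")
}

# Truncated-normal draws by resampling below the floor. sd = 0 degenerates
# to the (floored) mean.
rtrunc_norm <- function(k, mean, sd, floor) {
  if (k == 0L) return(numeric())
  if (sd == 0) return(rep(max(mean, floor), k))
  if (floor > mean + 8 * sd) stop_config("truncation floor is unreachable for this mean/sd")
  v <- rnorm(k, mean, sd)
  while (any(v < floor)) {
    low <- v < floor
    v[low] <- rnorm(sum(low), mean, sd)
  }
  v
}

#' Simulate an AOI-labeled gaze drive
#'
#' Generates alternating off-dashboard gaps and on-dashboard dwells from
#' each segment's glance model, then discretises the timeline into samples
#' at `rate_hz` with `aoi` either `"dashboard"` or `"none"`. A glance or
#' gap in progress at a segment boundary is not truncated; the interval
#' simply spills into the next segment. Per-segment RNG substreams are
#' derived from the one seed, so two schedules sharing a prefix share those
#' segments' realizations — which is what makes paired clean/perturbed
#' baseline experiments paired. Identical inputs give identical output.
#'
#' @param schedule Data frame with columns `duration_s` (> 0), `condition`
#'   (see [segment_conditions]) and `model` (name into `models`).
#' @param models Named list of [glance_model()]s covering every name in
#'   `schedule$model`.
#' @param rate_hz Output sampling frequency (> 0), default 60.
#' @param seed Integer seed.
#' @return A list with `gaze` (a [gaze_stream()]) and `segments`
#'   (annotation tibble `start_s, end_s, condition`).
#' @export
simulate_drive <- function(schedule, models, rate_hz = 60, seed = 1L) {
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop_config("rate_hz must be positive")
  if (!all(c("duration_s", "condition", "model") %in% names(schedule))) {
    stop_config("schedule needs columns duration_s, condition, model")
  }
  if (any(schedule$duration_s <= 0)) stop_config("segment durations must be positive")
  missing_models <- setdiff(unique(schedule$model), names(models))
  if (length(missing_models) > 0) {
    stop_config(sprintf("no glance model for: %s", toString(missing_models)))
  }
  seg_end <- cumsum(schedule$duration_s)
  seg_start <- c(0, seg_end[-length(seg_end)])
  total <- seg_end[length(seg_end)]

  dwell_start <- numeric()
  dwell_end <- numeric()
  t_cur <- 0
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(nrow(schedule))) {
    set.seed((as.integer(seed) + 9973L * i) %% 2147483647L)
    gm <- models[[schedule$model[i]]]
    while (t_cur < seg_end[i]) {
      gap <- rtrunc_norm(1L, gm$gap_mean_s, gm$gap_sd_s, gm$gap_floor_s)
      dwell <- rtrunc_norm(1L, gm$glance_dur_mean_s, gm$glance_dur_sd_s, gm$dwell_floor_s)
      t_cur <- t_cur + gap
      dwell_start <- c(dwell_start, t_cur)
      dwell_end <- c(dwell_end, t_cur + dwell)
      t_cur <- t_cur + dwell
    }
  }

  N <- as.integer(round(total * rate_hz))
  t <- (seq_len(N) - 1L) / rate_hz
  j <- findInterval(t, dwell_start)
  on <- j >= 1L & t < dwell_end[pmax(j, 1L)]
  gaze <- gaze_stream(tibble(t = t,
                             aoi = ifelse(on, "dashboard", "none"),
                             valid = TRUE),
                      rate_hz = rate_hz)
  segments <- tibble(start_s = seg_start, end_s = seg_end,
                     condition = schedule$condition)
  list(gaze = gaze, segments = segments)
}

#' Default simulated-study preset
#'
#' A six-minute drive of six alternating one-minute segments (plain driving
#' first, then a cognitively loading side task, and so on), sampled at
#' 60 Hz — the segment layout of a simulator validation study. The glance
#' models are synthetic choices, not measured values: attentive driving
#' checks the dashboard about every 4 s (SD 0.4 s) with 0.6 +/- 0.1 s
#' dwells, and distraction multiplies the gap SD by
#' `distraction_sd_multiplier` while leaving the mean alone.
#'
#' @param distraction_sd_multiplier Gap-SD inflation factor under the side
#'   task (>= 1; 1 gives a null drive where both conditions are identical).
#' @param seed Integer seed for [simulate_drive()].
#' @param distracted_baseline If `TRUE`, the first (calibration) segment is
#'   generated from the distracted model while keeping its `no_task` label —
#'   a drive whose baseline is contaminated, for studying baseline quality.
#' @param rate_hz Sampling frequency, default 60.
#' @return A list with `schedule`, `models`, `rate_hz`, `seed`, ready for
#'   [simulate_drive()] (or pass directly to [simulate_preset()]).
#' @export
make_study2_default <- function(distraction_sd_multiplier = 6,
                                seed = 1L,
                                distracted_baseline = FALSE,
                                rate_hz = 60) {
  if (!is.finite(distraction_sd_multiplier) || distraction_sd_multiplier < 1) {
    stop_config("distraction_sd_multiplier must be finite and >= 1")
  }
  attentive <- glance_model(gap_mean_s = 4.0, gap_sd_s = 0.4,
                            glance_dur_mean_s = 0.6, glance_dur_sd_s = 0.1)
  distracted <- glance_model(gap_mean_s = 4.0,
                             gap_sd_s = 0.4 * distraction_sd_multiplier,
                             glance_dur_mean_s = 0.6, glance_dur_sd_s = 0.1)
  cond <- rep(c("no_task", "cognitive_task"), 3)
  model <- cond
  if (distracted_baseline) model[1] <- "cognitive_task"
  schedule <- tibble(duration_s = rep(60, 6), condition = cond, model = model)
  list(schedule = schedule,
       models = list(no_task = attentive, cognitive_task = distracted),
       rate_hz = rate_hz, seed = as.integer(seed))
}

#' Run [simulate_drive()] on a preset
#' @param preset A list as returned by [make_study2_default()].
#' @return As [simulate_drive()].
#' @export
simulate_preset <- function(preset) {
  simulate_drive(preset$schedule, preset$models,
                 rate_hz = preset$rate_hz, seed = preset$seed)
}
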
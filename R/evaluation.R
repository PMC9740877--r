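#' Segment-level confusion counts
#'
#' Scores detector output against the drive's experimental segments. A
#' segment counts as "marked distracted" if any detection event overlaps it
#' at all — the published criterion is firing at least once within the
#' segment, so overlap duration is irrelevant and even a zero-length event
#' inside the segment marks it. Segments are half-open intervals
#' `[start_s, end_s)`: an event starting exactly at a segment's end belongs
#' to the following segment.
#'
#' @param events Detection events (tibble `start_s, end_s`, e.g. from
#'   [run_detector()] via [tidy()]).
#' @param segments Segment annotations (see [segment_table()]).
#' @param positive_conditions Condition labels that count as truly
#'   distracted (default `"cognitive_task"`).
#' @param exclude_conditions Condition labels dropped before scoring
#'   (default `"baseline"`: the threshold was calibrated there, so scoring
#'   it would be circular).
#' @return One-row tibble `true_pos, true_neg, false_pos, false_neg`
#'   (segment counts).
#' @export
score_segments <- function(events, segments,
                           positive_conditions = "cognitive_task",
                           exclude_conditions = "baseline") {
  segments <- segment_table(segments)
  segments <- dplyr::filter(segments, !(.data$condition %in% exclude_conditions))
  if (nrow(segments) == 0) stop_usage("no segments left to score")
  marked <- vapply(seq_len(nrow(segments)), function(i) {
    a <- segments$start_s[i]
    b <- segments$end_s[i]
    any(events$start_s < b & events$end_s >= a)
  }, logical(1))
  positive <- segments$condition %in% positive_conditions
  tibble(true_pos = sum(marked & positive),
         true_neg = sum(!marked & !positive),
         false_pos = sum(marked & !positive),
         false_neg = sum(!marked & positive))
}

#' Detection performance percentages
#'
#' Accuracy, sensitivity and specificity of segment-level detection, as
#' percentages:
#' `Acc = (TP + TN) / (TP + TN + FP + FN) * 100`,
#' `Sens = TP / (TP + FN) * 100`, `Spec = TN / (TN + FP) * 100`.
#' A metric whose denominator is zero (no segments of that class) is
#' reported as `NA`.
#'
#' @param counts Confusion counts from [score_segments()] (or any data
#'   frame / list with `true_pos, true_neg, false_pos, false_neg`).
#' @return One-row tibble `accuracy_pct, sensitivity_pct, specificity_pct`.
#' @export
performance <- function(counts) {
  tp <- as.numeric(counts$true_pos)[1]
  tn <- as.numeric(counts$true_neg)[1]
  fp <- as.numeric(counts$false_pos)[1]
  fn <- as.numeric(counts$false_neg)[1]
  vals <- c(tp, tn, fp, fn)
  if (anyNA(vals) || any(vals < 0)) stop_usage("confusion counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total == 0) stop_usage("all confusion counts are zero; nothing was scored")
  ratio <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  tibble(accuracy_pct = ratio(tp + tn, total),
         sensitivity_pct = ratio(tp, tp + fn),
         specificity_pct = ratio(tn, tn + fp))
}

#' Self-reported distraction level
#'
#' Difference between how focused a driver reported being without and with
#' the side task, each on a 1 (not focused) to 7 (very focused) scale. The
#' expected range is 0 (task not distracting) to 6 (very distracting);
#' negative values — more focused with the task than without — are allowed
#' but flagged with a warning.
#'
#' @param focus_without_task,focus_with_task Integer ratings in 1..7
#'   (vectorised).
#' @return Integer distraction level(s).
#' @export
distraction_level <- function(focus_without_task, focus_with_task) {
  check_scale <- function(v, nm) {
    if (anyNA(v) || any(v < 1 | v > 7) || any(v != round(v))) {
      stop_data(sprintf("`%s` must be integers on the 1-7 focus scale", nm))
    }
  }
  check_scale(focus_without_task, "focus_without_task")
  check_scale(focus_with_task, "focus_with_task")
  lvl <- as.integer(focus_without_task) - as.integer(focus_with_task)
  if (any(lvl < 0)) {
    warn(sprintf("%d negative distraction level(s): driver(s) reported more focus with the task",
                 sum(lvl < 0)))
  }
  lvl
}

#' Median split
#'
#' Splits observations at the midpoint-interpolated sample median. Values
#' strictly below the median go to the low group, strictly above to the
#' high group, and ties with the median go low — a fixed, documented policy
#' so group membership is deterministic.
#'
#' @param values Numeric vector, length >= 2.
#' @return A list with `low` and `high` (integer indices into `values`) and
#'   `median`.
#' @export
median_split <- function(values) {
  if (length(values) < 2 || anyNA(values)) {
    stop_usage("median_split needs >= 2 non-missing values")
  }
  med <- median(values)
  list(low = which(values <= med), high = which(values > med), median = med)
}
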
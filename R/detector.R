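#' Detector configuration
#'
#' Tuning parameters of the glance-variance change detector. The defaults
#' are the published ones: a window of the last 10 inter-glance gaps and a
#' 2-second smoothing horizon.
#'
#' @param n Window size in glances: how many past gaps between dashboard
#'   glances enter the rolling standard deviation. Integer >= 2.
#' @param smooth_seconds Length of the moving average applied to the rolling
#'   standard deviation, in seconds. Converted to a sample count as
#'   `m = round(smooth_seconds * rate_hz)`, minimum 1.
#' @param threshold Detection threshold on the accumulated rise of the
#'   smoothed standard deviation. `NULL` means uncalibrated; see
#'   [calibrate_threshold()]. Must be a finite non-negative number for
#'   detection to run.
#' @param target_aoi AOI label whose glances are monitored (default
#'   `"dashboard"`).
#' @param invalid_policy How samples flagged `valid = FALSE` are treated:
#'   `"none"` maps them off-target, `"hold_last"` carries the previous
#'   valid AOI forward.
#' @param threshold_statistic Which baseline statistic [calibrate_threshold()]
#'   maximises: the accumulated change `"cum"` (default, same scale the
#'   detector thresholds) or the raw per-sample derivative `"delta"`.
#' @param live_gap Whether the still-growing newest gap enters the rolling
#'   standard deviation before it completes. The default `"exclude"`
#'   computes the TDGV over completed inter-glance gaps only, so perfectly
#'   regular glancing gives a flat zero statistic and never alarms.
#'   `"include"` recomputes the SD with the live value at every off-target
#'   sample; this reacts within a still-open gap but superimposes a sawtooth
#'   (the live value sweeps from 0 up to the gap length every glance cycle)
#'   that raises the calibrated threshold even for regular gazers. See the
#'   methods vignette.
#' @param normalize_per_second If `TRUE` the per-sample derivative is scaled
#'   by the sampling rate so it is a per-second rate of change. Off by
#'   default: the published construction differences consecutive samples.
#' @return A list of class `tdgv_config`.
#' @export
detector_config <- function(n = 10L,
                            smooth_seconds = 2,
                            threshold = NULL,
                            target_aoi = "dashboard",
                            invalid_policy = c("none", "hold_last"),
                            threshold_statistic = c("cum", "delta"),
                            live_gap = c("exclude", "include"),
                            normalize_per_second = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_config("`n` must be an integer >= 2")
  if (!is.numeric(smooth_seconds) || smooth_seconds <= 0) {
    stop_config("`smooth_seconds` must be positive")
  }
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1 ||
        !is.finite(threshold) || threshold < 0) {
      stop_config("`threshold` must be a single finite non-negative number (or NULL)")
    }
  }
  structure(
    list(n = n,
         smooth_seconds = as.numeric(smooth_seconds),
         threshold = threshold,
         target_aoi = as.character(target_aoi)[1],
         invalid_policy = match.arg(invalid_policy),
         threshold_statistic = match.arg(threshold_statistic),
         live_gap = match.arg(live_gap),
         normalize_per_second = isTRUE(normalize_per_second)),
    class = "tdgv_config"
  )
}

#' Read a detector configuration from JSON
#'
#' The JSON object mirrors the [detector_config()] argument names.
#'
#' @param path JSON file path.
#' @return A `tdgv_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(detector_config))
  extra <- setdiff(names(j), known)
  if (length(extra) > 0) stop_config(sprintf("unknown config field(s): %s", toString(extra)))
  do.call(detector_config, j)
}

#' Standard deviation of a gap window
#'
#' Population standard deviation (divide by the count, not count - 1) of the
#' gap durations currently held in the window; 0 when fewer than two gaps
#' are available. The population flavour is defined for a single element and
#' so needs no start-up special case.
#'
#' @param gaps Numeric vector of inter-glance gap durations in seconds.
#' @return Standard deviation in seconds.
#' @examples
#' window_std(c(1, 3)) # 1
#' @export
window_std <- function(gaps) {
  if (anyNA(gaps) || any(gaps < 0)) {
    abort("gap durations must be non-negative", class = "tdgv_state_error")
  }
  k <- length(gaps)
  if (k < 2L) return(0)
  mu <- sum(gaps) / k
  sqrt(sum((gaps - mu)^2) / k)
}

#' Smooth a standard-deviation history
#'
#' Arithmetic mean of the most recent `min(m, length(sigma_history))`
#' values; the window shrinks at start-up rather than padding.
#'
#' @param sigma_history Numeric vector of rolling standard deviations,
#'   oldest first.
#' @param m Number of samples in the smoothing window
#'   (`round(smooth_seconds * rate_hz)`, >= 1).
#' @return The smoothed value.
#' @export
smooth_sigma <- function(sigma_history, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop_config("`m` must be >= 1")
  k <- length(sigma_history)
  if (k == 0L) return(0)
  take <- min(m, k)
  sum(sigma_history[(k - take + 1L):k]) / take
}

#' Accumulate non-negative changes
#'
#' The detector's decision statistic grows by every non-negative change of
#' the smoothed standard deviation and resets to zero the moment the change
#' turns negative, so only sustained rises in gaze-gap variance build up.
#'
#' @param delta Change of the smoothed standard deviation at the current
#'   sample. May be a vector, in which case the recurrence is applied along
#'   it and the full accumulator series is returned.
#' @param prev_cum Accumulator value at the previous sample (>= 0).
#' @return Updated accumulator value(s).
#' @examples
#' accumulate_delta(c(0.1, 0.2, -0.05, 0.3)) # 0.1 0.3 0.0 0.3
#' @export
accumulate_delta <- function(delta, prev_cum = 0) {
  if (!is.numeric(prev_cum) || length(prev_cum) != 1 || is.na(prev_cum) || prev_cum < 0) {
    stop_usage("`prev_cum` must be a single non-negative number")
  }
  out <- numeric(length(delta))
  acc <- prev_cum
  for (i in seq_along(delta)) {
    acc <- if (delta[i] < 0) 0 else acc + delta[i]
    out[i] <- acc
  }
  out
}

# On-target indicator after applying the invalid-sample policy.
effective_on <- function(stream, config) {
  aoi <- stream$aoi
  valid <- if ("valid" %in% names(stream)) stream$valid else rep(TRUE, length(aoi))
  valid[is.na(valid)] <- FALSE
  if (config$invalid_policy == "none") {
    aoi[!valid] <- "none"
  } else { # hold_last: carry the last valid label forward
    aoi[!valid] <- NA_character_
    src <- cummax(ifelse(!is.na(aoi), seq_along(aoi), 0L))
    aoi <- ifelse(src > 0L, aoi[pmax(src, 1L)], "none")
  }
  aoi == config$target_aoi
}

# Smoothing window length in samples.
smoothing_m <- function(config, rate) max(1L, as.integer(round(config$smooth_seconds * rate)))

#' Compute the glance-variance change trace of a gaze stream
#'
#' Streams through the samples exactly as an online detector would,
#' maintaining a fixed-capacity circular window over the gaps between
#' successive on-target glances: a slot is overwritten sample-by-sample
#' while its gap is still open and freezes when the next glance begins.
#' Emits per sample the population standard deviation `sigma` of the gaps
#' in the window (completed gaps only under the default
#' `live_gap = "exclude"`; including the still-open one under
#' `"include"`), the `smooth_seconds` moving average `sigma_smooth`, the
#' per-sample difference `delta`, and the non-negative accumulation `cum`
#' that the detector thresholds.
#'
#' @param stream A [gaze_stream()].
#' @param config A [detector_config()].
#' @return A tibble with columns `t, sigma, sigma_smooth, delta, cum`, one
#'   row per input sample.
#' @export
compute_tdgv <- function(stream, config = detector_config()) {
  if (!inherits(stream, "gaze_stream")) stream <- gaze_stream(stream)
  t <- stream$t
  on <- effective_on(stream, config)
  N <- length(t)
  if (N == 0L) {
    return(tibble(t = numeric(), sigma = numeric(), sigma_smooth = numeric(),
                  delta = numeric(), cum = numeric()))
  }
  rate <- rate_hz(stream)
  n <- config$n
  m <- smoothing_m(config, rate)
  include_live <- config$live_gap == "include"

  sigma <- numeric(N)
  slots <- numeric(n)
  nwritten <- 0L      # slots are written strictly in order until they wrap
  x <- -1L            # write index, 0-based as in the glance counter
  g <- 0L             # glances begun; gap k follows glance k
  gaze_time <- NA_real_
  prev_on <- FALSE
  for (i in seq_len(N)) {
    live <- FALSE
    if (on[i]) {
      if (!prev_on) {
        x <- x + 1L
        if (x >= n) x <- 0L
        g <- g + 1L
      }
      gaze_time <- t[i]
    } else if (x >= 0L) {
      slots[x + 1L] <- t[i] - gaze_time
      if (x + 1L > nwritten) nwritten <- x + 1L
      live <- TRUE
    }
    if (include_live) {
      if (nwritten >= 2L) {
        v <- slots[seq_len(nwritten)]
        mu <- sum(v) / nwritten
        sigma[i] <- sqrt(sum((v - mu)^2) / nwritten)
      }
    } else {
      # completed gaps currently in the window: the live overwrite has
      # already evicted the oldest one, so the span shrinks by one while a
      # gap is open
      K <- g - 1L
      lo <- max(1L, K - n + 1L + as.integer(live))
      w <- K - lo + 1L
      if (w >= 2L) {
        v <- slots[(((lo:K) - 1L) %% n) + 1L]
        mu <- sum(v) / w
        sigma[i] <- sqrt(sum((v - mu)^2) / w)
      }
    }
    prev_on <- on[i]
  }

  finish_trace(t, sigma, m, rate, config)
}

# Shared tail of the trace computation: smoothing, derivative, accumulation.
finish_trace <- function(t, sigma, m, rate, config) {
  N <- length(t)
  sigma_smooth <- vapply(seq_len(N), function(i) {
    j <- max(1L, i - m + 1L)
    sum(sigma[j:i]) / (i - j + 1L)
  }, numeric(1))
  delta <- c(0, diff(sigma_smooth))
  if (config$normalize_per_second) delta <- delta * rate
  cum <- accumulate_delta(delta)
  tibble(t = t, sigma = sigma, sigma_smooth = sigma_smooth,
         delta = delta, cum = cum)
}

#' Collapse a thresholded trace into detection events
#'
#' Flags every sample whose accumulated statistic strictly exceeds the
#' threshold and groups maximal runs of flagged samples into events. A
#' single flagged sample yields a zero-length event (`start_s == end_s`).
#'
#' @param trace A trace from [compute_tdgv()].
#' @param threshold Finite non-negative detection threshold.
#' @return A list with `trace` (the input plus a logical `distracted`
#'   column) and `events` (tibble `start_s, end_s`).
#' @export
detect_events <- function(trace, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0) {
    stop_usage("`threshold` must be a single finite non-negative number; run calibrate_threshold() first")
  }
  distracted <- trace$cum > threshold
  trace$distracted <- distracted
  if (length(distracted) == 0L || !any(distracted)) {
    events <- tibble(start_s = numeric(), end_s = numeric())
  } else {
    r <- rle(distracted)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    events <- tibble(start_s = trace$t[starts[keep]],
                     end_s = trace$t[ends[keep]])
  }
  list(trace = trace, events = events)
}

#' Run the distraction detector over a gaze stream
#'
#' Computes the glance-variance change trace ([compute_tdgv()]) and flags
#' distraction wherever the accumulated statistic exceeds the calibrated
#' threshold ([detect_events()]).
#'
#' @param stream A [gaze_stream()].
#' @param config A [detector_config()] whose `threshold` has been set,
#'   typically from [calibrate_threshold()] on a baseline segment.
#' @return An object of class `tdgv_detection`: list with `trace` (tibble
#'   `t, sigma, sigma_smooth, delta, cum, distracted`), `events` (tibble
#'   `start_s, end_s`), `config`, and `rate_hz`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
run_detector <- function(stream, config = detector_config()) {
  if (is.null(config$threshold)) {
    stop_usage(paste("detector threshold is uncalibrated;",
                     "set `threshold` in detector_config(), e.g. from calibrate_threshold()"))
  }
  if (!inherits(stream, "gaze_stream")) stream <- gaze_stream(stream)
  trace <- compute_tdgv(stream, config)
  det <- detect_events(trace, config$threshold)
  structure(list(trace = det$trace, events = det$events,
                 config = config, rate_hz = rate_hz(stream)),
            class = "tdgv_detection")
}

#' @export
print.tdgv_detection <- function(x, ...) {
  cat("<tdgv_detection>\n")
  cat(sprintf("  samples: %d at %.3g Hz, window n = %d, threshold = %.6g\n",
              nrow(x$trace), x$rate_hz, x$config$n, x$config$threshold))
  cat(sprintf("  events: %d, samples flagged: %d (%.2f%%)\n",
              nrow(x$events), sum(x$trace$distracted),
              100 * mean(x$trace$distracted)))
  invisible(x)
}

#' @rdname run_detector
#' @param x A `tdgv_detection`.
#' @param ... Unused.
#' @method tidy tdgv_detection
#' @export
tidy.tdgv_detection <- function(x, ...) {
  dplyr::mutate(x$events, duration_s = .data$end_s - .data$start_s)
}

#' @rdname run_detector
#' @method glance tdgv_detection
#' @export
glance.tdgv_detection <- function(x, ...) {
  tibble(n_samples = nrow(x$trace),
         rate_hz = x$rate_hz,
         threshold = x$config$threshold,
         n_events = nrow(x$events),
         max_cum = if (nrow(x$trace)) max(x$trace$cum) else NA_real_,
         pct_flagged = if (nrow(x$trace)) 100 * mean(x$trace$distracted) else NA_real_)
}
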
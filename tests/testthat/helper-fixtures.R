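# Shared fixtures. All synthetic; built in code at test time.

# 1 Hz stream whose detector trace was derived by hand before the detector
# was written: glances at t = 0, 3, 7, 9 give gaps 2 (t1-t2, frozen at t3),
# 3 (t4-t6, frozen at t7) and 1 (t8, frozen at t9); with n = 2 the third
# gap evicts the first.
hand_trace_stream <- function() {
  gaze_stream(
    tibble::tibble(
      t = 0:10,
      aoi = c("dashboard", "none", "none", "dashboard", "none", "none",
              "none", "dashboard", "none", "dashboard", "none")),
    rate_hz = 1)
}

# Expected series for hand_trace_stream() with n = 2, smooth_seconds = 2
# (m = 2). sigma is the population SD of the completed gaps in the window:
# zero until two gaps coexist (t7: {2,3} -> 0.5; t8: live overwrite evicts
# gap 2, one gap left -> 0; t9: {3,1} -> 1; t10: eviction again -> 0).
hand_trace_expected <- function() {
  sigma <- c(0, 0, 0, 0, 0, 0, 0, 0.5, 0, 1, 0)
  sigma_smooth <- c(0, 0, 0, 0, 0, 0, 0, 0.25, 0.25, 0.5, 0.5)
  delta <- c(0, diff(sigma_smooth))
  cum <- c(0, 0, 0, 0, 0, 0, 0, 0.25, 0.25, 0.5, 0.5)
  tibble::tibble(t = as.numeric(0:10), sigma = sigma,
                 sigma_smooth = sigma_smooth, delta = delta, cum = cum)
}

# Randomized on/off stream: alternating geometric run lengths, random rate
# and length, deterministic in `seed`.
random_onoff_stream <- function(seed, min_len = 100, max_len = 20000) {
  set.seed(seed)
  N <- sample(min_len:max_len, 1)
  rate <- runif(1, 10, 120)
  on_mean <- max(1, rate * runif(1, 0.2, 1))    # dwell ~ 0.2-1 s
  off_mean <- max(1, rate * runif(1, 1, 6))     # gap ~ 1-6 s
  state <- runif(1) < 0.5
  lab <- logical(0)
  while (length(lab) < N) {
    len <- 1L + stats::rgeom(1, 1 / (if (state) on_mean else off_mean))
    lab <- c(lab, rep(state, len))
    state <- !state
  }
  lab <- lab[seq_len(N)]
  gaze_stream(
    tibble::tibble(t = (seq_len(N) - 1) / rate,
                   aoi = ifelse(lab, "dashboard", "none")),
    rate_hz = rate)
}

# Perfectly periodic drive: constant gaps and dwells, zero variance.
periodic_stream <- function(duration_s = 360, rate = 60,
                            gap_s = 4.0, dwell_s = 0.6, seed = 1) {
  models <- list(no_task = glance_model(gap_mean_s = gap_s, gap_sd_s = 0,
                                        glance_dur_mean_s = dwell_s,
                                        glance_dur_sd_s = 0))
  schedule <- tibble::tibble(duration_s = duration_s, condition = "no_task",
                             model = "no_task")
  simulate_drive(schedule, models, rate_hz = rate, seed = seed)$gaze
}

expect_trace_equal <- function(a, b, tol = 1e-12) {
  cols <- c("t", "sigma", "sigma_smooth", "delta", "cum")
  for (cl in cols) {
    expect_lt(max(abs(a[[cl]] - b[[cl]]), 0), tol)
  }
  if ("distracted" %in% names(a) && "distracted" %in% names(b)) {
    expect_identical(a$distracted, b$distracted)
  }
}
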
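test_that("the hand-derived 1 Hz fixture is reproduced exactly", {
  cfg <- detector_config(n = 2, threshold = 0.3)
  out <- run_detector(hand_trace_stream(), cfg)
  exp <- hand_trace_expected()
  expect_equal(out$trace$sigma, exp$sigma)
  expect_equal(out$trace$sigma_smooth, exp$sigma_smooth)
  expect_equal(out$trace$delta, exp$delta)
  expect_equal(out$trace$cum, exp$cum)
  expect_equal(out$trace$distracted, exp$cum > 0.3)
  expect_equal(out$events, tibble::tibble(start_s = 9, end_s = 10))
})

test_that("the window capacity is n: a new glance evicts the oldest gap", {
  # gaps 2, 3, 1 with n = 2: at the third freeze (t = 9) the window is
  # {3, 1}, not {2, 3, 1}; sd 1 rather than sqrt(14)/3
  tr <- compute_tdgv(hand_trace_stream(), detector_config(n = 2))
  expect_equal(tr$sigma[10], 1)
  # with n = 3 all three gaps fit: population sd of {2, 3, 1}
  tr3 <- compute_tdgv(hand_trace_stream(), detector_config(n = 3))
  expect_equal(tr3$sigma[10], sqrt(2 / 3))
})

test_that("streams that never alternate produce a flat zero trace", {
  never <- gaze_stream(tibble::tibble(t = (0:499) / 10, aoi = "none"), rate_hz = 10)
  always <- gaze_stream(tibble::tibble(t = (0:499) / 10, aoi = "dashboard"), rate_hz = 10)
  for (s in list(never, always)) {
    out <- run_detector(s, detector_config(threshold = 0))
    expect_true(all(out$trace$sigma == 0))
    expect_true(all(out$trace$cum == 0))
    expect_equal(nrow(out$events), 0)
  }
  # empty stream, empty trace
  empty <- gaze_stream(tibble::tibble(t = numeric(), aoi = character()), rate_hz = 10)
  expect_equal(nrow(compute_tdgv(empty)), 0)
  expect_equal(nrow(batch_oracle(empty, detector_config(threshold = 0))), 0)
})

test_that("an uncalibrated detector refuses to run", {
  expect_error(run_detector(hand_trace_stream(), detector_config()),
               "calibrate", class = "tdgv_usage_error")
  expect_error(detect_events(hand_trace_expected(), Inf), class = "tdgv_usage_error")
  expect_error(detect_events(hand_trace_expected(), -0.1), class = "tdgv_usage_error")
})

test_that("streaming and batch recomputation agree on random streams in both window modes", {
  for (seed in 0:9) {
    s <- random_onoff_stream(seed, min_len = 200, max_len = 3000)
    for (mode in c("exclude", "include")) {
      cfg <- detector_config(threshold = 0.2, live_gap = mode,
                             n = sample(2:15, 1))
      expect_trace_equal(run_detector(s, cfg)$trace, batch_oracle(s, cfg))
    }
  }
})

test_that("invalid samples follow the configured policy", {
  df <- tibble::tibble(
    t = 0:9,
    aoi = c("dashboard", "none", "dashboard", "none", "none",
            "dashboard", "none", "none", "dashboard", "none"),
    valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  s <- gaze_stream(df, rate_hz = 1)
  # "none" policy: the invalid dashboard hit at t=2 is dropped, merging two gaps
  tr_none <- compute_tdgv(s, detector_config(n = 4, invalid_policy = "none"))
  drop <- gaze_stream(dplyr::mutate(df, aoi = replace(aoi, !valid, "none"),
                                    valid = TRUE), rate_hz = 1)
  expect_equal(tr_none$sigma, compute_tdgv(drop, detector_config(n = 4))$sigma)
  # "hold_last" carries the previous valid label forward: t=2 inherits
  # t=1's "none", t=6 inherits t=5's "dashboard"
  tr_hold <- compute_tdgv(s, detector_config(n = 4, invalid_policy = "hold_last"))
  held <- gaze_stream(dplyr::mutate(df, aoi = c("dashboard", "none", "none", "none", "none",
                                                "dashboard", "dashboard", "none", "dashboard", "none"),
                                    valid = TRUE),
                      rate_hz = 1)
  expect_equal(tr_hold$sigma, compute_tdgv(held, detector_config(n = 4))$sigma)
})

test_that("higher thresholds flag nested subsets of samples", {
  sim <- simulate_preset(make_study2_default(4, seed = 3))
  trace <- compute_tdgv(sim$gaze)
  grid <- seq(0, max(trace$cum), length.out = 10)
  flagged <- lapply(grid, function(T) which(detect_events(trace, T)$trace$distracted))
  for (k in seq_along(grid)[-1]) {
    expect_true(all(flagged[[k]] %in% flagged[[k - 1]]))
  }
})

test_that("event grouping collapses runs and supports zero-length events", {
  trace <- tibble::tibble(t = 0:9, sigma = 0, sigma_smooth = 0, delta = 0,
                          cum = c(0, 1, 1, 0, 1, 0, 0, 1, 1, 1))
  ev <- detect_events(trace, 0.5)$events
  expect_equal(ev$start_s, c(1, 4, 7))
  expect_equal(ev$end_s, c(2, 4, 9))
  expect_equal(ev$end_s[2] - ev$start_s[2], 0) # single sample, zero length
})

test_that("tidy and glance summarise a detection", {
  out <- run_detector(hand_trace_stream(), detector_config(n = 2, threshold = 0.3))
  td <- generics::tidy(out)
  expect_equal(td$duration_s, 1)
  gl <- generics::glance(out)
  expect_equal(gl$n_events, 1L)
  expect_equal(gl$max_cum, 0.5)
})
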
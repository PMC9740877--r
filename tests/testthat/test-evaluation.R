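seg6 <- function() {
  tibble::tibble(start_s = seq(0, 300, 60), end_s = seq(60, 360, 60),
                 condition = rep(c("no_task", "cognitive_task"), 3))
}

test_that("segments are marked by any event overlap, scored per class", {
  # events inside all three task segments and in one no-task segment
  ev <- tibble::tibble(start_s = c(70, 130, 190, 310), end_s = c(80, 135, 200, 320))
  counts <- score_segments(ev, seg6(), exclude_conditions = character())
  expect_equal(counts, tibble::tibble(true_pos = 3L, true_neg = 2L,
                                      false_pos = 1L, false_neg = 0L),
               ignore_attr = TRUE)
  expect_equal(sum(unlist(counts)), nrow(seg6()))

  # no events: all positives missed, all negatives clean
  none <- tibble::tibble(start_s = numeric(), end_s = numeric())
  counts0 <- score_segments(none, seg6(), exclude_conditions = character())
  expect_equal(counts0$false_neg, 3L)
  expect_equal(counts0$true_neg, 3L)

  # a zero-length event inside a segment still marks it
  dot <- tibble::tibble(start_s = 75, end_s = 75)
  expect_equal(score_segments(dot, seg6(), exclude_conditions = character())$true_pos, 1L)

  expect_error(score_segments(ev, seg6()[0, ]), class = "tdgv_data_error")
})

test_that("segment intervals are half-open: boundary events belong to the next segment", {
  seg <- seg6()
  # event starting exactly at t = 60 (end of segment 1) marks only segment 2
  ev <- tibble::tibble(start_s = 60, end_s = 60)
  counts <- score_segments(ev, seg, exclude_conditions = character())
  expect_equal(counts$true_pos, 1L)
  expect_equal(counts$false_pos, 0L)
})

test_that("baseline segments are excluded from scoring by default", {
  seg <- seg6()
  seg$condition[1] <- "baseline"
  ev <- tibble::tibble(start_s = 10, end_s = 20) # only overlaps the baseline
  counts <- score_segments(ev, seg)
  expect_equal(sum(unlist(counts)), 5L)
  expect_equal(counts$false_pos, 0L)
})

test_that("splitting an event into abutting parts does not change the score", {
  set.seed(21)
  for (i in 1:10) {
    starts <- sort(runif(4, 0, 350))
    ev <- tibble::tibble(start_s = starts, end_s = pmin(starts + runif(4, 0, 30), 360))
    mid <- (ev$start_s[2] + ev$end_s[2]) / 2
    split_ev <- tibble::tibble(
      start_s = c(ev$start_s[1], ev$start_s[2], mid, ev$start_s[3:4]),
      end_s = c(ev$end_s[1], mid, ev$end_s[2], ev$end_s[3:4]))
    expect_equal(score_segments(ev, seg6(), exclude_conditions = character()),
                 score_segments(split_ev, seg6(), exclude_conditions = character()))
  }
})

test_that("scoring agrees with a brute-force overlap enumeration", {
  set.seed(33)
  for (i in 1:25) {
    k <- sample(0:6, 1)
    starts <- sort(runif(k, -20, 380))
    ev <- tibble::tibble(start_s = starts, end_s = starts + runif(k, 0, 40))
    seg <- seg6()
    counts <- score_segments(ev, seg, exclude_conditions = character())
    # independent route: exhaustive pairwise check, "not disjoint" phrasing
    marked <- vapply(seq_len(nrow(seg)), function(j) {
      hit <- FALSE
      for (e in seq_len(nrow(ev))) {
        disjoint <- ev$end_s[e] < seg$start_s[j] || ev$start_s[e] >= seg$end_s[j]
        if (!disjoint) hit <- TRUE
      }
      hit
    }, logical(1))
    pos <- seg$condition == "cognitive_task"
    expect_equal(unlist(counts, use.names = FALSE),
                 c(sum(marked & pos), sum(!marked & !pos),
                   sum(marked & !pos), sum(!marked & pos)))
  }
})

test_that("performance implements the percentage formulas", {
  p <- performance(list(true_pos = 3, false_pos = 1, true_neg = 2, false_neg = 0))
  expect_equal(round(p$accuracy_pct, 2), 83.33)
  expect_equal(p$sensitivity_pct, 100)
  expect_equal(round(p$specificity_pct, 2), 66.67)

  p2 <- performance(list(true_pos = 1, true_neg = 1, false_pos = 0, false_neg = 0))
  expect_equal(unlist(p2), c(accuracy_pct = 100, sensitivity_pct = 100,
                             specificity_pct = 100))

  p3 <- performance(list(true_pos = 0, false_neg = 1, true_neg = 1, false_pos = 0))
  expect_equal(unlist(p3), c(accuracy_pct = 50, sensitivity_pct = 0,
                             specificity_pct = 100))

  # one-class inputs report the undefined metric as NA
  p4 <- performance(list(true_pos = 2, false_neg = 1, true_neg = 0, false_pos = 0))
  expect_true(is.na(p4$specificity_pct))
  expect_error(performance(list(true_pos = 0, true_neg = 0, false_pos = 0,
                                false_neg = 0)),
               class = "tdgv_usage_error")
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  set.seed(8)
  for (i in 1:30) {
    cts <- as.list(stats::setNames(sample(0:6, 4, replace = TRUE),
                                   c("true_pos", "true_neg", "false_pos", "false_neg")))
    P <- cts$true_pos + cts$false_neg
    N <- cts$true_neg + cts$false_pos
    if (P == 0 || N == 0) next
    p <- performance(cts)
    expect_equal(p$accuracy_pct,
                 (P * p$sensitivity_pct + N * p$specificity_pct) / (P + N))
    expect_true(p$accuracy_pct >= min(p$sensitivity_pct, p$specificity_pct) &&
                p$accuracy_pct <= max(p$sensitivity_pct, p$specificity_pct))
  }
})

test_that("distraction level is the focus difference on the 1-7 scale", {
  expect_equal(distraction_level(7, 3), 4L)
  expect_equal(distraction_level(5, 5), 0L)
  expect_warning(lvl <- distraction_level(3, 6), "negative")
  expect_equal(lvl, -3L)
  expect_equal(distraction_level(c(7, 4), c(3, 4)), c(4L, 0L))
  expect_error(distraction_level(0, 5), class = "tdgv_data_error")
  expect_error(distraction_level(5, 8), class = "tdgv_data_error")
  expect_error(distraction_level(5.5, 2), class = "tdgv_data_error")
})

test_that("median split sends ties to the low group", {
  s1 <- median_split(c(1, 2, 3, 4))
  expect_equal(s1$median, 2.5)
  expect_equal(s1$low, 1:2)
  expect_equal(s1$high, 3:4)

  s2 <- median_split(c(0, 2, 2, 4))
  expect_equal(s2$median, 2)
  expect_equal(s2$low, 1:3)
  expect_equal(s2$high, 4L)

  s3 <- median_split(c(5, 5))
  expect_equal(s3$low, 1:2)
  expect_length(s3$high, 0)

  expect_error(median_split(3), class = "tdgv_usage_error")
})
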
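---
title: "Glance-regularity distraction detection: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glance-regularity distraction detection: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdgv)
```

## The model

The detector assumes that an attentive driver re-checks the dashboard at
roughly regular intervals, and that cognitive load degrades the temporal
control of that habit before it changes anything else about it. The
observable is therefore not *where* the driver looks or *how long*, but how
*regular* the spacing of dashboard glances is.

Given a sample stream with an AOI label per timestamp, the pipeline per
sample is:

1. maintain the last `n` inter-glance **gaps** (off-dashboard durations) in
   a fixed-capacity circular window;
2. `sigma` — the population standard deviation of the gaps in the window
   (the temporal dashboard gaze variance, TDGV);
3. `sigma_smooth` — the mean of `sigma` over the last `smooth_seconds`
   (samples `m = round(smooth_seconds * rate_hz)`, minimum 1), because the
   raw series moves in steps whenever the window content changes;
4. `delta` — the first difference of `sigma_smooth`;
5. `cum` — one-sided accumulation: `cum = cum_prev + delta` while
   `delta >= 0`, reset to exactly 0 the moment `delta < 0`;
6. distraction is flagged while `cum > T` (strict), with `T` calibrated per
   driver.

Step 5 makes the statistic sensitive only to *rises* in glance-gap
variance: a return to regular checking drains it instantly. The printed
recurrence is deliberately the accumulating one — adding the current change
to the *accumulated* previous value — since a two-term sum would forget
everything older than two samples and could not express "builds up until
the trend reverses".

## The window and the still-open gap

A subtle but consequential choice is what "the gaps in the window" means
while a gap is still open. The bookkeeping follows the streaming update
exactly: while the driver looks away, the newest slot is rewritten at every
sample with the elapsed time since the last dashboard glance, and the
moment the driver looks back the slot freezes; the first rewrite of a slot
evicts the oldest stored gap.

What enters the standard deviation is configurable:

- `live_gap = "exclude"` (default): `sigma` is computed over **completed**
  gaps only. Perfectly periodic glancing then gives `sigma ≡ 0` once the
  window has content, a perfectly regular baseline calibrates to `T = 0`,
  and the detector never alarms on regular behavior — the property the
  whole construction is meant to have.
- `live_gap = "include"`: the still-growing value participates at every
  off-target sample. This reacts *within* an anomalously long gap instead
  of only after it, but it superimposes a sawtooth on `sigma` even for a
  metronomically regular gazer: the live value sweeps from ~0 up to the
  full gap length every glance cycle, so the window briefly contains one
  near-zero entry after each glance. The sawtooth's amplitude *shrinks* as
  the underlying gap variance grows, so it inflates the calibrated
  threshold precisely for the most regular (best) baselines. On the
  package's synthetic study conditions this mode pushes the calibrated
  threshold above everything a genuinely distracted segment produces and
  detection collapses; we therefore treat the live value as bookkeeping,
  not signal, by default.

Both modes are maintained, tested, and verified against an independent
batch recomputation that rebuilds the window at every sample from the
stream's glance structure in closed form.

During start-up the window simply holds fewer gaps; `sigma` is the
population SD of what is there, and 0 with fewer than two gaps. The
population flavour (divide by the count) is used everywhere — it is defined
for a single element and needs no start-up special case; the same flavour
is used in the baseline-quality z-transform for consistency.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n` | 10 | glances | window capacity; larger smooths the variance estimate but slows reaction |
| `smooth_seconds` | 2.0 | s | moving-average horizon on `sigma`; removes step artifacts |
| `threshold` | calibrated | s | decision bound on `cum`; from `calibrate_threshold()` |
| `target_aoi` | `"dashboard"` | — | the monitored AOI |
| `invalid_policy` | `"none"` | — | invalid samples count as off-target; `"hold_last"` carries the last valid label forward |
| `threshold_statistic` | `"cum"` | — | baseline maximum of `cum` (same scale the detector thresholds); `"delta"` maximises the raw derivative instead |
| `live_gap` | `"exclude"` | — | see above |
| `normalize_per_second` | `FALSE` | — | scale `delta` by the sampling rate; off so traces match the per-sample construction |

`threshold_statistic = "cum"` keeps calibration and detection on one scale:
the threshold is "the largest excursion the decision statistic showed while
the driver was demonstrably attentive". The `"delta"` reading (largest
single-sample change) is offered because the phrase "maximum positive
change" admits it, but a per-sample difference at 60 Hz lives on a scale
~100× smaller than the accumulator it would bound, which makes the
detector fire near-continuously; it is not the default.

The baseline-quality z-score normalises the baseline maximum of `cum` by
the mean and population SD of `cum` over the **whole drive, baseline
included** — the literal reading of "the whole drive"; excluding the
baseline would change z by a few percent at the six-minute scale and by
construction cannot change its ordering across drives sharing a schedule.

## Evaluation conventions

- Segments are half-open `[start_s, end_s)`, so abutting one-minute
  segments partition time and a detection starting exactly on a boundary
  belongs to the following segment.
- A segment is "marked" if *any* detection event overlaps it, including a
  zero-length event (a single flagged sample); marking is therefore
  invariant to how runs of flagged samples are grouped into events.
- The calibration segment is never scored — the threshold is defined as the
  maximum there, so scoring it would count a tautological true negative.
- Accuracy, sensitivity and specificity are reported in percent; a metric
  whose denominator is empty (single-class designs) is `NA`, not 0.
- Self-report scoring: distraction level = focus without task − focus with
  task, each on the 1–7 scale; negative values are allowed but flagged.
  Median splits use the midpoint-interpolated sample median with **ties to
  the low group** — a fixed policy so that group membership is
  reproducible.

## The simulator

`simulate_drive()` generates an alternating renewal process: off-dashboard
gaps and on-dashboard dwells drawn from truncated normal distributions,
discretised at `rate_hz` into `{dashboard, none}` labels. Distraction is
modelled **purely as gap-variance inflation** (`gap_sd_s` multiplied, mean
untouched): the driver keeps checking at the same average rate but loses
timing regularity. A mean shift can be added but is off by default.

Defaults of the bundled six-minute preset (`make_study2_default()`): six
alternating 60 s segments (plain driving first) at 60 Hz; attentive gaps
4.0 ± 0.4 s, dwells 0.6 ± 0.1 s, gap-SD multiplier 6 under task. These are
**synthetic choices, not field measurements**: a dashboard check every ~4 s
with sub-second dwells is a plausible motorway cadence, a coefficient of
variation of 0.1 encodes "regular habit", and the multiplier is chosen so
the distracted state is unambiguous at one-minute segment resolution. Gaps
are truncated below at 0.2 s and dwells at 0.05 s because non-positive
durations are physically impossible; with the default parameters the
truncation is almost never active.

Determinism: each segment consumes its own RNG substream derived from the
one seed, so schedules sharing a prefix share those segments' realizations.
This is what makes the clean-baseline vs contaminated-baseline comparison a
*paired* design: the two drives differ only in the generating model of the
first segment.

What the simulator deliberately does **not** emulate: raw gaze coordinates
(labels are generated directly), blinks and invalid-tracking runs, drift or
fatigue trends within a condition, glances to competing targets under
visual distraction, vehicle dynamics, and any dependence between
consecutive gaps beyond the renewal structure. Passing tests on this
ground truth demonstrate that the detector recovers variance inflation in
an idealised glance process — not that it reaches any particular accuracy
on real driving data, where baseline contamination by mind-wandering and
individual irregularity are known, and here reproduced, failure modes.

## Numerical choices and problem sizes

- Two-pass variance (explicit mean, then squared deviations) everywhere;
  the one-pass sum-of-squares shortcut loses catastrophically many digits
  exactly when `sigma` is near 0, which is the baseline regime.
- Strict inequality for detection, so `T = 0` from a perfectly regular
  baseline does not flag the zero statistic itself.
- Timestamps are float seconds; on a 1/60 s grid "constant" gaps differ in
  the last ulp, so regularity tests assert `sigma < 1e-12` rather than
  exact zeros, and the streaming/batch equivalence is asserted at the same
  tolerance.
- Test problem sizes: equivalence on 200 randomized streams of 100–20,000
  samples at 10–120 Hz; operating characteristics on 100 simulated drives
  (21,600 samples each); paired baseline experiments on 50 seed pairs;
  multiplier monotonicity on 50 seeds × {1, 2, 4, 6}. These sizes give
  standard errors on campaign means of ~1.5 percentage points.

## Known limitations

- The statistic rises with *any* loss of glance regularity; visually
  distracting side tasks change dashboard-glance timing too, so the method
  does not discriminate cognitive from visual distraction.
- Performance is hostage to baseline quality: a contaminated calibration
  segment inflates `T` and silently costs sensitivity. The `quality_z`
  diagnostic makes this measurable but cannot repair it.
- The threshold is per-driver and per-drive; there is no pooled or
  population threshold.
- Event *extent* is reported as flagged-sample runs; the method is scored
  at segment level and makes no claim about onset latency.
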
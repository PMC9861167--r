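---
title: "Farrowing early warning and supervision: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Farrowing early warning and supervision: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farrowwatch)
```

`farrowwatch` turns the raw output of a sow/piglet object detector into
farm-level events: a warning that farrowing is approaching, an alarm that
it has begun, and a running piglet count. This vignette explains the
statistical model behind each step, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the supervision strategy left
choices open.

## 1. From detections to a posture timeline

The input is a stream of detection events `(t, class, box, conf)` with
`class` one of four sow postures (lateral lying, sternal lying, standing,
sitting) or `piglet`. `timeline_from_stream()` resamples the posture
channel onto half-open intervals `[kΔ, (k+1)Δ)`:

* the interval's posture is the **highest-confidence** posture detection
  inside it (ties go to the earlier detection). Nothing in the warning
  strategy dictates how a per-moment posture is chosen when the detector
  emits several posture boxes per frame; highest-confidence selection is
  this package's choice, and it is deterministic.
* an interval with no posture detection is **missing** (`NA`), not
  carried forward: a detector that emits nothing should look like a gap,
  not like a frozen posture.

All internal times are real-valued seconds from stream start; hours enter
only at the reporting boundary (the frequency statistic), which avoids
mixed-unit bugs.

## 2. The warning statistic and the persistence rule

The warning statistic is the posture-transition frequency
`f = n / T` (transitions per hour). `count_transitions()` counts
consecutive pairs of non-missing samples with different labels inside a
window; missing samples are bridged, so `a, NA, b` with `a != b` counts
one transition — detector dropouts do not erase real posture changes.
`frequency_series()` evaluates `f` on a sliding window (default 1 h,
matching the per-hour scale on which the statistic is defined) advanced by a step
(default 15 min).

Perinatal activity follows a three-stage pattern: normal activity from
−48 h to −24 h, a pronounced rise and then collapse of `f` during the
nest-building day before farrowing, and near-stillness followed by slow
recovery after farrowing. The warning strategy exploits it with two
thresholds — warn when `f` stays **above 17.5/h**, then (only after that)
when it stays **below 10/h**, each sustained for **more than 5 h** to
filter out eating/drinking/resting bouts.

### What "sustained for more than 5 h" means here

The literal reading — the threshold condition holds at every window point
for 5 h, any single sub-threshold point resetting the clock — is not
usable with a 1 h window. Transition counts in a 1 h window are
Poisson-like: at a true rate of 20/h (the default peak) a window exceeds
17.5/h with probability ≈ 0.7, so a 5 h run of exceedances at every
15 min step is a rare event (~20%) even for a sow that is genuinely and
persistently above threshold. No threshold-crossing rule on 1 h windows
can be simultaneously strict pointwise and reliable.

`evaluate_warnings()` therefore defines sustainment with two components:

1. **Grace-bridged exceedance run** — a run starts at the first window
   above threshold and survives interruptions shorter than `grace_hours`
   (default 3 h). The run start is the reported `condition_onset`.
2. **Trailing-mean gate** — emission requires, in addition to the run
   having lasted at least `persistence_hours`, that the *mean* frequency
   over the trailing persistence window is beyond the threshold. This is
   what makes the rule honest: a run kept alive by grace alone cannot
   fire while the frequency is only sporadically high.

On clean fixtures the rule reproduces exact hand arithmetic: a series
rising above threshold at hour 10 emits at hour 15 with onset 10; a 3 h
exceedance emits nothing; a single-point dip neither resets the onset nor
delays emission. On stochastic input it fires on ≈ 99.5% of sows
simulated under the default behavior profile — the residue are sows whose
realized transition process never averages above 17.5/h over any 5 h
span, which no rule keyed to that threshold can catch. Conversely, a
stationary sow at 12/h triggers with probability ≈ 1% per 72 h; note
that *any* such rule must misfire occasionally for stationary rates close
to the threshold (at 17/h even the strict pointwise rule fires often), so
"never fires between the thresholds" can only hold away from the
boundary.

The lower warning is armed only after the upper one. Without that
ordering, any resting sow (`f ≈ 0`) would warn constantly, contradicting
the "normal activity" baseline stage. Whether the 5 h persistence applies
jointly or separately to the two thresholds is ambiguous; it is
applied to each separately here.

`emitted_at - condition_onset` equals the persistence on clean
exceedances; the trailing-mean gate can defer emission beyond that, so in
general `emitted_at >= condition_onset + persistence_hours`.

`warning_error()` reports the raw lead (onset − emission, in hours) and
the absolute deviation from a configured target lead (default 5 h). Under
the default simulator profile the mean lead is ≈ 13 h: the default
profile holds its peak for 12 h, so the exceedance is confirmed early.
The lead is a property of the behavior profile, not of the rule.

## 3. Farrowing alarm, duration, and piglet counts

`process_stream()` replays the stream on the frame grid. A frame is
piglet-positive if at least one piglet box falls in it; the alarm fires
at the first run of `k_consecutive` positive frames (default 3). The
debounce is the whole point: with independent per-frame false-positive
probability `p`, episodes of length ≥ k occur at rate ≈ `p^k`, so three
consecutive detections suppress false alarms by orders of magnitude while
delaying a true alarm by at most `(k-1)` frames.

Design choices the supervision strategy leaves open:

* **`t_start`** is the *first* frame of the confirming run, not the
  k-th: the farrowing start is defined as the time the first piglet was
  born, and the run's first frame is the least-biased estimate available
  (bias at most `k * frame_interval` — with zero noise the estimate is
  exact to one frame).
* **`t_end`** — the duration is defined as running to the last
  birth, but that gives no online stopping rule. Online, the monitor takes `t_end` as
  the last frame that raised the running-maximum count and finalises it
  after `end_quiet_hours` (default 1 h) without a new maximum.
* **`detected_num`** is the running maximum of the per-frame count
  `cur_num`. With no identity tracking, the running maximum is the only
  monotone litter estimator available from counts, and it guarantees
  `DA >= CA` on every stream. (The alternative reading — increment a
  counter on every piglet box — over-counts without tracking and is not
  used.)
* A false alarm is counted **per episode** (maximal positive run), not
  per frame: that is what a stockperson answering alarms experiences.

Alarm messages (`"Delivery Begin! Start time: <ISO-8601>"`) go to
pluggable *alert sinks* (console, log file, in-memory mock for tests) —
the software stand-in for LED/GPIO signalling, which is deliberately out
of scope.

## 4. The synthetic sow

`simulate_sow()` draws the true posture path as a continuous-time jump
process: transition times from an inhomogeneous exponential clock whose
rate follows the piecewise-linear three-stage profile, the new posture
uniform over the three alternatives. `behavior_profile()` defaults:

| parameter | default | meaning |
|---|---|---|
| `stage_a_rate` | 8/h | baseline activity, −48 h to −24 h |
| `stage_b_rise_start` | 24 h | rise begins (before onset) |
| `stage_b_peak_rate` | 20/h | nest-building peak (must exceed 17.5) |
| `stage_b_peak_start` | 16 h | peak reached (before onset) |
| `stage_b_decline_start` | 4 h | decline begins (before onset) |
| `stage_b_decline_end_rate` | 2/h | rate at onset (must be below 10) |
| `stage_c_rate` / `stage_c_late_rate` | 1/h, 4/h | post-onset stillness, recovery by +24 h |

The three-stage shape is qualitative; there are no canonical numeric
frequency values to copy, so these defaults are chosen once to satisfy
the shape and straddle the two warning thresholds. The 12 h peak plateau makes
the exceedance long enough for the 5 h persistence to confirm reliably at
a peak only 14% above threshold.

The birth process is likewise the package's own model: litter size
truncated-Poisson (mean 12, min 1), inter-birth intervals exponential
(mean 15 min) — the simplest process with a configurable mean farrowing
duration (~2.8 h for a litter of 12).

`apply_detector_noise()` emulates a frame-based detector: per frame it
misses the posture with probability `posture_miss_rate`, mislabels it
with probability `posture_false_rate` (uniform over the three wrong
postures), detects each born piglet with probability
`1 - piglet_miss_prob`, and adds Poisson(`piglet_false_rate`) false
piglet boxes. `noise_presets()` carries the error rates measured for four
hard farm scenarios (complex light 6.33%/15.19%, heat lamp at night
3.36%/7.56%, etc.). The piglet error rates in that measurement are
absolute counts over 410 images; the presets convert them with an assumed
denominator of one visible piglet per image, which is an assumption to be
tuned per deployment, not a measured rate.

What the simulator does **not** emulate: images (no occlusion geometry,
piglet adhesion, or heat-lamp optics), piglet movement or identity,
multi-sow pens, and confidence values correlated with difficulty
(confidences are uniform). Passing end-to-end tests on simulated sows
therefore demonstrates the correctness of the *decision logic* under the
stated stochastic model — not field performance of any particular
detector. Field-level counting accuracy is represented instead by the
shipped 22-pen CA/DA table (`sow_pen_accuracy()`), whose unweighted
per-sow means (63.2% / 92.9%) are the cohort's reported accuracies; the
per-sow mean is the only aggregation that reproduces those printed
values, and is the one `summarize_cohort()` uses.

## 5. Numerical choices and degenerate inputs

* Half-open intervals everywhere; an event exactly on a boundary belongs
  to the later interval.
* BCE uses natural logarithms and clips predictions to
  `[1e-7, 1 - 1e-7]`; both are unstated conventions elsewhere, and a base
  change is a constant factor.
* Precision/recall with a zero denominator return `NA` flagged with a
  reason rather than 0 or an error.
* `ca_da()` refuses an all-zero `true_num` column (no farrowing in the
  window — the ratio is meaningless).
* Zero-area boxes are rejected at parse time; `giou_loss()` refuses
  degenerate boxes rather than returning an arbitrary value.
* Timelines shorter than one window yield an empty frequency series with
  a message, not an error — an online caller simply has no statistic yet.
* Streams are serialised with 17 significant digits so that
  write-then-read reproduces doubles bit-exactly.

## 6. Problem sizes in the test suite

The package's own checks run at desk scale, chosen as a compromise
between statistical power and a fast test cycle: 50 end-to-end sows at a
5 s frame interval over a (−48 h, +12 h) horizon for the
warning/alarm/counting properties; 200 24 h streams at 1 s frames for the
false-alarm Monte Carlo (piglet false rate 0.02/frame, posture channel
suppressed since only the piglet channel matters there); 100 random
timelines for the exact window-recount equivalence; 20 seeds for
baseline-rate recovery. The 5 s sampling loses ~1.4% of transitions to
within-frame collisions at the 20/h peak — immaterial for the decision
logic, and the monitor is interval-agnostic by construction.

## 7. Known limitations

* Thresholds are global, not per-sow; gilts and sows with atypical
  nest-building profiles will shift the lead time. Threshold learning is
  out of scope.
* Single-stream contract: one sow per stream, no pen association or
  identity tracking; callers parallelise across pens.
* The warning lead under the default profile (~13 h) is a consequence of
  the assumed 12 h peak plateau; shorter plateaus give leads closer to
  5 h at the cost of occasional missed warnings (the peak is only 1.25
  Poisson standard deviations above the threshold per window-hour).
* `duration_d` can be distorted if a pre-onset false-positive episode
  raised the running maximum; with the default debounce this is rare but
  not impossible.
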
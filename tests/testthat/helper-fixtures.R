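# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests write themselves.

# A posture timeline from a label vector ("LL"/"ST"/"SD"/"SI" shorthands or
# full labels or NA), sampled every `interval` seconds.
make_timeline <- function(labels, interval = 1) {
  full <- c(LL = "lateral_lying", ST = "sternal_lying",
            SD = "standing", SI = "sitting")
  lab <- ifelse(labels %in% names(full), full[labels], labels)
  out <- tibble::tibble(
    t = (seq_along(lab) - 1) * interval,
    label = factor(lab, levels = posture_levels())
  )
  attr(out, "sample_interval") <- interval
  out
}

# A single detection event row.
make_event <- function(t, label, conf = 0.9,
                       box = c(0, 0, 10, 10)) {
  detection_stream(t = t, label = label, x_min = box[1], y_min = box[2],
                   x_max = box[3], y_max = box[4], conf = conf)
}

# A stream of piglet detections placed at the given frame indices
# (0-based), one detection per listed frame.
piglet_frames_stream <- function(frames, frame_interval = 1) {
  if (length(frames) == 0) return(detection_stream())
  detection_stream(
    t = frames * frame_interval, label = "piglet",
    x_min = 0, y_min = 0, x_max = 5, y_max = 5, conf = 0.9
  )
}

# Random valid detection stream (posture + piglet events).
random_stream <- function(n, t_max = 100) {
  x0 <- runif(n, 0, 500); y0 <- runif(n, 0, 300)
  detection_stream(
    t = sort(runif(n, 0, t_max)),
    label = sample(event_classes(), n, replace = TRUE),
    x_min = x0, y_min = y0,
    x_max = x0 + runif(n, 1, 100), y_max = y0 + runif(n, 1, 100),
    conf = runif(n)
  )
}

# Random timeline with missing samples, for oracle-equivalence checks.
random_timeline <- function(n, interval = 60, p_missing = 0.1) {
  lab <- sample(posture_levels(), n, replace = TRUE)
  lab[runif(n) < p_missing] <- NA
  out <- tibble::tibble(
    t = (seq_len(n) - 1) * interval,
    label = factor(lab, levels = posture_levels())
  )
  attr(out, "sample_interval") <- interval
  out
}

# Brute-force frequency series: recount every window from scratch with
# count_transitions(); the streaming implementation must match exactly.
brute_force_series <- function(timeline, config) {
  win_s <- config$window_hours * 3600
  step_s <- config$step_hours * 3600
  t0 <- timeline$t[1]
  t_max <- timeline$t[nrow(timeline)]
  if (t_max - t0 < win_s) return(tibble::tibble(t = numeric(), f = numeric()))
  ends <- seq(t0 + win_s, t_max, by = step_s)
  n <- vapply(ends, function(e) count_transitions(timeline, e - win_s, e), 0L)
  tibble::tibble(t = ends, f = n / config$window_hours)
}

# Lattice-count oracle for the GIoU loss on integer-coordinate boxes:
# areas counted as unit cells, so intersection/union/enclosure are exact.
lattice_giou_loss <- function(a, b) {
  cells <- function(v) {
    expand.grid(x = seq(v[1], v[3] - 1), y = seq(v[2], v[4] - 1))
  }
  key <- function(d) paste(d$x, d$y)
  ca <- key(cells(a)); cb <- key(cells(b))
  inter <- length(intersect(ca, cb))
  uni <- length(union(ca, cb))
  enc <- c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
  c_area <- nrow(cells(enc))
  1 - (inter / uni - (c_area - uni) / c_area)
}

# A frequency series fixture directly from values (hours scale).
make_series <- function(f, step_hours = 0.25, window_hours = 1) {
  t0 <- window_hours * 3600
  out <- tibble::tibble(
    t = t0 + (seq_along(f) - 1) * step_hours * 3600,
    f = f
  )
  attr(out, "window_hours") <- window_hours
  attr(out, "step_hours") <- step_hours
  out
}
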
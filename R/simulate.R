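#' Perinatal sow behavior profile
#'
#' Parameterises the instantaneous posture-transition rate (transitions per
#' hour) of a sow across the perinatal window, as a piecewise-linear
#' function of time relative to farrowing onset. The rate follows the
#' three-stage pattern of nest-building behavior:
#'
#' * **Stage A** (until `stage_b_rise_start` hours before onset): baseline
#'   activity at `stage_a_rate`.
#' * **Stage B**: the rate rises linearly to `stage_b_peak_rate` (reached
#'   `stage_b_peak_start` h before onset), stays at the peak until
#'   `stage_b_decline_start` h before onset, then declines linearly to
#'   `stage_b_decline_end_rate` at onset.
#' * **Stage C** (after onset): the sow is nearly still at `stage_c_rate`
#'   for the first hour, then activity recovers linearly to
#'   `stage_c_late_rate` by 24 h post onset.
#'
#' Defaults place the peak above the 17.5/h upper warning threshold and the
#' decline below the 10/h lower threshold; a profile violating either is
#' flagged "non-warning" (attribute `non_warning`), since no dual-threshold
#' warning can be expected from it.
#'
#' @param stage_a_rate Baseline transitions/hour (default 8).
#' @param stage_b_peak_rate Peak transitions/hour (default 20).
#' @param stage_b_rise_start Hours before onset at which the rise begins
#'   (default 24).
#' @param stage_b_peak_start Hours before onset at which the peak is
#'   reached (default 16).
#' @param stage_b_decline_start Hours before onset at which the decline
#'   begins (default 4).
#' @param stage_b_decline_end_rate Transitions/hour at onset (default 2).
#' @param stage_c_rate Transitions/hour just after onset (default 1).
#' @param stage_c_late_rate Transitions/hour 24 h after onset (default 4).
#' @return An object of class `"behavior_profile"`.
#' @export
behavior_profile <- function(stage_a_rate = 8,
                             stage_b_peak_rate = 20,
                             stage_b_rise_start = 24,
                             stage_b_peak_start = 16,
                             stage_b_decline_start = 4,
                             stage_b_decline_end_rate = 2,
                             stage_c_rate = 1,
                             stage_c_late_rate = 4) {
  rates <- c(stage_a_rate, stage_b_peak_rate, stage_b_decline_end_rate,
             stage_c_rate, stage_c_late_rate)
  stopifnot(all(rates >= 0),
            stage_b_rise_start > stage_b_peak_start,
            stage_b_peak_start > stage_b_decline_start,
            stage_b_decline_start > 0)
  p <- structure(
    list(stage_a_rate = stage_a_rate,
         stage_b_peak_rate = stage_b_peak_rate,
         stage_b_rise_start = stage_b_rise_start,
         stage_b_peak_start = stage_b_peak_start,
         stage_b_decline_start = stage_b_decline_start,
         stage_b_decline_end_rate = stage_b_decline_end_rate,
         stage_c_rate = stage_c_rate,
         stage_c_late_rate = stage_c_late_rate),
    class = "behavior_profile"
  )
  non_warning <- !(stage_b_peak_rate > 17.5 && stage_b_decline_end_rate < 10)
  if (non_warning) {
    warning("profile peak/decline do not straddle the 17.5 / 10 per-hour ",
            "warning thresholds; scenario flagged non-warning")
  }
  attr(p, "non_warning") <- non_warning
  p
}

#' Instantaneous transition rate of a profile
#'
#' @param profile A [behavior_profile()].
#' @param hours_rel Numeric vector of times in hours relative to farrowing
#'   onset (negative = before onset).
#' @return Transitions/hour at each time.
#' @export
transition_rate <- function(profile, hours_rel) {
  stopifnot(inherits(profile, "behavior_profile"))
  p <- profile
  h <- hours_rel
  rise_len <- p$stage_b_rise_start - p$stage_b_peak_start
  decl_len <- p$stage_b_decline_start
  out <- ifelse(
    h < -p$stage_b_rise_start, p$stage_a_rate,
    ifelse(h < -p$stage_b_peak_start,
      p$stage_a_rate + (p$stage_b_peak_rate - p$stage_a_rate) *
        (h + p$stage_b_rise_start) / rise_len,
    ifelse(h < -p$stage_b_decline_start, p$stage_b_peak_rate,
    ifelse(h < 0,
      p$stage_b_peak_rate + (p$stage_b_decline_end_rate - p$stage_b_peak_rate) *
        (h + decl_len) / decl_len,
    ifelse(h < 1, p$stage_c_rate,
      p$stage_c_rate + (p$stage_c_late_rate - p$stage_c_rate) *
        pmin((h - 1) / 23, 1))))))
  out
}

#' Litter model
#'
#' Birth-process parameters for a farrowing: litter size is drawn from a
#' Poisson distribution truncated below at `min_litter`, and inter-birth
#' intervals are exponential.
#'
#' @param mean_litter Mean of the (untruncated) Poisson litter size
#'   (default 12).
#' @param min_litter Smallest admissible litter (default 1).
#' @param mean_birth_interval_min Mean minutes between consecutive births
#'   (default 15).
#' @return An object of class `"litter_model"`.
#' @export
litter_model <- function(mean_litter = 12, min_litter = 1,
                         mean_birth_interval_min = 15) {
  stopifnot(mean_litter > 0, min_litter >= 1, mean_birth_interval_min > 0)
  structure(
    list(mean_litter = mean_litter, min_litter = as.integer(min_litter),
         mean_birth_interval_min = mean_birth_interval_min),
    class = "litter_model"
  )
}

#' Detector noise profile
#'
#' Per-frame error rates of an object detector, used to corrupt a ground
#' truth script into a realistic detection stream.
#'
#' @param scenario Name of the scenario.
#' @param posture_miss_rate Probability that a frame emits no posture
#'   detection.
#' @param posture_false_rate Probability that an emitted posture detection
#'   carries a wrong label (uniform over the three incorrect postures).
#' @param piglet_miss_prob Probability, per piglet per frame, that an
#'   already-born piglet is not detected.
#' @param piglet_false_rate Expected number of false piglet boxes per frame
#'   (Poisson).
#' @return An object of class `"noise_profile"`.
#' @seealso [noise_presets()]
#' @export
noise_profile <- function(scenario = "custom",
                          posture_miss_rate = 0,
                          posture_false_rate = 0,
                          piglet_miss_prob = 0,
                          piglet_false_rate = 0) {
  probs <- c(posture_miss_rate, posture_false_rate, piglet_miss_prob)
  stopifnot(all(probs >= 0 & probs <= 1), piglet_false_rate >= 0)
  structure(
    list(scenario = scenario,
         posture_miss_rate = posture_miss_rate,
         posture_false_rate = posture_false_rate,
         piglet_miss_prob = piglet_miss_prob,
         piglet_false_rate = piglet_false_rate),
    class = "noise_profile"
  )
}

#' Scenario presets for detector noise
#'
#' Ready-made [noise_profile()]s for the four complex farm scenarios in
#' which detector error rates were measured on a 410-image test set:
#' posture miss/false rates are the reported percentages; piglet errors
#' were reported as absolute counts over the 410 images and are converted
#' to per-frame rates with an assumed denominator of one visible piglet
#' per image (an assumption, not a measured rate; tune per deployment).
#'
#' @return Named list of [noise_profile()] objects: `none`,
#'   `complex_light`, `first_piglet_born`, `different_color_heat_lamp`,
#'   `heat_lamp_night`.
#' @export
noise_presets <- function() {
  list(
    none = noise_profile("none"),
    complex_light = noise_profile(
      "complex_light", posture_miss_rate = 0.0633,
      posture_false_rate = 0.1519,
      piglet_miss_prob = 0, piglet_false_rate = 11 / 410),
    first_piglet_born = noise_profile(
      "first_piglet_born", posture_miss_rate = 0, posture_false_rate = 0,
      piglet_miss_prob = 2 / 410, piglet_false_rate = 5 / 410),
    different_color_heat_lamp = noise_profile(
      "different_color_heat_lamp", posture_miss_rate = 0,
      posture_false_rate = 0.012,
      piglet_miss_prob = 7 / 410, piglet_false_rate = 1 / 410),
    heat_lamp_night = noise_profile(
      "heat_lamp_night", posture_miss_rate = 0.0336,
      posture_false_rate = 0.0756,
      piglet_miss_prob = 15 / 410, piglet_false_rate = 10 / 410)
  )
}

#' Simulate one perinatal sow
#'
#' Generates a ground-truth script for a single sow: the true posture path
#' (a continuous-time jump process whose transition clock is an
#' inhomogeneous exponential with instantaneous rate given by the
#' [behavior_profile()]), plus a farrowing with litter size and birth times
#' from the [litter_model()]. At each transition the new posture is drawn
#' uniformly from the three postures different from the current one.
#' Transition times are sampled by Poisson thinning against the profile's
#' maximum rate.
#'
#' All script times are in seconds from stream start (the beginning of the
#' horizon); farrowing onset, i.e. the first birth, maps to
#' `-horizon[1] * 3600` seconds.
#'
#' @param profile A [behavior_profile()].
#' @param litter A [litter_model()].
#' @param horizon Length-2 numeric, hours relative to farrowing onset,
#'   `horizon[1] < 0 < horizon[2]` (default `c(-48, 24)`).
#' @param seed Integer seed; the script is fully reproducible from it.
#' @return An object of class `"sow_script"`: list with `posture_path`
#'   (tibble of change points `t`, `label`; the initial posture at `t = 0`
#'   followed by one row per transition), `birth_times` (seconds,
#'   increasing), `farrow_onset` (seconds, `= birth_times[1]`),
#'   `litter_size`, `horizon`, and `span_seconds`.
#' @export
simulate_sow <- function(profile = behavior_profile(),
                         litter = litter_model(),
                         horizon = c(-48, 24), seed = NULL) {
  stopifnot(inherits(profile, "behavior_profile"),
            inherits(litter, "litter_model"),
            length(horizon) == 2)
  if (!(horizon[1] < 0 && horizon[2] > 0)) {
    stop("degenerate horizon: need horizon[1] < 0 < horizon[2]")
  }
  if (!is.null(seed)) set.seed(seed)
  span_h <- horizon[2] - horizon[1]
  # max of a piecewise-linear function is attained at a node
  nodes <- c(horizon[1], -profile$stage_b_rise_start,
             -profile$stage_b_peak_start, -profile$stage_b_decline_start,
             0, 1, horizon[2])
  nodes <- pmin(pmax(nodes, horizon[1]), horizon[2])
  rate_max <- max(transition_rate(profile, nodes))
  trans_h <- numeric(0)
  if (rate_max > 0) {
    n_cand <- stats::rpois(1, rate_max * span_h)
    cand <- sort(stats::runif(n_cand, 0, span_h))
    keep <- stats::runif(n_cand) <
      transition_rate(profile, horizon[1] + cand) / rate_max
    trans_h <- cand[keep]
  }
  n_trans <- length(trans_h)
  labels <- integer(n_trans + 1L)
  labels[1L] <- sample.int(4L, 1L)
  if (n_trans > 0) {
    # uniform over the three postures != current
    step <- sample.int(3L, n_trans, replace = TRUE)
    for (i in seq_len(n_trans)) {
      labels[i + 1L] <- ((labels[i] - 1L + step[i]) %% 4L) + 1L
    }
  }
  posture_path <- tibble::tibble(
    t = c(0, trans_h * 3600),
    label = factor(posture_levels()[labels], levels = posture_levels())
  )
  litter_size <- 0L
  while (litter_size < litter$min_litter) {
    litter_size <- stats::rpois(1, litter$mean_litter)
  }
  onset_s <- -horizon[1] * 3600
  gaps <- if (litter_size > 1) {
    stats::rexp(litter_size - 1L, rate = 1 / (litter$mean_birth_interval_min * 60))
  } else {
    numeric(0)
  }
  birth_times <- onset_s + c(0, cumsum(gaps))
  structure(
    list(posture_path = posture_path,
         birth_times = birth_times,
         farrow_onset = onset_s,
         litter_size = as.integer(litter_size),
         horizon = horizon,
         span_seconds = span_h * 3600),
    class = "sow_script"
  )
}

#' @export
print.sow_script <- function(x, ...) {
  cat("<sow_script> ", x$horizon[1], "..", x$horizon[2], " h, ",
      nrow(x$posture_path) - 1L, " posture transitions, litter ",
      x$litter_size, " (onset at ", x$farrow_onset, " s)\n", sep = "")
  invisible(x)
}

#' Corrupt a ground-truth script into a detection stream
#'
#' Emulates a frame-based object detector watching the simulated sow. For
#' every frame on the grid `0, frame_interval, 2 * frame_interval, ...`:
#'
#' * with probability `posture_miss_rate` no posture box is emitted;
#'   otherwise one posture box is emitted, carrying the true posture, or —
#'   with probability `posture_false_rate` — a label drawn uniformly from
#'   the three incorrect postures;
#' * every piglet born at or before the frame time is detected
#'   independently with probability `1 - piglet_miss_prob`;
#' * a Poisson(`piglet_false_rate`) number of false piglet boxes is added.
#'
#' Box geometry is synthesised inside the pen rectangle; confidences are
#' uniform on `[0.5, 1]`. The stream is reproducible from the seed.
#'
#' @param script A [simulate_sow()] result.
#' @param noise A [noise_profile()].
#' @param frame_interval Seconds between frames (default 1).
#' @param seed Integer seed.
#' @param pen Pen rectangle `c(x_min, y_min, x_max, y_max)` in pixels.
#' @return A detection stream tibble (see [detection_stream()]), sorted by
#'   time.
#' @export
apply_detector_noise <- function(script, noise = noise_profile(),
                                 frame_interval = 1, seed = NULL,
                                 pen = c(0, 0, 1280, 720)) {
  stopifnot(inherits(script, "sow_script"), inherits(noise, "noise_profile"),
            frame_interval > 0, length(pen) == 4,
            pen[1] < pen[3], pen[2] < pen[4])
  if (!is.null(seed)) set.seed(seed)
  n_frames <- as.integer(ceiling(script$span_seconds / frame_interval))
  t_frame <- (seq_len(n_frames) - 1) * frame_interval

  # posture channel
  true_idx <- findInterval(t_frame, script$posture_path$t)
  true_lab <- as.integer(script$posture_path$label)[true_idx]
  emitted <- stats::runif(n_frames) >= noise$posture_miss_rate
  lab <- true_lab[emitted]
  flip <- stats::runif(sum(emitted)) < noise$posture_false_rate
  if (any(flip)) {
    lab[flip] <- ((lab[flip] - 1L +
                     sample.int(3L, sum(flip), replace = TRUE)) %% 4L) + 1L
  }
  n_post <- sum(emitted)
  sow_w <- min(400, (pen[3] - pen[1]) * 0.6)
  sow_h <- min(250, (pen[4] - pen[2]) * 0.6)
  sx <- stats::runif(n_post, pen[1], pen[3] - sow_w)
  sy <- stats::runif(n_post, pen[2], pen[4] - sow_h)
  posture_events <- tibble::tibble(
    t = t_frame[emitted],
    label = posture_levels()[lab],
    x_min = sx, y_min = sy, x_max = sx + sow_w, y_max = sy + sow_h,
    conf = stats::runif(n_post, 0.5, 1)
  )

  # piglet channel
  born <- findInterval(t_frame, script$birth_times)
  detected <- stats::rbinom(n_frames, born, 1 - noise$piglet_miss_prob)
  false_boxes <- stats::rpois(n_frames, noise$piglet_false_rate)
  per_frame <- detected + false_boxes
  n_pig <- sum(per_frame)
  pig_w <- min(60, (pen[3] - pen[1]) * 0.1)
  pig_h <- min(40, (pen[4] - pen[2]) * 0.1)
  px <- stats::runif(n_pig, pen[1], pen[3] - pig_w)
  py <- stats::runif(n_pig, pen[2], pen[4] - pig_h)
  piglet_events <- tibble::tibble(
    t = rep(t_frame, per_frame),
    label = "piglet",
    x_min = px, y_min = py, x_max = px + pig_w, y_max = py + pig_h,
    conf = stats::runif(n_pig, 0.5, 1)
  )

  out <- rbind(posture_events, piglet_events)
  out <- out[order(out$t), , drop = FALSE]
  tibble::as_tibble(out)
}
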
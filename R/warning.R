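#' Warning-engine configuration
#'
#' Thresholds and window parameters of the dual-threshold persistence rule
#' for pre-farrowing warnings. The posture-transition frequency is computed
#' on a sliding window of `window_hours` advanced by `step_hours`; an upper
#' warning requires the frequency to stay above `upper_threshold` for more
#' than `persistence_hours`, and (after the upper warning) a lower warning
#' requires it to stay below `lower_threshold` for the same persistence.
#' Sub-threshold dips shorter than `grace_hours` do not reset the
#' persistence clock (see [evaluate_warnings()] for the exact rule).
#'
#' @param upper_threshold Transitions/hour (default 17.5).
#' @param lower_threshold Transitions/hour (default 10).
#' @param persistence_hours Hours the condition must be sustained
#'   (default 5).
#' @param window_hours Sliding-window length in hours (default 1).
#' @param step_hours Window step in hours (default 0.25).
#' @param grace_hours Longest tolerated interruption of the threshold
#'   condition, hours (default 3).
#' @param target_lead_hours Intended warning lead used by
#'   [warning_error()] (default 5).
#' @return An object of class `"warning_config"`.
#' @export
warning_config <- function(upper_threshold = 17.5, lower_threshold = 10,
                           persistence_hours = 5, window_hours = 1,
                           step_hours = 0.25, grace_hours = 3,
                           target_lead_hours = 5) {
  stopifnot(upper_threshold > lower_threshold, lower_threshold > 0,
            persistence_hours > 0, window_hours > 0, step_hours > 0,
            grace_hours >= 0, target_lead_hours >= 0)
  structure(
    list(upper_threshold = upper_threshold,
         lower_threshold = lower_threshold,
         persistence_hours = persistence_hours,
         window_hours = window_hours,
         step_hours = step_hours,
         grace_hours = grace_hours,
         target_lead_hours = target_lead_hours),
    class = "warning_config"
  )
}

#' Count posture transitions in a time interval
#'
#' Counts, among the timeline samples with `t_from <= t < t_to`, the
#' consecutive pairs of non-missing samples whose labels differ. Missing
#' samples are skipped, so a change observed across a detector dropout
#' (`a, NA, b` with `a != b`) still counts as one transition.
#'
#' @param timeline A posture timeline (see [timeline_from_stream()]): data
#'   frame with columns `t` (seconds, strictly increasing) and `label`.
#' @param t_from,t_to Interval bounds in seconds, `t_from < t_to`.
#' @return Integer number of transitions.
#' @export
count_transitions <- function(timeline, t_from, t_to) {
  stopifnot(is.data.frame(timeline), t_from < t_to)
  inside <- timeline$t >= t_from & timeline$t < t_to
  lab <- as.integer(timeline$label[inside])
  lab <- lab[!is.na(lab)]
  if (length(lab) < 2) return(0L)
  sum(diff(lab) != 0L)
}

#' Posture-transition frequency
#'
#' The warning statistic: `f = n / T`, the number of posture transitions
#' per hour.
#'
#' @param n Number of transitions.
#' @param t_hours Observation time in hours, `> 0`.
#' @return Transitions per hour.
#' @export
#' @examples
#' transition_frequency(35, 2) # 17.5
transition_frequency <- function(n, t_hours) {
  if (any(t_hours <= 0)) stop("t_hours must be positive")
  n / t_hours
}

#' Sliding-window frequency series
#'
#' Computes the posture-transition frequency on a sliding window of
#' `window_hours`, advanced by `step_hours`, over the whole timeline. Each
#' point reports the window's end time and the frequency of the
#' transitions inside it, with the same counting rule as
#' [count_transitions()].
#'
#' @param timeline A posture timeline.
#' @param config A [warning_config()].
#' @return A tibble with columns `t` (window end, seconds) and `f`
#'   (transitions/hour), class `"frequency_series"`, with attributes
#'   `window_hours` and `step_hours`. Empty (with a message) if the
#'   timeline is shorter than one window.
#' @export
frequency_series <- function(timeline, config = warning_config()) {
  stopifnot(is.data.frame(timeline), inherits(config, "warning_config"))
  win_s <- config$window_hours * 3600
  step_s <- config$step_hours * 3600
  empty <- structure(
    tibble::tibble(t = numeric(), f = numeric()),
    window_hours = config$window_hours, step_hours = config$step_hours,
    class = c("frequency_series", class(tibble::tibble())))
  if (nrow(timeline) == 0) {
    message("timeline shorter than one window; empty frequency series")
    return(empty)
  }
  t0 <- timeline$t[1]
  t_max <- timeline$t[nrow(timeline)]
  if (t_max - t0 < win_s) {
    message("timeline shorter than one window; empty frequency series")
    return(empty)
  }
  ends <- seq(t0 + win_s, t_max, by = step_s)
  # transition i sits between consecutive non-missing samples at a_i < b_i;
  # it falls in a window [from, to) iff a_i >= from and b_i < to. Both
  # vectors are increasing, so each condition cuts a prefix/suffix.
  keep <- !is.na(timeline$label)
  tt <- timeline$t[keep]
  lab <- as.integer(timeline$label[keep])
  if (length(lab) >= 2) {
    changed <- diff(lab) != 0L
    a <- tt[-length(tt)][changed]
    b <- tt[-1][changed]
  } else {
    a <- b <- numeric(0)
  }
  n_before_b <- findInterval(ends, b, left.open = TRUE)     # b_i < end
  n_before_a <- findInterval(ends - win_s, a, left.open = TRUE) # a_i < from
  n <- n_before_b - n_before_a
  out <- tibble::tibble(t = ends, f = transition_frequency(n, config$window_hours))
  attr(out, "window_hours") <- config$window_hours
  attr(out, "step_hours") <- config$step_hours
  class(out) <- c("frequency_series", class(out))
  out
}

# Scan a series for one sustained threshold crossing.
# cond: logical vector, TRUE where the threshold condition holds pointwise.
# Sustainment: a condition run starts at the first TRUE point and survives
# interruptions shorter than grace_h; emission occurs at the first point
# where the run has lasted >= persist_h AND the mean of f over the trailing
# persistence window is beyond the threshold (direction given by `upper`).
# Returns c(onset, emitted) in seconds, or NULL.
scan_condition <- function(t, f, cond, threshold, upper, persist_s, grace_s) {
  run_start <- NA_real_
  last_true <- -Inf
  for (i in seq_along(t)) {
    if (cond[i]) {
      if (is.na(run_start)) run_start <- t[i]
      last_true <- t[i]
    } else if (!is.na(run_start) && t[i] - last_true > grace_s) {
      run_start <- NA_real_
    }
    if (!is.na(run_start) && t[i] - run_start >= persist_s) {
      trail <- t > t[i] - persist_s & t <= t[i]
      m <- mean(f[trail])
      if ((upper && m > threshold) || (!upper && m < threshold)) {
        return(c(onset = run_start, emitted = t[i]))
      }
    }
  }
  NULL
}

#' Evaluate the dual-threshold warning strategy
#'
#' Runs the pre-farrowing warning state machine over a frequency series:
#'
#' 1. **Upper warning** — emitted once the frequency has stayed above
#'    `upper_threshold` for more than `persistence_hours`. A sustained
#'    exceedance is a run of above-threshold points in which interruptions
#'    shorter than `grace_hours` are tolerated; emission additionally
#'    requires the mean frequency over the trailing persistence window to
#'    exceed the threshold, so that a run kept alive by the grace rule
#'    cannot fire while the frequency is only sporadically high.
#' 2. **Lower warning** — armed only after the upper warning (otherwise a
#'    resting sow, whose frequency is near 0, would warn constantly);
#'    emitted by the symmetric rule for staying below `lower_threshold`.
#'
#' At most one event of each kind is emitted per run (state machine
#' idle -> upper fired -> lower fired). `emitted_at - condition_onset`
#' equals the persistence on clean (uninterrupted) exceedances and can
#' exceed it when the trailing-mean gate defers emission.
#'
#' @param series A [frequency_series()].
#' @param config A [warning_config()].
#' @return A tibble of warning events with columns `kind` (`"upper"` /
#'   `"lower"`), `condition_onset` and `emitted_at` (seconds); zero rows if
#'   nothing fired.
#' @export
evaluate_warnings <- function(series, config = warning_config()) {
  stopifnot(is.data.frame(series), inherits(config, "warning_config"))
  out <- tibble::tibble(kind = character(), condition_onset = numeric(),
                        emitted_at = numeric())
  if (nrow(series) == 0) return(out)
  persist_s <- config$persistence_hours * 3600
  grace_s <- config$grace_hours * 3600
  up <- scan_condition(series$t, series$f, series$f > config$upper_threshold,
                       config$upper_threshold, upper = TRUE,
                       persist_s, grace_s)
  if (is.null(up)) return(out)
  out <- tibble::add_row(out, kind = "upper",
                         condition_onset = up[["onset"]],
                         emitted_at = up[["emitted"]])
  after <- series$t > up[["emitted"]]
  if (any(after)) {
    t2 <- series$t[after]
    f2 <- series$f[after]
    lo <- scan_condition(t2, f2, f2 < config$lower_threshold,
                         config$lower_threshold, upper = FALSE,
                         persist_s, grace_s)
    if (!is.null(lo)) {
      out <- tibble::add_row(out, kind = "lower",
                             condition_onset = lo[["onset"]],
                             emitted_at = lo[["emitted"]])
    }
  }
  out
}

#' Warning timing error
#'
#' Compares the emission time of an upper warning with the true farrowing
#' onset. The raw lead is `(true_farrow_onset - emitted_at)` in hours
#' (positive = warning before onset); the error is the absolute deviation
#' of the lead from the configured target lead. A negative lead flags a
#' late warning.
#'
#' @param emitted_at Warning emission time(s), seconds.
#' @param true_farrow_onset True onset time(s), seconds.
#' @param target_lead_hours Intended lead (default 5 h).
#' @return A tibble with columns `lead_hours`, `error_hours`, `late`.
#' @export
#' @examples
#' warning_error(5 * 3600, 10 * 3600)          # lead 5 h, error 0
#' warning_error(0, -3600)                     # late by 1 h, error 6 h
warning_error <- function(emitted_at, true_farrow_onset,
                          target_lead_hours = 5) {
  lead <- (true_farrow_onset - emitted_at) / 3600
  tibble::tibble(
    lead_hours = lead,
    error_hours = abs(lead - target_lead_hours),
    late = lead < 0
  )
}
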
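#' Farrowing-monitor configuration
#'
#' @param k_consecutive Number of consecutive piglet-positive frames
#'   required before the farrowing alarm fires (default 3, the
#'   "three consecutive detections" debounce).
#' @param end_quiet_hours Hours without a new running-maximum piglet count
#'   after which the farrowing end time is considered final (default 1).
#' @return An object of class `"monitor_config"`.
#' @export
monitor_config <- function(k_consecutive = 3L, end_quiet_hours = 1) {
  stopifnot(k_consecutive >= 1, end_quiet_hours >= 0)
  structure(
    list(k_consecutive = as.integer(k_consecutive),
         end_quiet_hours = end_quiet_hours),
    class = "monitor_config"
  )
}

#' Alert sinks
#'
#' An alert sink is a destination for alarm messages — the software
#' abstraction of the farm-side LED/GPIO signalling. A sink is a list with
#' an `emit(message, t)` function; emitting never mutates monitor state.
#' `console_sink()` prints to the console, `log_sink()` appends to a text
#' file, and `mock_sink()` records messages in memory for tests
#' (retrieve them with [sink_messages()]).
#'
#' @param path File the log sink appends to.
#' @return An object of class `"alert_sink"`.
#' @name alert_sinks
NULL

#' @rdname alert_sinks
#' @export
console_sink <- function() {
  structure(list(emit = function(message, t) {
    cat(sprintf("[t=%.1fs] %s\n", t, message))
  }), class = "alert_sink")
}

#' @rdname alert_sinks
#' @export
log_sink <- function(path) {
  structure(list(emit = function(message, t) {
    cat(sprintf("[t=%.1fs] %s\n", t, message), file = path, append = TRUE)
  }), class = "alert_sink")
}

#' @rdname alert_sinks
#' @export
mock_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$messages <- character()
  env$times <- numeric()
  structure(list(
    emit = function(message, t) {
      env$messages <- c(env$messages, message)
      env$times <- c(env$times, t)
    },
    env = env
  ), class = "alert_sink")
}

#' Messages recorded by a mock sink
#'
#' @param sink A [mock_sink()].
#' @return Tibble with columns `t` and `message`.
#' @export
sink_messages <- function(sink) {
  stopifnot(inherits(sink, "alert_sink"), !is.null(sink$env))
  tibble::tibble(t = sink$env$times, message = sink$env$messages)
}

# Per-frame piglet counts on the monitor's frame grid.
frame_piglet_counts <- function(events, frame_interval, span = NULL) {
  stopifnot(is.data.frame(events), frame_interval > 0)
  if (is.null(span)) {
    span <- if (nrow(events) > 0) max(events$t) else 0
    n_frames <- as.integer(floor(span / frame_interval)) + 1L
  } else {
    stopifnot(span > 0)
    n_frames <- as.integer(ceiling(span / frame_interval))
  }
  pig_t <- events$t[events$label == "piglet"]
  idx <- floor(pig_t / frame_interval) + 1L
  idx <- idx[idx >= 1L & idx <= n_frames]
  list(
    t = (seq_len(n_frames) - 1) * frame_interval,
    cur = tabulate(idx, nbins = n_frames)
  )
}

# First maximal run of >= k TRUE values; returns start index or NA.
first_run_at_least <- function(x, k) {
  r <- rle(x)
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) return(NA_integer_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[hit[1]]
}

#' Supervise a detection stream for farrowing
#'
#' Replays a detection stream on the frame grid
#' `[k * frame_interval, (k + 1) * frame_interval)` and applies the
#' debounced farrowing-alarm logic: a frame is piglet-positive if at least
#' one piglet detection falls in it, and the alarm fires at the first run
#' of `k_consecutive` piglet-positive frames. The estimated farrowing
#' start `t_start` is the time of the first frame of that run (the best
#' available estimate of the first birth). The per-frame piglet count
#' `cur_num` is the number of piglet boxes in the frame; `detected_num` is
#' its running maximum — the monotone litter estimate. The farrowing end
#' `t_end` is the time of the last frame that raised the running maximum,
#' finalised once `end_quiet_hours` pass without a new maximum; the
#' farrowing duration is `t_end - t_start`.
#'
#' On alarm, the message `"Delivery Begin! Start time: <timestamp>"` is
#' dispatched exactly once to every sink; the timestamp is ISO-8601 wall
#' clock when `stream_start` is given, otherwise an ISO-8601 duration from
#' stream start.
#'
#' @param events Detection stream (validate with [validate_stream()]).
#' @param frame_interval Seconds between frames.
#' @param config A [monitor_config()].
#' @param sinks List of [alert_sinks] to notify on alarm.
#' @param span Stream span in seconds (defaults to the last event time).
#' @param stream_start Optional `POSIXct` anchoring `t = 0` to wall clock.
#' @return A list with `state` (a [farrowing_state()]), `alarms` (tibble
#'   `t`, `message`), and `frames` (tibble `t`, `cur_num`, `detected_num`).
#' @export
process_stream <- function(events, frame_interval,
                           config = monitor_config(), sinks = list(),
                           span = NULL, stream_start = NULL) {
  stopifnot(inherits(config, "monitor_config"))
  fc <- frame_piglet_counts(events, frame_interval, span)
  cur <- fc$cur
  detected <- cummax(cur)
  n <- length(cur)
  start_idx <- first_run_at_least(cur >= 1L, config$k_consecutive)
  alarms <- tibble::tibble(t = numeric(), message = character())
  if (is.na(start_idx)) {
    state <- farrowing_state(0L, cur_num = cur[n], detected_num = detected[n])
  } else {
    t_start <- fc$t[start_idx]
    raised <- which(cur == detected & detected > c(0L, detected[-n]))
    t_last_raise <- fc$t[max(raised)]
    quiet_s <- config$end_quiet_hours * 3600
    t_end <- if (fc$t[n] - t_last_raise >= quiet_s) t_last_raise else NULL
    state <- farrowing_state(1L, t_start = t_start, t_end = t_end,
                             cur_num = cur[n], detected_num = detected[n])
    msg <- paste0("Delivery Begin! Start time: ",
                  format_alarm_time(t_start, stream_start))
    alarms <- tibble::tibble(t = t_start, message = msg)
    for (s in sinks) s$emit(msg, t_start)
  }
  list(state = state, alarms = alarms,
       frames = tibble::tibble(t = fc$t, cur_num = cur, detected_num = detected))
}

format_alarm_time <- function(t_seconds, stream_start = NULL) {
  if (is.null(stream_start)) {
    sprintf("PT%.0fS", t_seconds) # ISO-8601 duration from stream start
  } else {
    format(stream_start + t_seconds, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
}

#' Count false farrowing alarms
#'
#' A false alarm is a maximal run of at least `k` consecutive
#' piglet-positive frames that begins before the true farrowing onset.
#' Counting per episode (per maximal run, not per frame) matches how a
#' stockperson experiences an alarm.
#'
#' @param events Detection stream.
#' @param script Ground-truth [simulate_sow()] script.
#' @param frame_interval Seconds between frames.
#' @param k Debounce length (1 = single detection, 3 = three consecutive
#'   detections).
#' @return Integer number of false alarms.
#' @export
count_false_alarms <- function(events, script, frame_interval, k) {
  stopifnot(inherits(script, "sow_script"), k >= 1)
  fc <- frame_piglet_counts(events, frame_interval, span = script$span_seconds)
  r <- rle(fc$cur >= 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  eligible <- r$values & r$lengths >= k
  sum(eligible & fc$t[starts] < script$farrow_onset)
}

#' Per-frame piglet-count table
#'
#' Aligns the monitor's per-frame counts with the ground truth: `cur_num`
#' piglet boxes in the frame, `detected_num` the running maximum, and
#' `true_num` the number of piglets born at or before the frame time.
#' This table is the input to the counting-accuracy metrics [ca_da()].
#'
#' @param events Detection stream.
#' @param script Ground-truth [simulate_sow()] script.
#' @param frame_interval Seconds between frames.
#' @param span Stream span in seconds (defaults to the script's span).
#' @return Tibble with columns `t`, `cur_num`, `detected_num`, `true_num`.
#' @export
piglet_count_report <- function(events, script, frame_interval, span = NULL) {
  stopifnot(inherits(script, "sow_script"))
  if (is.null(span)) span <- script$span_seconds
  fc <- frame_piglet_counts(events, frame_interval, span = span)
  tibble::tibble(
    t = fc$t,
    cur_num = fc$cur,
    detected_num = cummax(fc$cur),
    true_num = findInterval(fc$t, script$birth_times)
  )
}
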
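#' Sow posture vocabulary
#'
#' The four mutually exclusive sow postures recognised by the pipeline.
#' Newborn piglets are a separate object class, never a posture.
#'
#' @return Character vector of the four posture labels.
#' @export
#' @examples
#' posture_levels()
posture_levels <- function() {
  c("lateral_lying", "sternal_lying", "standing", "sitting")
}

#' Detection-stream class vocabulary
#'
#' @return Character vector of the five object classes a detector emits:
#'   the four postures plus `"piglet"`.
#' @export
event_classes <- function() {
  c(posture_levels(), "piglet")
}

#' Build a detection stream
#'
#' Assembles detector outputs into the canonical stream layout used across
#' the package: one row per detection with time (seconds from stream
#' start), class label, axis-aligned bounding box in pixel coordinates
#' (origin top-left), and confidence.
#'
#' @param t Numeric, seconds since stream start.
#' @param label Character, one of [event_classes()].
#' @param x_min,y_min,x_max,y_max Box corners in pixels; `x_min < x_max`,
#'   `y_min < y_max`.
#' @param conf Detector confidence in `[0, 1]`.
#' @return A tibble with columns `t`, `label`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `conf`.
#' @export
detection_stream <- function(t = numeric(), label = character(),
                             x_min = numeric(), y_min = numeric(),
                             x_max = numeric(), y_max = numeric(),
                             conf = numeric()) {
  tibble::tibble(
    t = as.numeric(t), label = as.character(label),
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    conf = as.numeric(conf)
  )
}

stream_columns <- c("t", "label", "x_min", "y_min", "x_max", "y_max", "conf")

#' Validate and sort a detection stream
#'
#' Rejects malformed records (unknown label, inverted or zero-area box,
#' confidence outside `[0, 1]`, negative or non-finite time) without
#' crashing, and returns the surviving events sorted by time. The
#' rejections are attached as an attribute and summarised in a message.
#'
#' @param events Data frame in the [detection_stream()] layout.
#' @param quiet Suppress the rejection-count message.
#' @return The valid events, sorted by `t`, with attribute `"rejections"`:
#'   a tibble of `row` (position in the input) and `reason`.
#' @seealso [stream_rejections()]
#' @export
validate_stream <- function(events, quiet = FALSE) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(stream_columns, names(events))
  if (length(missing_cols) > 0) {
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(events)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    bad_t <- !is.finite(events$t) | events$t < 0
    bad_label <- !(events$label %in% event_classes())
    bad_box <- !is.finite(events$x_min) | !is.finite(events$y_min) |
      !is.finite(events$x_max) | !is.finite(events$y_max) |
      events$x_min >= events$x_max | events$y_min >= events$y_max
    bad_conf <- !is.finite(events$conf) | events$conf < 0 | events$conf > 1
    reason[bad_conf] <- "confidence outside [0, 1]"
    reason[bad_box] <- "inverted or degenerate bounding box"
    reason[bad_label] <- "unknown class label"
    reason[bad_t] <- "negative or non-finite time"
  }
  keep <- is.na(reason)
  rejections <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  out <- tibble::as_tibble(events[keep, stream_columns, drop = FALSE])
  out <- out[order(out$t), , drop = FALSE]
  attr(out, "rejections") <- rejections
  if (!quiet && nrow(rejections) > 0) {
    message(nrow(rejections), " of ", n, " stream record(s) rejected")
  }
  out
}

#' Rejection report of a validated stream
#'
#' @param x Object returned by [validate_stream()] or [read_stream()].
#' @return Tibble of rejected records and reasons (empty if none).
#' @export
stream_rejections <- function(x) {
  r <- attr(x, "rejections")
  if (is.null(r)) tibble::tibble(row = integer(), reason = character()) else r
}

#' Posture timeline from a detection stream
#'
#' Resamples a detection stream onto a regular grid of half-open intervals
#' `[k * interval, (k + 1) * interval)`. Each interval's posture is the
#' class of the highest-confidence sow-posture detection falling inside it
#' (ties broken by the earlier detection); intervals with no posture
#' detection are `NA` ("missing"), mirroring a detector that emitted
#' nothing. Piglet detections never contribute a posture.
#'
#' @param events Detection stream (validated; see [validate_stream()]).
#' @param sample_interval Grid spacing in seconds, `> 0`.
#' @param span Stream span in seconds. Defaults to the time of the last
#'   event, so the timeline has `ceiling(span / sample_interval)` samples
#'   (one more when the last event sits exactly on a grid point). Events at
#'   or beyond `span` are dropped.
#' @return A tibble with columns `t` (interval start, seconds) and `label`
#'   (factor over [posture_levels()], `NA` = missing), one row per
#'   interval; attribute `"sample_interval"` records the grid spacing.
#' @export
timeline_from_stream <- function(events, sample_interval, span = NULL) {
  stopifnot(is.data.frame(events), sample_interval > 0)
  post <- events[events$label %in% posture_levels(), , drop = FALSE]
  if (is.null(span)) {
    if (nrow(events) == 0) {
      return(empty_timeline(sample_interval))
    }
    span <- max(events$t)
    n_int <- floor(span / sample_interval) + 1L
  } else {
    stopifnot(span > 0)
    n_int <- as.integer(ceiling(span / sample_interval))
  }
  idx <- floor(post$t / sample_interval) + 1L # 1-based interval index
  inside <- idx >= 1L & idx <= n_int
  post <- post[inside, , drop = FALSE]
  idx <- idx[inside]
  label <- rep(NA_character_, n_int)
  if (nrow(post) > 0) {
    # highest confidence wins within an interval; tie -> earlier detection
    ord <- order(idx, -post$conf, post$t)
    first <- !duplicated(idx[ord])
    label[idx[ord][first]] <- post$label[ord][first]
  }
  out <- tibble::tibble(
    t = (seq_len(n_int) - 1) * sample_interval,
    label = factor(label, levels = posture_levels())
  )
  attr(out, "sample_interval") <- sample_interval
  out
}

empty_timeline <- function(sample_interval = NA_real_) {
  out <- tibble::tibble(
    t = numeric(),
    label = factor(character(), levels = posture_levels())
  )
  attr(out, "sample_interval") <- sample_interval
  out
}

#' Farrowing supervision state
#'
#' Container for the outcome of supervising one stream: the alarm flag,
#' estimated farrowing start/end and duration, and the piglet counts.
#' `alarm == 1L` exactly when `t_start` is set; `duration_d` is
#' `t_end - t_start` when both ends are known and `NULL` otherwise.
#'
#' @param alarm 0 or 1.
#' @param t_start,t_end Seconds from stream start, or `NULL`.
#' @param cur_num Piglets visible in the final frame.
#' @param detected_num Running maximum of `cur_num` over the stream.
#' @return An object of class `"farrowing_state"`.
#' @export
farrowing_state <- function(alarm = 0L, t_start = NULL, t_end = NULL,
                            cur_num = 0L, detected_num = 0L) {
  alarm <- as.integer(alarm)
  stopifnot(alarm %in% c(0L, 1L))
  if (alarm == 1L && is.null(t_start)) stop("alarm set without t_start")
  if (alarm == 0L && !is.null(t_start)) stop("t_start set without alarm")
  stopifnot(cur_num >= 0, detected_num >= cur_num)
  duration <- if (!is.null(t_start) && !is.null(t_end)) t_end - t_start else NULL
  structure(
    list(alarm = alarm, t_start = t_start, t_end = t_end,
         duration_d = duration, cur_num = as.integer(cur_num),
         detected_num = as.integer(detected_num)),
    class = "farrowing_state"
  )
}

#' @export
print.farrowing_state <- function(x, ...) {
  cat("<farrowing_state>\n")
  fmt <- function(v) if (is.null(v)) "Null" else sprintf("%.1f s", v)
  cat("  alarm:       ", x$alarm, "\n", sep = "")
  cat("  t_start:     ", fmt(x$t_start), "\n", sep = "")
  cat("  t_end:       ", fmt(x$t_end), "\n", sep = "")
  cat("  duration_d:  ", fmt(x$duration_d), "\n", sep = "")
  cat("  cur_num:     ", x$cur_num, "\n", sep = "")
  cat("  detected_num:", x$detected_num, "\n", sep = "")
  invisible(x)
}
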
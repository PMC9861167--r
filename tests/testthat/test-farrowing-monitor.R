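test_that("no piglet detections means no alarm", {
  ev <- make_event(c(10, 20, 30), rep("standing", 3))
  res <- process_stream(ev, 1, monitor_config())
  expect_equal(res$state$alarm, 0L)
  expect_null(res$state$t_start)
  expect_equal(nrow(res$alarms), 0)
})

test_that("the alarm fires on k consecutive piglet-positive frames", {
  ev <- piglet_frames_stream(c(3, 4, 5))
  res <- process_stream(ev, 1, monitor_config(k_consecutive = 3), span = 20)
  expect_equal(res$state$alarm, 1L)
  expect_equal(res$state$t_start, 3)

  # isolated positives never confirm
  iso <- piglet_frames_stream(c(1, 4, 7))
  res <- process_stream(iso, 1, monitor_config(k_consecutive = 3), span = 20)
  expect_equal(res$state$alarm, 0L)

  # single-detection mode fires immediately on the first positive
  res <- process_stream(iso, 1, monitor_config(k_consecutive = 1), span = 20)
  expect_equal(res$state$alarm, 1L)
  expect_equal(res$state$t_start, 1)
})

test_that("t_start lies within the confirming run", {
  set.seed(404)
  for (i in 1:10) {
    frames <- sort(sample(0:200, 60))
    ev <- piglet_frames_stream(frames, frame_interval = 2)
    k <- sample(1:4, 1)
    res <- process_stream(ev, 2, monitor_config(k_consecutive = k), span = 402)
    if (res$state$alarm == 1L) {
      first_pos <- min(frames) * 2
      expect_gte(res$state$t_start, first_pos)
      # the confirming run's k-th frame is t_start + (k-1) frames
      run_frames <- res$state$t_start / 2 + 0:(k - 1)
      expect_true(all(run_frames %in% frames))
    }
  }
})

test_that("detected_num is the running maximum of cur_num", {
  # cur per frame [1,2,1] -> detected [1,2,2]
  ev <- piglet_frames_stream(c(0, 1, 1, 2))
  res <- process_stream(ev, 1, monitor_config())
  expect_equal(res$frames$cur_num, c(1L, 2L, 1L))
  expect_equal(res$frames$detected_num, c(1L, 2L, 2L))
  expect_equal(res$state$detected_num, max(res$frames$cur_num))
})

test_that("t_end finalises only after the quiet period", {
  ev <- piglet_frames_stream(c(0, 1, 2, 3, 10, 10)) # two boxes in frame 10
  # last max-raise at frame 10; stream ends at frame 20: quiet 10 s < 1 h
  res <- process_stream(ev, 1, monitor_config(), span = 21)
  expect_null(res$state$t_end)
  expect_null(res$state$duration_d)
  # extend the stream past the quiet period
  res <- process_stream(ev, 1, monitor_config(end_quiet_hours = 1),
                        span = 3611)
  expect_equal(res$state$t_end, 10)
  expect_equal(res$state$duration_d, 10)
})

test_that("the alarm message is dispatched exactly once, idempotently", {
  ev <- piglet_frames_stream(c(3, 4, 5, 9, 10, 11))
  sink <- mock_sink()
  res <- process_stream(ev, 1, monitor_config(), sinks = list(sink), span = 20)
  msgs <- sink_messages(sink)
  expect_equal(nrow(msgs), 1)
  expect_equal(msgs$message, "Delivery Begin! Start time: PT3S")
  expect_equal(msgs$t, 3)

  # reprocessing the same stream emits the same single message again,
  # with identical content (no accumulated state in the monitor)
  res2 <- process_stream(ev, 1, monitor_config(), sinks = list(sink), span = 20)
  expect_identical(res$state, res2$state)
  expect_equal(nrow(sink_messages(sink)), 2)

  # wall-clock anchoring produces an ISO-8601 timestamp
  t0 <- as.POSIXct("2023-01-05 08:00:00", tz = "UTC")
  res3 <- process_stream(ev, 1, monitor_config(), span = 20, stream_start = t0)
  expect_equal(res3$alarms$message,
               "Delivery Begin! Start time: 2023-01-05T08:00:03Z")
})

test_that("false alarms are counted per pre-onset episode", {
  s <- simulate_sow(horizon = c(-1, 1), seed = 405)

  # noiseless stream: no false alarms for any k
  clean <- apply_detector_noise(s, noise_profile(), 10, seed = 1)
  expect_equal(count_false_alarms(clean, s, 10, 1), 0L)
  expect_equal(count_false_alarms(clean, s, 10, 3), 0L)

  # three isolated pre-onset false positives: 3 at k=1, 0 at k=3
  iso <- piglet_frames_stream(c(5, 50, 100), frame_interval = 10)
  expect_equal(count_false_alarms(iso, s, 10, 1), 3L)
  expect_equal(count_false_alarms(iso, s, 10, 3), 0L)

  # a pre-onset run of length 3 is one episode, not three
  run3 <- piglet_frames_stream(c(5, 6, 7), frame_interval = 10)
  expect_equal(count_false_alarms(run3, s, 10, 1), 1L)
  expect_equal(count_false_alarms(run3, s, 10, 3), 1L)
})

test_that("a longer debounce never increases the false-alarm count", {
  set.seed(406)
  s <- simulate_sow(horizon = c(-4, 1), seed = 406)
  for (i in 1:8) {
    ev <- apply_detector_noise(
      s, noise_profile(posture_miss_rate = 1, piglet_false_rate = 0.05),
      frame_interval = 10, seed = i)
    counts <- vapply(1:4, function(k) count_false_alarms(ev, s, 10, k), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the count report aligns detections with ground truth", {
  s <- simulate_sow(horizon = c(-1, 2), seed = 407)
  clean <- apply_detector_noise(s, noise_profile(), 10, seed = 2)
  rep <- piglet_count_report(clean, s, 10)
  expect_equal(rep$cur_num, rep$true_num)   # perfect detection
  expect_equal(rep$detected_num, cummax(rep$cur_num))
  acc <- ca_da(rep)
  expect_equal(acc$ca, 1)
  expect_equal(acc$da, 1)

  # one false piglet box before onset: cur 1 while true 0 at that frame
  pre <- piglet_frames_stream(5, frame_interval = 10)
  rep2 <- piglet_count_report(pre, s, 10)
  expect_equal(rep2$cur_num[6], 1L)
  expect_equal(rep2$true_num[6], 0L)
})
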
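test_that("count_transitions counts label changes, bridging gaps", {
  expect_equal(count_transitions(make_timeline(rep("LL", 6)), 0, 6), 0L)
  tl <- make_timeline(c("LL", "LL", "ST", "SI", "SI", "LL"))
  expect_equal(count_transitions(tl, 0, 6), 3L)
  # missing samples are skipped; the comparison bridges the gap
  expect_equal(count_transitions(make_timeline(c("LL", NA, "ST")), 0, 3), 1L)
  expect_equal(count_transitions(make_timeline(c("LL", NA, "LL")), 0, 3), 0L)
  # window is half-open [from, to)
  expect_equal(count_transitions(tl, 0, 3), 1L)
  expect_error(count_transitions(tl, 5, 5))
})

test_that("transition_frequency is n / T in hours", {
  expect_equal(transition_frequency(0, 1), 0)
  expect_equal(transition_frequency(35, 2), 17.5)
  expect_equal(transition_frequency(12, 0.5), 24)
  expect_error(transition_frequency(3, 0), "positive")
  expect_error(transition_frequency(3, -1), "positive")
})

test_that("frequency_series handles flat and short timelines", {
  tl <- make_timeline(rep("ST", 2 * 3600), interval = 2) # 4 h constant
  fs <- frequency_series(tl, warning_config())
  expect_true(all(fs$f == 0))
  expect_equal(fs$t[1], 3600)

  short <- make_timeline(rep("ST", 10), interval = 1)
  expect_message(out <- frequency_series(short), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("k changes inside one window give f = k there", {
  # 2 h timeline at 1-min samples, 5 changes packed into minutes 70..75
  lab <- rep("LL", 121)
  lab[71:75] <- c("ST", "SI", "LL", "ST", "SI")
  tl <- make_timeline(lab, interval = 60)
  cfg <- warning_config(window_hours = 1, step_hours = 1)
  fs <- frequency_series(tl, cfg)
  expect_equal(fs$f[fs$t == 2 * 3600], 6) # 5 in + 1 out of the burst
  expect_equal(count_transitions(tl, 3600, 2 * 3600), 6L)
})

test_that("streaming series equals per-window recount on random timelines", {
  set.seed(402)
  for (i in 1:25) {
    tl <- random_timeline(n = sample(200:600, 1),
                          interval = runif(1, 30, 120))
    cfg <- warning_config(window_hours = runif(1, 0.5, 2),
                          step_hours = runif(1, 0.1, 0.5))
    fs <- frequency_series(tl, cfg)
    bf <- brute_force_series(tl, cfg)
    expect_equal(fs$t, bf$t)
    expect_equal(fs$f, bf$f) # exact integer agreement of counts
  }
})

test_that("a sow between the thresholds never warns", {
  series <- make_series(rep(12, 200)) # 50 h at 12/h
  expect_equal(nrow(evaluate_warnings(series)), 0)
})

test_that("a sustained exceedance warns with onset + persistence timing", {
  t <- seq(3600, 30 * 3600, by = 900)
  f <- ifelse(t < 10 * 3600, 12, 20)
  ev <- evaluate_warnings(tibble::tibble(t = t, f = f))
  up <- ev[ev$kind == "upper", ]
  expect_equal(nrow(up), 1)
  expect_equal(up$condition_onset, 10 * 3600)
  expect_equal(up$emitted_at, 15 * 3600)
})

test_that("an exceedance shorter than the persistence does not warn", {
  t <- seq(3600, 40 * 3600, by = 900)
  f <- ifelse(t >= 10 * 3600 & t <= 13 * 3600, 20, 12) # 3 h only
  expect_equal(nrow(evaluate_warnings(tibble::tibble(t = t, f = f))), 0)
})

test_that("short dips are tolerated, long interruptions reset the clock", {
  t <- seq(3600, 40 * 3600, by = 900)
  f <- ifelse(t >= 10 * 3600, 20, 12)
  dip <- function(f, from_h, to_h) ifelse(t >= from_h * 3600 & t < to_h * 3600, 12, f)

  one_point <- f; one_point[which(t == 12 * 3600)] <- 12
  ev <- evaluate_warnings(tibble::tibble(t = t, f = one_point))
  expect_equal(ev$condition_onset[1], 10 * 3600)
  expect_equal(ev$emitted_at[1], 15 * 3600)

  # a dip longer than grace_hours restarts the run
  long_dip <- dip(f, 12, 15.5) # 3.5 h > default 3 h grace
  ev <- evaluate_warnings(tibble::tibble(t = t, f = long_dip))
  expect_equal(ev$condition_onset[ev$kind == "upper"], 15.5 * 3600)
})

test_that("the lower warning is armed only after the upper one", {
  # frequency falls below 10 but never exceeded 17.5: nothing fires
  t <- seq(3600, 40 * 3600, by = 900)
  expect_equal(nrow(evaluate_warnings(tibble::tibble(t = t, f = rep(1, length(t))))), 0)

  # full pattern: high then quiet -> upper followed by lower
  f <- ifelse(t < 20 * 3600, 20, 2)
  ev <- evaluate_warnings(tibble::tibble(t = t, f = f))
  expect_equal(ev$kind, c("upper", "lower"))
  expect_true(ev$emitted_at[2] > ev$emitted_at[1])
  expect_equal(ev$condition_onset[2], 20 * 3600)
})

test_that("increasing persistence never adds events", {
  set.seed(403)
  for (i in 1:10) {
    # alternate between quiet (~9/h) and busy (~22/h) sampling rates
    tl <- random_timeline(n = 400, interval = c(300, 120)[i %% 2 + 1],
                          p_missing = 0.05)
    base <- warning_config()
    longer <- warning_config(persistence_hours = 8)
    n_base <- nrow(evaluate_warnings(frequency_series(tl, base), base))
    n_long <- nrow(evaluate_warnings(frequency_series(tl, longer), longer))
    expect_lte(n_long, n_base)
  }
})

test_that("warning_error measures deviation from the target lead", {
  onset <- 100 * 3600
  expect_equal(warning_error(95 * 3600, onset)$error_hours, 0)
  e <- warning_error(93.5 * 3600, onset)
  expect_equal(e$lead_hours, 6.5)
  expect_equal(e$error_hours, 1.5)
  expect_false(e$late)
  late <- warning_error(101 * 3600, onset)
  expect_equal(late$lead_hours, -1)
  expect_equal(late$error_hours, 6)
  expect_true(late$late)
})
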
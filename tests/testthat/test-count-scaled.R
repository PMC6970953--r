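test_that("minute aggregation sums constituent epochs and drops partials", {
  expect_equal(aggregate_to_minutes(mk_series(c(10, 20, 30, 40)))$value, 100)
  expect_equal(aggregate_to_minutes(mk_series(rep(0, 8)))$value, c(0, 0))
  # 7 epochs of 15 s: the partial second minute is dropped
  expect_equal(aggregate_to_minutes(mk_series(c(1, 1, 1, 1, 2, 2, 2)))$value, 4)
  # 60-s input passes through
  m <- aggregate_to_minutes(mk_series(c(5, 6), epoch = 60))
  expect_equal(m$value, c(5, 6))
})

test_that("count scaling normalises to the mean non-zero value", {
  s <- scale_counts(tibble::tibble(time = T0 + c(0, 60, 120),
                                   value = c(7, 7, 7)))
  expect_equal(s$scaled, c(1, 1, 1))
  expect_equal(scale_factor(s), 7)

  s <- scale_counts(tibble::tibble(time = T0 + c(0, 60, 120),
                                   value = c(0, 2, 4)))
  expect_equal(scale_factor(s), 3)  # mean of {2, 4}
  expect_equal(s$scaled, c(0, 2 / 3, 4 / 3))
  # mean over non-zero scaled values is exactly 1
  expect_equal(mean(s$scaled[s$scaled > 0]), 1, tolerance = 1e-12)

  z <- scale_counts(tibble::tibble(time = T0 + c(0, 60), value = c(0, 0)))
  expect_equal(scale_factor(z), 1)
  expect_equal(z$scaled, c(0, 0))
})

test_that("weighted activity follows the window arithmetic, edges renormalised", {
  uni <- cs_config(weights = rep(1 / 7, 7))
  expect_equal(weighted_activity(rep(0, 20), uni), rep(0, 20))
  # constant scaled activity 1 gives the weight total everywhere, edges too
  expect_equal(weighted_activity(rep(1, 20), uni), rep(1, 20))
  # window values [2,0,0,0,0,0,0] over t-4..t+2 under uniform weights
  expect_equal(weighted_activity(c(2, 0, 0, 0, 0, 0, 0), uni)[5], 2 / 7)
})

test_that("classification is a strict threshold on weighted activity", {
  zeros <- scale_counts(tibble::tibble(time = T0 + 60 * (0:19),
                                       value = rep(0, 20)))
  expect_true(all(classify_sleep_wake(zeros)$label == "sleep"))
  # constant activity scales to exactly 1: never strictly below threshold
  const <- scale_counts(tibble::tibble(time = T0 + 60 * (0:19),
                                       value = rep(250, 20)))
  for (cfg in list(cs_config(), cs_config(weights = rep(1 / 7, 7)))) {
    expect_true(all(classify_sleep_wake(const, cfg)$label == "wake"))
  }
})

test_that("event detection matches the run-length definitions", {
  lab <- mk_labels(lab_seq(5, "wake", 15, "sleep", 5, "wake", 20, "sleep"))
  ev <- detect_events(lab)
  expect_equal(ev$minute[ev$type == "onset"], c(5L, 25L))
  expect_equal(ev$minute[ev$type == "wake"], 19L)
  # onset timestamped at minute start; wake at minute end
  expect_equal(ev$time[ev$type == "onset"][1], T0 + 5 * 60)
  expect_equal(ev$time[ev$type == "wake"][1], T0 + 20 * 60)

  # only 4 preceding wake minutes: no onset event
  ev2 <- detect_events(mk_labels(lab_seq(4, "wake", 15, "sleep")))
  expect_equal(nrow(ev2), 0)
  # an uninterrupted all-sleep night has no events at all
  expect_equal(nrow(detect_events(mk_labels(rep("sleep", 120)))), 0)
})

test_that("event detection agrees with the brute-force oracle", {
  withr::local_seed(101)
  for (rep_i in 1:40) {
    n <- sample(30:300, 1)
    lab <- sample(c("sleep", "wake"), n, replace = TRUE,
                  prob = c(0.8, 0.2))
    ev <- detect_events(mk_labels(lab))
    oracle <- brute_events(lab)
    expect_equal(ev$minute[ev$type == "onset"], oracle$onset)
    expect_equal(ev$minute[ev$type == "wake"], oracle$wake)
  }
})

test_that("flag-anchored search: forward first, then backward, then the flag", {
  flag <- as.POSIXct("2024-03-01 19:30:00", tz = "UTC")
  ev_at <- function(t) tibble::tibble(type = "onset", minute = 0L, time = t)
  h <- function(x) as.POSIXct(paste("2024-03-01", x), tz = "UTC")

  expect_equal(locate_sleep_onset(ev_at(h("20:10:00")), flag), h("20:10:00"))
  expect_equal(locate_sleep_onset(ev_at(h("18:00:00")), flag), h("18:00:00"))
  expect_equal(locate_sleep_onset(ev_at(h("10:00:00"))[0, ], flag), flag)
  # several forward events: the first wins; several backward: the last
  both <- dplyr::bind_rows(ev_at(h("20:10:00")), ev_at(h("21:00:00")))
  expect_equal(locate_sleep_onset(both, flag), h("20:10:00"))
  back2 <- dplyr::bind_rows(ev_at(h("17:45:00")), ev_at(h("19:00:00")))
  expect_equal(locate_sleep_onset(back2, flag), h("19:00:00"))
  # an event exactly at the flag is a forward match, not a backward one
  expect_equal(locate_sleep_onset(ev_at(flag), flag), flag)

  wk <- tibble::tibble(type = "wake", minute = 0L, time = h("06:40:00") + 86400)
  wflag <- h("06:00:00") + 86400
  expect_equal(locate_sleep_offset(wk, wflag), h("06:40:00") + 86400)
  wk$time <- h("05:00:00") + 86400
  expect_equal(locate_sleep_offset(wk, wflag), h("05:00:00") + 86400)
  expect_equal(locate_sleep_offset(wk[0, ], wflag), wflag)
})

test_that("a clean synthetic night is scored onset 20:00, offset 06:30", {
  start <- as.POSIXct("2024-03-01 19:00:00", tz = "UTC")
  times <- seq(start, start + 13 * 3600 - 15, by = 15)
  zero_span <- times >= as.POSIXct("2024-03-01 20:00:00", tz = "UTC") &
    times < as.POSIXct("2024-03-02 06:30:00", tz = "UTC")
  s <- epoch_series(times, ifelse(zero_span, 0, 100))
  n <- score_night(s)
  expect_lte(abs(as.numeric(n$onset -
    as.POSIXct("2024-03-01 20:00:00", tz = "UTC"), units = "mins")), 1)
  expect_lte(abs(as.numeric(n$offset -
    as.POSIXct("2024-03-02 06:30:00", tz = "UTC"), units = "mins")), 1)
  # minute labels broadcast to 4 epochs each
  expect_equal(nrow(n$labels), 4 * nrow(n$minute_labels))
  expect_equal(epoch_length_s(n$labels), 15)

  # all-zero recording: no events anywhere, both flags used
  z <- epoch_series(times, rep(0, length(times)))
  nz <- score_night(z)
  expect_equal(nz$onset, as.POSIXct("2024-03-01 19:30:00", tz = "UTC"))
  expect_equal(nz$offset, as.POSIXct("2024-03-02 06:00:00", tz = "UTC"))
  expect_true(all(nz$labels$label == "sleep"))

  # a recording that misses the wake-time flag is rejected
  expect_error(score_night(epoch_series(times[times < as.POSIXct(
    "2024-03-02 05:00:00", tz = "UTC")], rep(0, sum(times < as.POSIXct(
      "2024-03-02 05:00:00", tz = "UTC"))))),
    class = "actiscore_coverage_error")
})

test_that("classification is invariant to rescaling all raw counts", {
  withr::local_seed(7)
  start <- as.POSIXct("2024-03-01 19:00:00", tz = "UTC")
  times <- seq(start, start + 13 * 3600 - 15, by = 15)
  counts <- rnbinom(length(times), size = 2,
                    mu = ifelse(seq_along(times) %% 97 < 60, 5, 180))
  a <- score_night(epoch_series(times, counts))
  b <- score_night(epoch_series(times, counts * 7.3))
  expect_equal(a$labels$label, b$labels$label)
  expect_equal(a$onset, b$onset)
  expect_equal(a$offset, b$offset)
  expect_equal(scale_factor(scale_counts(aggregate_to_minutes(
    epoch_series(times, counts * 7.3)))), 7.3 * a$scale_factor)
})

test_that("raising the threshold never shrinks the sleep minute set", {
  withr::local_seed(11)
  scaled <- tibble::tibble(time = T0 + 60 * (0:199),
                           value = rexp(200, 1 / 50))
  scaled <- scale_counts(scaled)
  prev <- rep(FALSE, 200)
  for (thr in c(0.25, 0.5, 1, 2, 4)) {
    lab <- classify_sleep_wake(scaled, cs_config(threshold = thr))
    cur <- lab$label == "sleep"
    expect_true(all(cur[prev]))  # previously-sleep minutes stay sleep
    prev <- cur
  }
})

test_that("scoring is deterministic for identical input and config", {
  p <- scenario_params("default", n_subjects = 1, seed = 33)
  co <- simulate_cohort(p)
  s <- co$counts$series[[1]]
  n1 <- score_night(s)
  n2 <- score_night(s)
  expect_identical(n1$labels$label, n2$labels$label)
  expect_identical(n1$onset, n2$onset)
  expect_identical(n1$events, n2$events)
})
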
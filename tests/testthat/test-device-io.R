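test_that("plain count CSV parses, and malformed input is rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,count", "00:00:00,0", "00:00:15,2", "00:00:30,4"), f)
  s <- read_counts_csv(f)
  expect_equal(nrow(s), 3)
  expect_equal(epoch_length_s(s), 15)
  expect_equal(s$count, c(0, 2, 4))

  # a deleted row leaves a timestamp gap: rejected, not imputed
  writeLines(c("timestamp,count", "00:00:00,0", "00:00:15,2",
               "00:00:45,6"), f)
  expect_error(read_counts_csv(f), class = "actiscore_gap_error")

  writeLines(c("timestamp,wrong", "00:00:00,0"), f)
  expect_error(read_counts_csv(f), class = "actiscore_format_error")

  writeLines(c("timestamp,count", "00:00:00,-5", "00:00:15,1"), f)
  expect_error(read_counts_csv(f), class = "actiscore_validation_error")
})

test_that("ActiLife-style export reads axis-1 counts past the banner", {
  f <- withr::local_tempfile(fileext = ".csv")
  banner <- c(
    "ActiLife-style export v0",
    "Serial Number: XXX123",
    "Start Time 21:30:00",
    "Start Date 3/1/2024",
    "Epoch Period (hh:mm:ss) 00:00:15",
    "Down Sampled: No",
    "Filter: Normal",
    "Voltage: 4.1",
    "Mode: 61",
    "--------------------------------"
  )
  writeLines(c(banner, "Axis1,Axis2,Axis3",
               "12,1,2", "0,3,4", "88,5,6", "7,0,0"), f)
  s <- read_counts_csv(f, dialect = "actilife", subject_id = "K1",
                       device = "actigraph", site = "wrist")
  expect_equal(s$count, c(12, 0, 88, 7))  # axis-1 column only
  expect_equal(epoch_length_s(s), 15)
  expect_equal(s$time[1], as.POSIXct("2024-03-01 21:30:00", tz = "UTC"))
  expect_equal(s$site[1], "wrist")

  # write (plain) -> read round trip preserves the series field-for-field
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_counts_csv(s, f2)
  s2 <- read_counts_csv(f2, subject_id = "K1", device = "actigraph",
                        site = "wrist")
  expect_equal(s2$count, s$count)
  expect_equal(s2$time, s$time)
})

test_that("hypnogram CSV round-trips with lights markers and rejects bad stages", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("epoch_start,stage", "2024-03-01 22:00:00,W",
               "2024-03-01 22:00:30,N1"), f)
  h <- read_hypnogram_csv(f)
  expect_equal(nrow(h), 2)
  expect_equal(h$stage, c("W", "N1"))

  writeLines(c("epoch_start,stage", "2024-03-01 22:00:00,W",
               "2024-03-01 22:00:30,N4"), f)
  expect_error(read_hypnogram_csv(f), class = "actiscore_validation_error")

  # a simulated 8-h hypnogram (960 epochs) round-trips exactly
  p <- scenario_params("default", n_subjects = 1, seed = 5,
                       record_start = "22:00", record_end = "06:00",
                       bedtime_range = c("22:10", "22:30"),
                       bedtime_mean = "22:20",
                       offset_range = c("05:15", "05:40"),
                       offset_mean = "05:30", waso_latest_start = "05:00")
  co <- simulate_cohort(p)
  h0 <- co$hypnograms[[1]]
  expect_equal(nrow(h0), 960)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram_csv(h0, f3)
  h1 <- read_hypnogram_csv(f3)
  expect_equal(h1$stage, h0$stage)
  expect_equal(h1$time, h0$time)
  expect_equal(attr(h1, "lights_out"), attr(h0, "lights_out"))
})

test_that("outcomes CSV round-trips and degenerates to a header-only file", {
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = "S01", device = "actigraph", site = "hip",
                   algorithm = "count-scaled"),
    compute_outcomes(mk_labels(rep("sleep", 600)), T0, T0 + 600 * 60)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_outcomes_csv(out, f)
  back <- read_outcomes_csv(f)
  expect_equal(back$spt_min, out$spt_min)
  expect_equal(back$onset, out$onset)
  expect_equal(back$efficiency_pct, out$efficiency_pct)

  write_outcomes_csv(out[0, ], f)
  empty <- read_outcomes_csv(f)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("subject_id", "efficiency_pct") %in% names(empty)))
})

test_that("validation report JSON round-trips numerics at full precision", {
  report <- list(
    block = list(
      pabak = 2 * 0.88224719 - 1,
      accuracy = 88.224719101123595,
      agreement = interpret_kappa(2 * 0.88224719 - 1)
    )
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_validation_report(report, f)
  back <- read_validation_report(f)
  expect_identical(back$block$pabak, report$block$pabak)
  expect_identical(back$block$accuracy, report$block$accuracy)
  expect_equal(back$block$agreement, "substantial agreement")
})
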
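test_that("hypnogram collapse maps W to wake and finds PSG onset/offset", {
  h <- hypnogram(T0 + 30 * (0:4), c("W", "N1", "N2", "R", "W"))
  p <- collapse_hypnogram(h)
  expect_equal(p$labels$label, c("wake", "sleep", "sleep", "sleep", "wake"))
  expect_equal(p$onset, T0 + 30)        # first sleep epoch
  expect_equal(p$offset, T0 + 4 * 30)   # end of the last sleep epoch

  expect_error(collapse_hypnogram(hypnogram(T0 + 30 * (0:3), rep("W", 4))),
               class = "actiscore_no_sleep_error")

  all_n2 <- collapse_hypnogram(hypnogram(T0 + 30 * (0:3), rep("N2", 4)))
  expect_equal(all_n2$onset, T0)
  expect_equal(all_n2$offset, T0 + 4 * 30)

  # lights-out marker moves PSG onset past earlier sleep
  h2 <- hypnogram(T0 + 30 * (0:5), c("N1", "W", "N2", "N2", "N2", "W"))
  p2 <- collapse_hypnogram(h2, lights_out = T0 + 60)
  expect_equal(p2$onset, T0 + 60)
})

test_that("15-s alignment duplicates PSG epochs and trims to the overlap", {
  psg <- actiscore:::new_sleep_wake("S01", T0 + 30 * (0:1),
                                    c("sleep", "wake"), 30, "psg")
  act <- actiscore:::new_sleep_wake("S01", T0 + 15 * (0:3),
                                    c("sleep", "sleep", "wake", "wake"),
                                    15, "count-scaled")
  pairs <- align_to_15s(psg, act)
  expect_equal(pairs$psg, c("sleep", "sleep", "wake", "wake"))
  expect_equal(pairs$act, c("sleep", "sleep", "wake", "wake"))

  # actigraphy starting 30 s late drops the first PSG epoch
  act2 <- actiscore:::new_sleep_wake("S01", T0 + 30 + 15 * (0:3),
                                     rep("sleep", 4), 15, "count-scaled")
  psg2 <- actiscore:::new_sleep_wake("S01", T0 + 30 * (0:3),
                                     c("wake", "sleep", "sleep", "sleep"),
                                     30, "psg")
  pairs2 <- align_to_15s(psg2, act2)
  expect_equal(min(pairs2$time), T0 + 30)
  expect_equal(nrow(pairs2), 4)

  act3 <- actiscore:::new_sleep_wake("S01", T0 + 7 + 15 * (0:9),
                                     rep("sleep", 10), 15, "count-scaled")
  expect_error(align_to_15s(psg, act3),
               class = "actiscore_alignment_error")
  act4 <- actiscore:::new_sleep_wake("S01", T0 + 7200 + 15 * (0:9),
                                     rep("sleep", 10), 15, "count-scaled")
  expect_error(align_to_15s(psg, act4), class = "actiscore_overlap_error")
})

test_that("confusion cells count the four agreement categories and conserve n", {
  pairs <- tibble::tibble(psg = c("sleep", "sleep", "wake", "wake"),
                          act = c("sleep", "wake", "wake", "sleep"))
  ct <- confusion_table(pairs)
  expect_equal(unlist(ct[, 1:4]),
               c(true_sleep = 1, false_sleep = 1, true_wake = 1,
                 false_wake = 1))
  expect_equal(ct$total, nrow(pairs))

  withr::local_seed(5)
  rnd <- tibble::tibble(
    psg = sample(c("sleep", "wake"), 500, replace = TRUE),
    act = sample(c("sleep", "wake"), 500, replace = TRUE))
  expect_equal(confusion_table(rnd)$total, 500)

  # swapping the streams swaps false sleep with false wake
  ct_sw <- confusion_table(dplyr::rename(rnd, psg = "act", act = "psg"))
  ct0 <- confusion_table(rnd)
  expect_equal(ct_sw$false_sleep, ct0$false_wake)
  expect_equal(ct_sw$true_sleep, ct0$true_sleep)
})

test_that("agreement statistics and PABAK follow their formulas", {
  ct <- confusion_table(tibble::tibble(
    psg = c("sleep", "sleep", "wake", "wake"),
    act = c("sleep", "wake", "wake", "sleep")))
  st <- agreement_stats(ct)
  expect_equal(st$sensitivity_pct, 50)
  expect_equal(st$specificity_pct, 50)
  expect_equal(st$accuracy_pct, 50)
  expect_equal(st$pabak, 0)

  perfect <- actiscore:::confusion_from_cells(10, 0, 5, 0)
  stp <- agreement_stats(perfect)
  expect_equal(c(stp$sensitivity_pct, stp$specificity_pct, stp$accuracy_pct),
               c(100, 100, 100))
  expect_equal(stp$pabak, 1)

  # no PSG wake epochs: specificity is undefined, never zero
  no_wake <- actiscore:::confusion_from_cells(10, 0, 0, 2)
  expect_true(is.na(agreement_stats(no_wake)$specificity_pct))

  # PABAK = 2 * accuracy - 1, for every table
  withr::local_seed(9)
  for (i in 1:25) {
    cells <- as.list(rmultinom(1, 2000, c(0.7, 0.05, 0.15, 0.1))[, 1])
    st_i <- agreement_stats(do.call(actiscore:::confusion_from_cells, cells))
    expect_equal(st_i$pabak, 2 * st_i$accuracy_pct / 100 - 1,
                 tolerance = 1e-9)
  }
})

test_that("PABAK from an observed agreement proportion, with its CI", {
  expect_equal(pabak(0.882)$pabak, 0.764)
  expect_equal(pabak(1)$pabak, 1)
  expect_equal(pabak(0.5)$pabak, 0)
  p <- pabak(0.9, n = 1000)
  se <- sqrt(0.9 * 0.1 / 1000)
  expect_equal(p$ci_low, 2 * (0.9 - qnorm(0.975) * se) - 1)
  expect_equal(p$ci_high, 2 * (0.9 + qnorm(0.975) * se) - 1)
  expect_equal(pabak(1, n = 50)$ci_high, 1)  # clipped at 1
  expect_error(pabak(1.2), class = "actiscore_validation_error")
})

test_that("kappa bands match the verbal scale, upper bounds inclusive", {
  expect_equal(interpret_kappa(c(0.76, 0.81, 0, -0.2, 0.2, 0.21, 0.405, 0.61)),
               c("substantial agreement", "almost perfect agreement",
                 "poor agreement", "poor agreement", "slight agreement",
                 "fair agreement", "moderate agreement",
                 "substantial agreement"))
  expect_error(interpret_kappa(1.5), class = "actiscore_validation_error")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(same[, c("mean_diff", "sd_diff", "loa_low", "loa_high")]),
               c(mean_diff = 0, sd_diff = 0, loa_low = 0, loa_high = 0))

  ba <- bland_altman(c(-10, 0, 10), c(0, 0, 0))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 10)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-19.6, 19.6))

  # translation: adding c to the device shifts bias and both limits by c
  x <- c(540, 600, 585, 570)
  y <- c(555, 580, 590, 560)
  b0 <- bland_altman(x, y)
  b1 <- bland_altman(x + 12.5, y)
  expect_equal(b1$mean_diff, b0$mean_diff + 12.5)
  expect_equal(b1$loa_low, b0$loa_low + 12.5)
  expect_equal(b1$loa_high, b0$loa_high + 12.5)

  expect_error(bland_altman(1, 1),
               class = "actiscore_insufficient_data_error")
})

test_that("paired tests reproduce closed-form t and handle degenerate input", {
  d <- c(1, 2, 3, 4, 5)
  res <- paired_tests(d, rep(0, 5), "paired_t")
  expect_equal(res$statistic, 3 / (sd(d) / sqrt(5)), tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-res$statistic, df = 4), tolerance = 1e-9)

  z <- paired_tests(rep(2, 4), rep(2, 4), "paired_t")
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)

  w0 <- paired_tests(rep(3, 4), rep(3, 4), "wilcoxon")
  expect_equal(w0$p_value, 1)
  expect_equal(w0$note, "all differences zero")

  # symmetric differences: no evidence of a shift
  ws <- paired_tests(c(-2, -1, 1, 2), rep(0, 4), "wilcoxon")
  expect_gt(ws$p_value, 0.8)
})

test_that("per-subject pooling and bootstrap are exact in degenerate cases", {
  cells <- tibble::tibble(true_sleep = 80, false_sleep = 5, true_wake = 10,
                          false_wake = 5)
  one <- per_subject_summary(cells, n_boot = 200, seed = 4)
  expect_equal(one$pooled$accuracy_pct, 90)
  acc <- one$subject_level[one$subject_level$metric == "accuracy_pct", ]
  expect_equal(acc$mean, 90)
  expect_equal(c(acc$ci_low, acc$ci_high), c(90, 90))  # point interval

  two <- per_subject_summary(dplyr::bind_rows(cells, cells),
                             n_boot = 200, seed = 4)
  expect_equal(two$pooled$accuracy_pct, 90)  # identical subjects pool to one

  b1 <- per_subject_summary(dplyr::bind_rows(cells, cells * 3L), seed = 99)
  b2 <- per_subject_summary(dplyr::bind_rows(cells, cells * 3L), seed = 99)
  expect_identical(b1$subject_level, b2$subject_level)
})

test_that("PSG 60-s collapse lets wake win within each minute", {
  lab <- actiscore:::new_sleep_wake(
    "S01", T0 + 30 * (0:5),
    c("sleep", "wake", "sleep", "sleep", "wake", "wake"), 30, "psg")
  m <- collapse_psg_to_60s(lab)
  expect_equal(m$label, c("wake", "sleep", "wake"))
  expect_equal(epoch_length_s(m), 60)
})
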
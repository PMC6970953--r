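#' Collapse a hypnogram to sleep/wake with PSG onset and offset
#'
#' Stage `W` becomes wake; `N1`, `N2`, `N3` and `R` become sleep. PSG sleep
#' onset is the first sleep epoch at or after lights out (or from the start of
#' the recording when no lights-out marker is present) and sleep offset the
#' end of the last sleep epoch.
#'
#' @param h A [hypnogram()].
#' @param lights_out Optional POSIXct lights-out marker; defaults to the
#'   marker stored in `h`, if any.
#' @return A list of class `psg_night`: `labels` (30-s `sleep_wake` tibble),
#'   `onset`, `offset`.
#' @export
collapse_hypnogram <- function(h, lights_out = NULL) {
  lights_out <- lights_out %||% attr(h, "lights_out")
  labels <- new_sleep_wake(
    subject_id = h$subject_id[1], time = h$time,
    label = ifelse(h$stage == "W", "wake", "sleep"),
    epoch_length_s = 30, algorithm = "psg", params = list()
  )
  sleep_idx <- which(labels$label == "sleep")
  if (!is.null(lights_out)) {
    sleep_idx <- sleep_idx[labels$time[sleep_idx] >= lights_out]
  }
  if (length(sleep_idx) == 0) {
    abort("hypnogram contains no sleep epochs",
          class = "actiscore_no_sleep_error")
  }
  structure(list(
    labels = labels,
    onset = labels$time[sleep_idx[1]],
    offset = labels$time[max(which(labels$label == "sleep"))] + 30
  ), class = "psg_night")
}

#' Align PSG and actigraphy labels on a 15-s grid
#'
#' Splits each PSG 30-s label into two 15-s labels, trims both streams to
#' their overlapping span and pairs them epoch-by-epoch. Both streams must
#' start on a shared 15-s grid and overlap by at least one minute.
#'
#' @param psg A `psg_night` from [collapse_hypnogram()] or a 30-s
#'   `sleep_wake` tibble.
#' @param act A 15-s `sleep_wake` tibble (count-scaled labels broadcast to the
#'   native epochs).
#' @return A tibble of class `aligned_pairs` with columns `time`, `psg`,
#'   `act`.
#' @export
align_to_15s <- function(psg, act) {
  psg_lab <- if (inherits(psg, "psg_night")) psg$labels else psg
  if (epoch_length_s(psg_lab) != 30 || epoch_length_s(act) != 15) {
    abort("align_to_15s() expects 30-s PSG labels and 15-s actigraphy labels",
          class = "actiscore_validation_error")
  }
  off <- as.numeric(psg_lab$time[1]) - as.numeric(act$time[1])
  if (abs(off %% 15) > 1e-6 && abs(off %% 15 - 15) > 1e-6) {
    abort("PSG and actigraphy grids are misaligned by a non-multiple of 15 s",
          class = "actiscore_alignment_error")
  }
  psg15 <- tibble(
    time = rep(psg_lab$time, each = 2) + rep(c(0, 15), nrow(psg_lab)),
    psg = rep(psg_lab$label, each = 2)
  )
  pairs <- inner_join(psg15,
                      tibble(time = act$time, act = act$label),
                      by = "time") |> arrange(.data$time)
  if (nrow(pairs) < 4) {
    abort("PSG and actigraphy overlap by less than one minute",
          class = "actiscore_overlap_error")
  }
  structure(pairs, class = c("aligned_pairs", class(pairs)))
}

#' Confusion table of PSG versus actigraphy epochs
#'
#' Counts each aligned epoch as true sleep (both sleep), false sleep
#' (actigraphy sleep, PSG wake), true wake (both wake) or false wake
#' (actigraphy wake, PSG sleep). Sleep is the positive class throughout.
#'
#' @param pairs An `aligned_pairs` tibble (or any tibble with `psg` and `act`
#'   label columns).
#' @return A one-row tibble of class `confusion_table` with the four cell
#'   counts and `total`.
#' @export
confusion_table <- function(pairs) {
  if (nrow(pairs) == 0) {
    abort("no aligned epochs to tabulate", class = "actiscore_empty_input_error")
  }
  x <- tibble(
    true_sleep = sum(pairs$psg == "sleep" & pairs$act == "sleep"),
    false_sleep = sum(pairs$psg == "wake" & pairs$act == "sleep"),
    true_wake = sum(pairs$psg == "wake" & pairs$act == "wake"),
    false_wake = sum(pairs$psg == "sleep" & pairs$act == "wake")
  )
  x$total <- x$true_sleep + x$false_sleep + x$true_wake + x$false_wake
  structure(x, class = c("confusion_table", class(x)))
}

# Wald CI for a proportion, on the percentage scale, clipped to [0, 100].
prop_ci_pct <- function(p, n, conf = 0.95) {
  if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p * (1 - p) / n)
  pmin(pmax(100 * c(p - z * se, p + z * se), 0), 100)
}

#' Epoch-by-epoch agreement statistics
#'
#' Sensitivity (percent of PSG sleep epochs scored sleep), specificity
#' (percent of PSG wake epochs scored wake), accuracy (percent of all epochs
#' in agreement), and the prevalence-adjusted bias-adjusted kappa
#' `PABAK = 2 * p_o - 1` with its verbal agreement band. A metric whose
#' denominator is zero is returned as `NA` (undefined), never as 0.
#' Confidence intervals are normal approximations on the underlying
#' proportions.
#'
#' @param table A [confusion_table()].
#' @param conf Confidence level.
#' @return A one-row tibble with the four statistics, their CIs and the
#'   agreement label.
#' @export
agreement_stats <- function(table, conf = 0.95) {
  ts <- table$true_sleep; fs <- table$false_sleep
  tw <- table$true_wake; fw <- table$false_wake
  tot <- ts + fs + tw + fw
  sens <- if (ts + fw > 0) ts / (ts + fw) else NA_real_
  spec <- if (tw + fs > 0) tw / (tw + fs) else NA_real_
  acc <- if (tot > 0) (ts + tw) / tot else NA_real_
  pb <- pabak(acc, n = tot, conf = conf)
  ci_sens <- prop_ci_pct(sens, ts + fw, conf)
  ci_spec <- prop_ci_pct(spec, tw + fs, conf)
  ci_acc <- prop_ci_pct(acc, tot, conf)
  tibble(
    n_epochs = tot,
    sensitivity_pct = 100 * sens, sensitivity_low = ci_sens[1],
    sensitivity_high = ci_sens[2],
    specificity_pct = 100 * spec, specificity_low = ci_spec[1],
    specificity_high = ci_spec[2],
    accuracy_pct = 100 * acc, accuracy_low = ci_acc[1],
    accuracy_high = ci_acc[2],
    pabak = pb$pabak, pabak_low = pb$ci_low, pabak_high = pb$ci_high,
    agreement = interpret_kappa(pb$pabak)
  )
}

#' Prevalence-adjusted bias-adjusted kappa
#'
#' `PABAK = 2 * p_o - 1`, where `p_o` is the observed proportional agreement;
#' overnight recordings are dominated by sleep epochs and PABAK corrects
#' kappa for that extreme prevalence imbalance. The confidence interval is the
#' normal approximation on `p_o`, transformed and clipped to `[-1, 1]`.
#'
#' @param x Observed agreement: a [confusion_table()], or the observed
#'   proportion of agreement `p_o` in `[0, 1]`.
#' @param n Number of epochs behind `p_o` (taken from the table when `x` is
#'   one); without it no CI is computed.
#' @param conf Confidence level.
#' @return A one-row tibble: `pabak`, `ci_low`, `ci_high`, `n`.
#' @examples
#' pabak(0.882, n = 20000) # observed agreement 88.2%
#' @export
pabak <- function(x, n = NULL, conf = 0.95) {
  if (inherits(x, "confusion_table")) {
    n <- x$total
    p_o <- (x$true_sleep + x$true_wake) / n
  } else {
    p_o <- as.numeric(x)
    if (is.na(p_o) || p_o < 0 || p_o > 1) {
      if (is.na(p_o)) return(tibble(pabak = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_, n = n %||% NA_real_))
      abort("observed agreement must lie in [0, 1]",
            class = "actiscore_validation_error")
    }
  }
  k <- 2 * p_o - 1
  if (is.null(n) || is.na(n) || n <= 0) {
    return(tibble(pabak = k, ci_low = NA_real_, ci_high = NA_real_,
                  n = NA_real_))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p_o * (1 - p_o) / n)
  lo <- max(-1, 2 * (p_o - z * se) - 1)
  hi <- min(1, 2 * (p_o + z * se) - 1)
  tibble(pabak = k, ci_low = lo, ci_high = hi, n = n)
}

#' Verbal agreement band for a kappa-type statistic
#'
#' The conventional bands: `<= 0` poor; 0.01-0.20 slight; 0.21-0.40 fair;
#' 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.00 almost perfect
#' (band upper bounds inclusive).
#'
#' @param value Kappa or PABAK values in `[-1, 1]`.
#' @return Character vector of agreement labels.
#' @export
interpret_kappa <- function(value) {
  if (any(!is.na(value) & (value < -1 | value > 1))) {
    abort("kappa must lie in [-1, 1]", class = "actiscore_validation_error")
  }
  dplyr::case_when(
    is.na(value) ~ NA_character_,
    value <= 0 ~ "poor agreement",
    value <= 0.20 ~ "slight agreement",
    value <= 0.40 ~ "fair agreement",
    value <= 0.60 ~ "moderate agreement",
    value <= 0.80 ~ "substantial agreement",
    TRUE ~ "almost perfect agreement"
  )
}

#' Bland-Altman comparison of two paired measurements
#'
#' Differences are taken device minus reference; the limits of agreement are
#' the mean difference plus/minus 1.96 times the sample standard deviation of
#' the differences, the range expected to contain 95% of individual
#' differences.
#'
#' @param device,reference Paired numeric vectors of equal length `>= 2`.
#' @return A one-row tibble of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, with the paired data kept for [autoplot()].
#' @export
bland_altman <- function(device, reference) {
  if (length(device) != length(reference)) {
    abort("paired vectors must have equal length",
          class = "actiscore_validation_error")
  }
  if (length(device) < 2) {
    abort("Bland-Altman needs at least two pairs",
          class = "actiscore_insufficient_data_error")
  }
  d <- device - reference
  m <- mean(d)
  s <- sd(d)
  out <- tibble(mean_diff = m, sd_diff = s, loa_low = m - 1.96 * s,
                loa_high = m + 1.96 * s, n = length(d))
  attr(out, "pairs") <- tibble(mean = (device + reference) / 2, diff = d)
  structure(out, class = c("bland_altman", class(out)))
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot: differences against pairwise means with the bias line
#'   and the limits of agreement.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "blue") +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (device - reference)")
}

#' Paired comparison of device and reference outcomes
#'
#' Two-sided paired t-test for approximately normal outcomes, or the Wilcoxon
#' signed-rank test (zero differences dropped, normal approximation with
#' continuity correction) for skewed outcomes such as WASO. When every
#' difference is zero the Wilcoxon statistic is undefined and the result is
#' returned with `p_value = 1` and a zero-variance note.
#'
#' @param device,reference Paired numeric vectors.
#' @param method `"paired_t"` or `"wilcoxon"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `n`, `note`.
#' @export
paired_tests <- function(device, reference,
                         method = c("paired_t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(device) != length(reference)) {
    abort("paired vectors must have equal length",
          class = "actiscore_validation_error")
  }
  d <- device - reference
  if (method == "paired_t") {
    if (length(d) < 2) {
      abort("paired t-test needs at least two pairs",
            class = "actiscore_insufficient_data_error")
    }
    if (sd(d) == 0) {
      return(tibble(method = method, statistic = 0,
                    p_value = if (mean(d) == 0) 1 else NA_real_,
                    n = length(d), note = "zero-variance differences"))
    }
    ht <- stats::t.test(device, reference, paired = TRUE)
    tibble(method = method, statistic = unname(ht$statistic),
           p_value = ht$p.value, n = length(d), note = NA_character_)
  } else {
    nz <- d[d != 0]
    if (length(nz) == 0) {
      return(tibble(method = method, statistic = 0, p_value = 1,
                    n = length(d), note = "all differences zero"))
    }
    ht <- suppressWarnings(
      stats::wilcox.test(device, reference, paired = TRUE, exact = FALSE,
                         correct = TRUE)
    )
    tibble(method = method, statistic = unname(ht$statistic),
           p_value = ht$p.value, n = length(d), note = NA_character_)
  }
}

#' Pooled and subject-level agreement summaries
#'
#' Pools the per-subject confusion cells into one table (every epoch weighted
#' equally) and, separately, summarises the subject-level metric distribution
#' with a seeded nonparametric bootstrap percentile interval on the mean
#' (every subject weighted equally). Overnight agreement tables rarely state
#' which of the two a published interval is; this reports both.
#'
#' @param per_subject A tibble with one row per subject containing the columns
#'   `true_sleep`, `false_sleep`, `true_wake`, `false_wake` (e.g. stacked
#'   [confusion_table()] rows).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed making the bootstrap reproducible.
#' @param conf Confidence level.
#' @return A list with `pooled` (one-row [agreement_stats()] tibble) and
#'   `subject_level` (tibble of metric, mean, bootstrap CI, n).
#' @export
per_subject_summary <- function(per_subject, n_boot = 2000, seed = 1,
                                conf = 0.95) {
  if (nrow(per_subject) < 1) {
    abort("need at least one subject", class = "actiscore_empty_input_error")
  }
  pooled_ct <- confusion_from_cells(
    sum(per_subject$true_sleep), sum(per_subject$false_sleep),
    sum(per_subject$true_wake), sum(per_subject$false_wake)
  )
  pooled <- agreement_stats(pooled_ct, conf = conf)
  per_stats <- purrr::pmap_dfr(
    per_subject[, c("true_sleep", "false_sleep", "true_wake", "false_wake")],
    function(true_sleep, false_sleep, true_wake, false_wake) {
      agreement_stats(confusion_from_cells(true_sleep, false_sleep,
                                           true_wake, false_wake))
    }
  )
  metrics <- c("sensitivity_pct", "specificity_pct", "accuracy_pct", "pabak")
  n_sub <- nrow(per_stats)
  alpha <- (1 - conf) / 2
  subject_level <- withr::with_seed(seed, {
    purrr::map_dfr(metrics, function(m) {
      v <- per_stats[[m]]
      if (n_sub == 1) {
        return(tibble(metric = m, mean = mean(v, na.rm = TRUE),
                      ci_low = v[1], ci_high = v[1], n = 1L))
      }
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(v[sample.int(n_sub, replace = TRUE)], na.rm = TRUE)
      }, numeric(1))
      tibble(metric = m, mean = mean(v, na.rm = TRUE),
             ci_low = unname(quantile(boots, alpha, na.rm = TRUE)),
             ci_high = unname(quantile(boots, 1 - alpha, na.rm = TRUE)),
             n = n_sub)
    })
  })
  list(pooled = pooled, subject_level = subject_level)
}

# Internal constructor for a confusion table from four cell counts.
confusion_from_cells <- function(true_sleep, false_sleep, true_wake,
                                 false_wake) {
  x <- tibble(true_sleep = true_sleep, false_sleep = false_sleep,
              true_wake = true_wake, false_wake = false_wake)
  x$total <- true_sleep + false_sleep + true_wake + false_wake
  structure(x, class = c("confusion_table", class(x)))
}
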
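#' Night-level sleep outcomes from scored labels
#'
#' Derives the six standard outcomes between sleep onset and offset: sleep
#' period time `SPT = offset - onset` (min); wake after sleep onset `WASO`,
#' the minutes labelled wake strictly between onset and offset, counting only
#' wake bouts of at least `waso_min_bout_min` minutes (the default 1 counts
#' every wake epoch; 5 gives the consecutive-awakenings convention); total
#' sleep time `TST = SPT - WASO`; and sleep efficiency `100 * TST / SPT`.
#'
#' @param labels A `sleep_wake` tibble at any epoch resolution.
#' @param onset,offset POSIXct sleep onset and offset, `onset < offset`, both
#'   within the label span.
#' @param waso_min_bout_min Minimum wake-bout duration in minutes.
#' @return A one-row tibble: `onset`, `offset`, `spt_min`, `waso_min`,
#'   `tst_min`, `efficiency_pct`.
#' @examples
#' t0 <- as.POSIXct("2024-03-01 21:00:00", tz = "UTC")
#' lab <- actiscore:::new_sleep_wake("S01", t0 + seq(0, by = 60, length.out = 600),
#'                                  rep("sleep", 600), 60, "manual")
#' compute_outcomes(lab, t0, t0 + 600 * 60)
#' @export
compute_outcomes <- function(labels, onset, offset, waso_min_bout_min = 1) {
  if (!(onset < offset)) {
    abort("sleep onset must precede sleep offset",
          class = "actiscore_ordering_error")
  }
  len <- epoch_length_s(labels)
  spt <- as.numeric(difftime(offset, onset, units = "mins"))
  inside <- labels$time >= onset & (labels$time + len) <= offset
  lab <- labels$label[inside]
  waso <- 0
  if (length(lab) > 0) {
    r <- rle(lab)
    dur_min <- r$lengths * len / 60
    keep <- r$values == "wake" & dur_min >= waso_min_bout_min
    waso <- sum(dur_min[keep])
  }
  waso <- min(waso, spt)
  tst <- spt - waso
  tibble(onset = onset, offset = offset, spt_min = spt, waso_min = waso,
         tst_min = tst, efficiency_pct = 100 * tst / spt)
}

#' Sleep outcomes for a scored night
#'
#' Convenience wrapper applying [compute_outcomes()] to a `scored_night`,
#' keeping subject/device/site/algorithm identifiers.
#'
#' @param night A [score_night()] result.
#' @param waso_min_bout_min Minimum wake-bout duration in minutes; defaults to
#'   the night's configuration.
#' @return A one-row tibble of identifiers plus the six outcomes.
#' @export
sleep_outcomes <- function(night, waso_min_bout_min = NULL) {
  waso_min_bout_min <- waso_min_bout_min %||% night$config$waso_min_bout_min
  dplyr::bind_cols(
    tibble(subject_id = night$subject_id, device = night$device,
           site = night$site, algorithm = night$algorithm),
    compute_outcomes(night$labels, night$onset, night$offset,
                     waso_min_bout_min = waso_min_bout_min)
  )
}

#' Summarise one outcome variable across a cohort
#'
#' Mean with sample standard deviation, or median with 25th/75th percentiles
#' (linear interpolation), the two summary styles used for night-level sleep
#' outcome tables (WASO and sleep efficiency are conventionally summarised as
#' median (IQR), the remaining variables as mean (SD)). With a single value
#' the SD is reported as 0 and flagged via `n = 1` rather than returned
#' missing.
#'
#' @param outcomes A data frame of per-subject outcomes.
#' @param variable Name of the numeric column to summarise.
#' @param summary_kind `"mean_sd"` or `"median_iqr"`.
#' @return A one-row tibble: `variable`, `summary_kind`, `center`,
#'   `spread_low`, `spread_high`, `n`.
#' @export
summarize_cohort <- function(outcomes, variable,
                             summary_kind = c("mean_sd", "median_iqr")) {
  summary_kind <- match.arg(summary_kind)
  v <- outcomes[[variable]]
  if (is.null(v) || length(v) == 0) {
    abort(sprintf("no values to summarise for '%s'", variable),
          class = "actiscore_empty_input_error")
  }
  if (summary_kind == "mean_sd") {
    s <- if (length(v) < 2) 0 else sd(v)
    tibble(variable = variable, summary_kind = summary_kind,
           center = mean(v), spread_low = mean(v) - s,
           spread_high = mean(v) + s, n = length(v))
  } else {
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    tibble(variable = variable, summary_kind = summary_kind,
           center = q[2], spread_low = q[1], spread_high = q[3],
           n = length(v))
  }
}
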
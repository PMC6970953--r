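#' Aggregate sub-minute epochs to one value per minute
#'
#' Sums each whole minute's constituent epoch counts, dropping a trailing
#' partial minute. A 60-s series passes through unchanged.
#'
#' @param series An [epoch_series()] whose epoch length divides 60.
#' @return A tibble with columns `time` (minute start) and `value` (summed
#'   counts), carrying `epoch_length_s = 60`.
#' @examples
#' t0 <- as.POSIXct("2024-03-01 20:00:00", tz = "UTC")
#' aggregate_to_minutes(epoch_series(t0 + seq(0, 45, 15), c(10, 20, 30, 40)))
#' @export
aggregate_to_minutes <- function(series) {
  len <- epoch_length_s(series)
  if (len == 60) {
    out <- tibble(time = series$time, value = series$count)
  } else {
    if (60 %% len != 0) {
      abort(sprintf("epoch length %s s does not divide 60", len),
            class = "actiscore_resolution_error")
    }
    per <- 60 / len
    n_min <- floor(nrow(series) / per)
    if (n_min < 1) {
      abort("series does not span a whole minute",
            class = "actiscore_validation_error")
    }
    idx <- seq_len(n_min * per)
    grp <- rep(seq_len(n_min), each = per)
    out <- tibble(
      time = series$time[seq(1, by = per, length.out = n_min)],
      value = as.numeric(tapply(series$count[idx], grp, sum))
    )
  }
  attr(out, "epoch_length_s") <- 60
  out
}

#' Scale activity to the recording's mean non-zero value
#'
#' Divides every value by the mean of the strictly positive values of the
#' recording, so that across devices and placements "1" means the recording's
#' own average level of movement. An all-zero recording is returned unchanged
#' with a scale factor of 1 (the mean of an empty set is undefined; identity
#' is the only neutral choice).
#'
#' @param x A minute-activity tibble from [aggregate_to_minutes()] (column
#'   `value`) or an [epoch_series()] (column `count`).
#' @return `x` with an added `scaled` column and a `scale_factor` attribute.
#' @examples
#' m <- tibble::tibble(time = Sys.time() + c(0, 60, 120), value = c(0, 2, 4))
#' scale_counts(m) # scale factor 3: the mean of {2, 4}
#' @export
scale_counts <- function(x) {
  col <- if ("value" %in% names(x)) "value" else "count"
  v <- x[[col]]
  if (length(v) < 1) {
    abort("cannot scale an empty series", class = "actiscore_validation_error")
  }
  nz <- v[v > 0]
  factor <- if (length(nz) == 0) 1 else mean(nz)
  x$scaled <- v / factor
  attr(x, "scale_factor") <- factor
  x
}

#' Scale factor of a scaled series
#' @param x Output of [scale_counts()].
#' @return The positive scale factor.
#' @export
scale_factor <- function(x) {
  f <- attr(x, "scale_factor")
  if (is.null(f)) abort("`x` carries no scale factor; run scale_counts() first",
                        class = "actiscore_validation_error")
  f
}

#' Weighted activity over the classification window
#'
#' For each minute, the weighted sum of the scaled activity over the window
#' from `window_before_min` minutes before to `window_after_min` minutes after
#' the current minute. Where the window runs off a recording edge the
#' surviving weights are renormalised to the full-window weight sum, so edge
#' minutes are not biased toward sleep.
#'
#' @param scaled Numeric vector of scaled minute activity, or the tibble from
#'   [scale_counts()].
#' @param config A [cs_config()].
#' @return Numeric vector of weighted activity, one value per minute.
#' @export
weighted_activity <- function(scaled, config = cs_config()) {
  x <- if (is.numeric(scaled)) scaled else scaled$scaled
  n <- length(x)
  w <- config$weights
  offs <- seq.int(-config$window_before_min, config$window_after_min)
  num <- numeric(n)
  den <- numeric(n)
  for (j in seq_along(offs)) {
    k <- offs[j]
    src <- seq_len(n) + k
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + w[j] * x[src[ok]]
    den[ok] <- den[ok] + w[j]
  }
  num * (sum(w) / den)
}

#' Classify each minute as sleep or wake
#'
#' A minute is scored sleep when its weighted scaled activity is strictly
#' below the threshold (default 1); otherwise wake.
#'
#' @param scaled Tibble from [scale_counts()] at minute resolution (columns
#'   `time`, `scaled`).
#' @param config A [cs_config()].
#' @param subject_id Subject label recorded in the output.
#' @return A minute-resolution `sleep_wake` tibble (columns `subject_id`,
#'   `time`, `label` in `"sleep"`/`"wake"`) with provenance attributes.
#' @export
classify_sleep_wake <- function(scaled, config = cs_config(),
                                subject_id = "S01") {
  wa <- weighted_activity(scaled, config)
  new_sleep_wake(
    subject_id = subject_id, time = scaled$time,
    label = ifelse(wa < config$threshold, "sleep", "wake"),
    epoch_length_s = 60, algorithm = "count-scaled",
    params = unclass(config)
  )
}

#' Detect sleep and wake events in a minute label sequence
#'
#' A sleep (onset) event is the start of `sleep_run_min` continuous minutes of
#' sleep preceded by `wake_run_min` minutes of wake; a wake event is the last
#' minute of `sleep_run_min` continuous minutes of sleep followed by
#' `wake_run_min` minutes of wake. Onset events are timestamped at the start
#' of their minute; wake events at the end of theirs (the first minute of
#' wake). The `minute` column gives the 0-based minute index into the series.
#'
#' @param labels Minute-resolution `sleep_wake` tibble.
#' @param config A [cs_config()].
#' @return A tibble with columns `type` (`"onset"`/`"wake"`), `minute`, `time`.
#' @export
detect_events <- function(labels, config = cs_config()) {
  s <- labels$label == "sleep"
  n <- length(s)
  sr <- config$sleep_run_min
  wr <- config$wake_run_min
  empty <- tibble(type = character(), minute = integer(),
                  time = labels$time[0])
  if (n < sr + wr) return(empty)
  cs <- c(0, cumsum(s))
  run_sleep <- function(i, len) cs[i + len] - cs[i] == len   # all sleep
  run_wake <- function(i, len) cs[i + len] - cs[i] == 0      # all wake
  i_on <- seq.int(wr + 1L, n - sr + 1L)
  on <- i_on[run_sleep(i_on, sr) & run_wake(i_on - wr, wr)]
  j_wk <- seq.int(sr, n - wr)
  wk <- j_wk[run_sleep(j_wk - sr + 1L, sr) & run_wake(j_wk + 1L, wr)]
  bind_rows(
    tibble(type = "onset", minute = on - 1L, time = labels$time[on]),
    tibble(type = "wake", minute = wk - 1L, time = labels$time[wk] + 60)
  ) |> arrange(.data$time)
}

# Shared flag-anchored search: first event in [flag, flag + fwd h]; else last
# event in [flag - bwd h, flag); else the flag itself. The backward window is
# half-open so an event exactly at the flag is matched by the forward pass
# only.
locate_event <- function(times, flag, fwd_h, bwd_h) {
  if (length(times) > 0) {
    fwd <- times[times >= flag & times <= flag + fwd_h * 3600]
    if (length(fwd) > 0) return(min(fwd))
    bwd <- times[times >= flag - bwd_h * 3600 & times < flag]
    if (length(bwd) > 0) return(max(bwd))
  }
  flag
}

#' Locate sleep onset from detected events
#'
#' Searches `forward_search_h` hours forward from the bedtime flag for the
#' first onset event, then `backward_search_h` hours backward for the last
#' one, and falls back to the flag itself when neither window contains an
#' event.
#'
#' @param events Event tibble from [detect_events()].
#' @param flag POSIXct bedtime flag.
#' @param config A [cs_config()].
#' @return POSIXct sleep onset.
#' @export
locate_sleep_onset <- function(events, flag, config = cs_config()) {
  locate_event(events$time[events$type == "onset"], flag,
               config$forward_search_h, config$backward_search_h)
}

#' Locate sleep offset from detected events
#'
#' Mirror of [locate_sleep_onset()] on wake events, anchored at the wake-time
#' flag.
#'
#' @inheritParams locate_sleep_onset
#' @param flag POSIXct wake-time flag.
#' @return POSIXct sleep offset.
#' @export
locate_sleep_offset <- function(events, flag, config = cs_config()) {
  locate_event(events$time[events$type == "wake"], flag,
               config$forward_search_h, config$backward_search_h)
}

#' Score one night of activity counts
#'
#' Runs the full automated pipeline on a single overnight recording:
#' aggregation to minutes, count scaling, weighted-sum classification, event
#' detection and flag-anchored onset/offset location (`algorithm =
#' "count-scaled"`), or reintegration to 60-s epochs, count capping and the
#' Sadeh index (`algorithm = "sadeh"`, which reuses the same event and flag
#' logic to locate onset and offset -- recorded in the provenance). For the
#' count-scaled scorer each minute's label is broadcast back to its
#' constituent native epochs so the result can be compared with PSG
#' epoch-by-epoch; Sadeh labels stay at 60-s resolution.
#'
#' @param series An [epoch_series()] covering the bedtime flag through the
#'   following wake-time flag.
#' @param config A [cs_config()].
#' @param algorithm `"count-scaled"` or `"sadeh"`.
#' @param sadeh A [sadeh_params()], used when `algorithm = "sadeh"`.
#' @return A list of class `scored_night`: `labels` (native-resolution
#'   `sleep_wake` tibble), `minute_labels`, `events`, `onset`, `offset`,
#'   `scale_factor` (count-scaled only), plus metadata and the full
#'   configuration.
#' @export
score_night <- function(series, config = cs_config(),
                        algorithm = c("count-scaled", "sadeh"),
                        sadeh = sadeh_params()) {
  algorithm <- match.arg(algorithm)
  series <- validate_epoch_series(series,
                                  epoch_length_s = attr(series, "epoch_length_s"))
  len <- epoch_length_s(series)
  rec_start <- series$time[1]
  rec_end <- series$time[nrow(series)] + len
  bed <- resolve_flag(parse_clock(config$bedtime_flag), rec_start)
  wake <- resolve_flag(parse_clock(config$waketime_flag), bed)
  if (bed < rec_start || wake > rec_end) {
    abort("recording does not cover the bedtime and wake-time flags",
          class = "actiscore_coverage_error")
  }

  sf <- NA_real_
  if (algorithm == "count-scaled") {
    if (config$scaling_resolution == "epoch") {
      sc_ep <- scale_counts(series)
      sf <- scale_factor(sc_ep)
      minutes <- aggregate_to_minutes(series)
      minutes$scaled <- minutes$value / sf
      scaled <- minutes
    } else {
      scaled <- scale_counts(aggregate_to_minutes(series))
      sf <- scale_factor(scaled)
    }
    minute_labels <- classify_sleep_wake(scaled, config,
                                         subject_id = series$subject_id[1])
    per <- 60 / len
    n_ep <- nrow(minute_labels) * per
    labels <- new_sleep_wake(
      subject_id = series$subject_id[1],
      time = series$time[seq_len(n_ep)],
      label = rep(minute_labels$label, each = per),
      epoch_length_s = len, algorithm = "count-scaled",
      params = unclass(config)
    )
  } else {
    min_series <- reintegrate_to_60s(series)
    capped <- cap_counts(min_series, sadeh)
    minute_labels <- sadeh_classify(capped, sadeh)
    labels <- minute_labels
  }
  events <- detect_events(minute_labels, config)
  onset <- locate_sleep_onset(events, bed, config)
  offset <- locate_sleep_offset(events, wake, config)
  structure(list(
    subject_id = series$subject_id[1], device = series$device[1],
    site = series$site[1], algorithm = algorithm,
    labels = labels, minute_labels = minute_labels, events = events,
    onset = onset, offset = offset,
    bedtime_flag = bed, waketime_flag = wake,
    scale_factor = sf, config = config,
    sadeh = if (algorithm == "sadeh") sadeh else NULL
  ), class = "scored_night")
}

#' @export
print.scored_night <- function(x, ...) {
  cat(sprintf("<scored_night> %s %s/%s [%s]\n", x$subject_id, x$device,
              x$site, x$algorithm))
  cat(sprintf("  onset  %s\n  offset %s\n",
              format(x$onset, "%Y-%m-%d %H:%M:%S"),
              format(x$offset, "%Y-%m-%d %H:%M:%S")))
  cat(sprintf("  %d labelled epochs (%g s), %d events\n",
              nrow(x$labels), epoch_length_s(x$labels), nrow(x$events)))
  invisible(x)
}

#' Tidy a scored night into its per-epoch labels
#'
#' @param x A `scored_night`.
#' @param ... Unused.
#' @return The per-epoch label tibble with metadata columns.
#' @method tidy scored_night
#' @export
tidy.scored_night <- function(x, ...) {
  mutate(as_tibble(x$labels), device = x$device, site = x$site,
         algorithm = x$algorithm, .after = "subject_id")
}

#' One-row summary of a scored night
#'
#' @param x A `scored_night`.
#' @param ... Unused.
#' @return A one-row tibble with identifiers, onset/offset and the sleep
#'   outcomes from [compute_outcomes()].
#' @method glance scored_night
#' @export
glance.scored_night <- function(x, ...) {
  out <- compute_outcomes(x$labels, x$onset, x$offset,
                          waso_min_bout_min = x$config$waso_min_bout_min)
  dplyr::bind_cols(
    tibble(subject_id = x$subject_id, device = x$device, site = x$site,
           algorithm = x$algorithm, scale_factor = x$scale_factor),
    out
  )
}

#' Raster plot of counts and scored state for one night
#'
#' @param object A `scored_night`.
#' @param ... Unused.
#' @return A ggplot object: scored sleep shaded, onset/offset marked.
#' @method autoplot scored_night
#' @export
autoplot.scored_night <- function(object, ...) {
  lab <- as_tibble(object$labels)
  len <- epoch_length_s(object$labels)
  runs <- lab |>
    mutate(grp = cumsum(.data$label != lag(.data$label, default = "none"))) |>
    group_by(.data$grp, .data$label) |>
    summarise(start = min(.data$time), end = max(.data$time) + len,
              .groups = "drop") |>
    filter(.data$label == "sleep")
  ggplot2::ggplot(object$minute_labels) +
    ggplot2::geom_rect(
      data = runs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.25, inherit.aes = FALSE
    ) +
    ggplot2::geom_vline(xintercept = c(object$onset, object$offset),
                        linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s %s/%s (%s): scored sleep period", object$subject_id,
                      object$device, object$site, object$algorithm)
    )
}
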
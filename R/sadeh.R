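#' Reintegrate a count series to 60-s epochs
#'
#' Sums sub-minute epochs into 1-min epochs (the resolution the Sadeh index is
#' defined on), dropping a trailing partial minute. A 60-s series passes
#' through unchanged.
#'
#' @param series An [epoch_series()] whose epoch length divides 60.
#' @return An [epoch_series()] at 60-s resolution with the same metadata.
#' @export
reintegrate_to_60s <- function(series) {
  len <- epoch_length_s(series)
  if (len == 60) return(series)
  minutes <- aggregate_to_minutes(series)
  validate_epoch_series(
    tibble(subject_id = series$subject_id[1], device = series$device[1],
           site = series$site[1], time = minutes$time, count = minutes$value),
    epoch_length_s = 60
  )
}

#' Cap per-minute counts
#'
#' Replaces every count above `count_cap` (default 300) by the cap, the
#' standard preprocessing before the Sadeh index. Idempotent; set
#' `count_cap = Inf` in [sadeh_params()] to disable.
#'
#' @param series An [epoch_series()].
#' @param params A [sadeh_params()].
#' @return The series with capped counts.
#' @export
cap_counts <- function(series, params = sadeh_params()) {
  series$count <- pmin(series$count, params$count_cap)
  series
}

#' Sadeh sleep index for every minute of a series
#'
#' Evaluates `SI = intercept + coef_mu * mu + coef_nat * nat + coef_sigma *
#' sigma + coef_logact * log(activity + 1)` at each minute, where `mu` and
#' `nat` (the number of epochs with activity in `[50, 100)`) are taken over an
#' 11-min window centred on the minute, and `sigma` is the sample standard
#' deviation over the 6 minutes ending at and including the minute. Windows
#' truncate at the recording edges (no padding); `sigma` of a single minute is
#' 0.
#'
#' @param counts Numeric vector of (capped) per-minute counts, or a 60-s
#'   [epoch_series()].
#' @param params A [sadeh_params()].
#' @return Numeric vector of index values, one per minute.
#' @export
sadeh_index <- function(counts, params = sadeh_params()) {
  x <- if (is.numeric(counts)) counts else counts$count
  n <- length(x)
  hw <- params$window_half_width_min
  lb <- params$sigma_lookback_min
  is_nat <- as.numeric(x >= 50 & x < 100)
  csx <- c(0, cumsum(x))
  csn <- c(0, cumsum(is_nat))
  t <- seq_len(n)
  lo <- pmax(1L, t - hw)
  hi <- pmin(n, t + hw)
  wlen <- hi - lo + 1
  mu <- (csx[hi + 1] - csx[lo]) / wlen
  nat <- csn[hi + 1] - csn[lo]
  slo <- pmax(1L, t - (lb - 1L))
  sigma <- vapply(t, function(i) {
    v <- x[slo[i]:i]
    if (length(v) < 2) 0 else sd(v)
  }, numeric(1))
  params$intercept + params$coef_mu * mu + params$coef_nat * nat +
    params$coef_sigma * sigma + params$coef_logact * log(x + 1)
}

#' Classify a night with the Sadeh algorithm
#'
#' Caps counts, evaluates the Sadeh index at 60-s resolution and scores each
#' minute sleep when `SI >= 0`.
#'
#' @param series An [epoch_series()]; sub-minute epochs are reintegrated to
#'   60 s first.
#' @param params A [sadeh_params()].
#' @return A 60-s `sleep_wake` tibble with provenance attributes.
#' @export
sadeh_classify <- function(series, params = sadeh_params()) {
  series <- reintegrate_to_60s(series)
  capped <- cap_counts(series, params)
  si <- sadeh_index(capped$count, params)
  new_sleep_wake(
    subject_id = series$subject_id[1], time = series$time,
    label = ifelse(si >= 0, "sleep", "wake"),
    epoch_length_s = 60, algorithm = "sadeh", params = unclass(params)
  )
}
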
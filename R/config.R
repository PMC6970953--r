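#' Configuration for the count-scaled scoring algorithm
#'
#' Bundles every tunable of the count-scaled scorer. The defaults encode the
#' published procedure for school-age children: a 19:30 bedtime flag and a
#' 06:00 wake-time flag, a weighted sum over the current minute, the preceding
#' 4 minutes and the following 2 minutes compared against a sleep-wake
#' threshold of 1 (weighted activity `< 1` scores sleep), sleep events defined
#' as 15 continuous minutes of sleep preceded by 5 minutes of wake (and the
#' mirror image for wake events), and a 3-h-forward / 2-h-backward search
#' around each flag.
#'
#' The default weight vector puts weight 0.8 on the current minute, 0.1 on
#' each of the four preceding minutes and 0.15 on each of the two following
#' minutes. With counts scaled so that the mean non-zero minute is 1, this
#' keeps state transitions sharp to the minute: a minute of sustained average
#' wake movement always reaches the threshold (its own 0.8 plus at least 0.2
#' from adjacent wake minutes), while the preceding-window (0.4) and
#' following-window (0.3) sums stay below it, so the first quiet minute after
#' movement already scores sleep. A uniform 1/7 smoothing vector may be
#' supplied instead.
#'
#' @param bedtime_flag,waketime_flag Clock times (`"HH:MM"`) anchoring the
#'   onset and offset searches.
#' @param threshold Sleep-wake threshold on the weighted scaled activity.
#' @param window_before_min,window_after_min Minutes before/after the current
#'   minute entering the weighted sum.
#' @param weights Non-negative weight vector of length
#'   `window_before_min + 1 + window_after_min`, ordered from the earliest
#'   minute to the latest.
#' @param sleep_run_min,wake_run_min Run lengths (minutes) defining sleep and
#'   wake events.
#' @param forward_search_h,backward_search_h Hours searched after/before a
#'   flag for an event.
#' @param waso_min_bout_min Minimum wake-bout duration (minutes) counted into
#'   WASO; 1 counts every wake minute, 5 gives the consecutive-awakenings
#'   convention.
#' @param scaling_resolution `"minute"` (default) scales by the mean non-zero
#'   minute value after aggregation; `"epoch"` scales at the native epoch
#'   resolution before aggregation.
#' @return A list of class `cs_config`.
#' @export
cs_config <- function(bedtime_flag = "19:30",
                      waketime_flag = "06:00",
                      threshold = 1,
                      window_before_min = 4L,
                      window_after_min = 2L,
                      weights = c(0.1, 0.1, 0.1, 0.1, 0.8, 0.15, 0.15),
                      sleep_run_min = 15L,
                      wake_run_min = 5L,
                      forward_search_h = 3,
                      backward_search_h = 2,
                      waso_min_bout_min = 1L,
                      scaling_resolution = c("minute", "epoch")) {
  scaling_resolution <- match.arg(scaling_resolution)
  cfg <- list(
    bedtime_flag = bedtime_flag, waketime_flag = waketime_flag,
    threshold = threshold,
    window_before_min = as.integer(window_before_min),
    window_after_min = as.integer(window_after_min),
    weights = as.numeric(weights),
    sleep_run_min = as.integer(sleep_run_min),
    wake_run_min = as.integer(wake_run_min),
    forward_search_h = forward_search_h,
    backward_search_h = backward_search_h,
    waso_min_bout_min = as.integer(waso_min_bout_min),
    scaling_resolution = scaling_resolution
  )
  if (length(cfg$weights) != cfg$window_before_min + 1L + cfg$window_after_min) {
    abort("weights must have length window_before_min + 1 + window_after_min",
          class = "actiscore_validation_error")
  }
  if (any(cfg$weights < 0) || sum(cfg$weights) <= 0) {
    abort("weights must be non-negative with positive sum",
          class = "actiscore_validation_error")
  }
  stopifnot(cfg$sleep_run_min > 0, cfg$wake_run_min > 0,
            cfg$forward_search_h > 0, cfg$backward_search_h > 0,
            cfg$waso_min_bout_min > 0)
  for (f in c("bedtime_flag", "waketime_flag")) parse_clock(cfg[[f]])
  class(cfg) <- "cs_config"
  cfg
}

#' Parameters of the Sadeh sleep index
#'
#' The Sadeh index for a 1-min epoch is
#' `SI = intercept + coef_mu * mu + coef_nat * nat + coef_sigma * sigma +
#' coef_logact * log(activity + 1)`, where `mu` is the mean activity over an
#' 11-min window centred on the epoch, `nat` the number of epochs in that
#' window with activity in `[50, 100)`, `sigma` the standard deviation of
#' activity over the last 6 minutes (ending at and including the current
#' epoch), and the epoch is scored sleep when `SI >= 0`. Coefficients default
#' to the published 1994 values; counts are capped at 300 before the index is
#' evaluated (set `count_cap = Inf` to disable).
#'
#' @param intercept,coef_mu,coef_nat,coef_sigma,coef_logact Model
#'   coefficients.
#' @param count_cap Per-minute count ceiling applied before the index.
#' @param window_half_width_min Half width of the centred window (5 gives the
#'   11-min window).
#' @param sigma_lookback_min Number of minutes, ending at the current epoch,
#'   entering the standard-deviation term.
#' @return A list of class `sadeh_params`.
#' @export
sadeh_params <- function(intercept = 7.601, coef_mu = -0.065,
                         coef_nat = -1.08, coef_sigma = -0.056,
                         coef_logact = -0.703,
                         count_cap = 300,
                         window_half_width_min = 5L,
                         sigma_lookback_min = 6L) {
  stopifnot(count_cap > 0, window_half_width_min >= 0, sigma_lookback_min >= 1)
  p <- list(intercept = intercept, coef_mu = coef_mu, coef_nat = coef_nat,
            coef_sigma = coef_sigma, coef_logact = coef_logact,
            count_cap = count_cap,
            window_half_width_min = as.integer(window_half_width_min),
            sigma_lookback_min = as.integer(sigma_lookback_min))
  class(p) <- "sadeh_params"
  p
}

# Parse "HH:MM" or "HH:MM:SS" into seconds after midnight.
parse_clock <- function(x) {
  p <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!(length(p) %in% c(2L, 3L)) || anyNA(suppressWarnings(as.numeric(p)))) {
    abort(sprintf("cannot parse clock time '%s'", x),
          class = "actiscore_format_error")
  }
  p <- as.numeric(p)
  p[1] * 3600 + p[2] * 60 + if (length(p) == 3L) p[3] else 0
}

# First occurrence of clock time `clock` (seconds after midnight) at or after
# `from`.
resolve_flag <- function(clock, from) {
  day <- trunc(from, units = "days")
  cand <- day + clock
  if (cand < from) cand <- cand + 86400
  cand
}

#' Read a scoring configuration from a YAML file
#'
#' Keys mirror the arguments of [cs_config()] (under `count_scaled:`) and
#' [sadeh_params()] (under `sadeh:`); missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `count_scaled` and `sadeh`.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "actiscore_format_error")
  }
  y <- yaml::read_yaml(path)
  cs <- do.call(cs_config, y$count_scaled %||% list())
  sd <- do.call(sadeh_params, y$sadeh %||% list())
  list(count_scaled = cs, sadeh = sd)
}
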
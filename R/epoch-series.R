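#' Build a per-epoch activity-count series
#'
#' An epoch-count series is a tibble with one row per recording epoch and
#' columns `subject_id`, `device`, `site`, `time` (POSIXct, local clock time
#' stored as UTC) and `count` (non-negative vertical-axis activity counts).
#' Epochs must be evenly spaced, the epoch length must divide 60 seconds (15 s
#' is the canonical device setting) or equal 60 s, and counts are taken as
#' exported -- no device rescaling is attempted.
#'
#' @param time POSIXct vector of epoch start times, strictly increasing and
#'   evenly spaced.
#' @param count Numeric vector of activity counts, all `>= 0`.
#' @param subject_id,device,site Metadata labels; `site` must be `"hip"` or
#'   `"wrist"`.
#' @return A tibble of class `epoch_series`.
#' @examples
#' t0 <- as.POSIXct("2024-03-01 20:00:00", tz = "UTC")
#' epoch_series(t0 + seq(0, 45, by = 15), c(0, 2, 4, 8))
#' @export
epoch_series <- function(time, count, subject_id = "S01",
                         device = "actigraph", site = c("hip", "wrist")) {
  site <- match.arg(site)
  x <- tibble(
    subject_id = as.character(subject_id),
    device = as.character(device),
    site = site,
    time = time,
    count = as.numeric(count)
  )
  validate_epoch_series(x)
}

#' Validate an epoch-count series
#'
#' Checks the `epoch_series` invariants (non-negative counts, uniform epoch
#' spacing, epoch length dividing 60 s or equal to 60 s) and returns the input
#' with the `epoch_series` class attached. Readers and the simulator call this
#' on everything they produce; malformed input is rejected, never repaired.
#'
#' @param x A data frame with columns `subject_id`, `device`, `site`, `time`,
#'   `count`.
#' @param epoch_length_s Epoch length in seconds, required only when `x` has a
#'   single row (it cannot be inferred from one timestamp).
#' @return `x` as a validated `epoch_series` tibble.
#' @export
validate_epoch_series <- function(x, epoch_length_s = NULL) {
  x <- as_tibble(x)
  need <- c("subject_id", "device", "site", "time", "count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("epoch series is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "actiscore_format_error")
  }
  if (nrow(x) < 1) {
    abort("epoch series must contain at least one epoch",
          class = "actiscore_validation_error")
  }
  if (!inherits(x$time, "POSIXct")) {
    abort("`time` must be POSIXct", class = "actiscore_validation_error")
  }
  bad <- which(!is.finite(x$count) | x$count < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or non-finite count at row %d", bad[1]),
          class = "actiscore_validation_error")
  }
  if (nrow(x) >= 2) {
    dt <- as.numeric(diff(as.numeric(x$time)))
    len <- dt[1]
    if (len <= 0) {
      abort("epoch timestamps must be strictly increasing",
            class = "actiscore_validation_error")
    }
    off <- which(abs(dt - len) > 1e-6)
    if (length(off) > 0) {
      abort(sprintf("non-uniform epoch spacing at %s",
                    format(x$time[off[1] + 1], "%Y-%m-%d %H:%M:%S")),
            class = "actiscore_gap_error")
    }
    if (!is.null(epoch_length_s) && abs(epoch_length_s - len) > 1e-6) {
      abort("declared epoch length disagrees with timestamp spacing",
            class = "actiscore_validation_error")
    }
    epoch_length_s <- len
  }
  if (is.null(epoch_length_s)) {
    abort("single-row series requires an explicit `epoch_length_s`",
          class = "actiscore_validation_error")
  }
  if (!(epoch_length_s == 60 || (epoch_length_s > 0 && 60 %% epoch_length_s == 0))) {
    abort(sprintf("unsupported epoch length %s s (must divide 60 or equal 60)",
                  epoch_length_s),
          class = "actiscore_resolution_error")
  }
  attr(x, "epoch_length_s") <- as.numeric(epoch_length_s)
  class(x) <- unique(c("epoch_series", class(x)))
  x
}

#' Epoch length of a series in seconds
#'
#' @param x An `epoch_series`, hypnogram or label tibble with a `time` column.
#' @return Epoch length in seconds.
#' @export
epoch_length_s <- function(x) {
  len <- attr(x, "epoch_length_s")
  if (!is.null(len)) return(len)
  if (nrow(x) < 2) {
    abort("cannot infer epoch length from fewer than two rows",
          class = "actiscore_validation_error")
  }
  as.numeric(x$time[2]) - as.numeric(x$time[1])
}

#' Sleep stage alphabet
#'
#' The five AASM stage symbols used in hypnograms.
#' @export
AASM_STAGES <- c("W", "N1", "N2", "N3", "R")

#' Build a 30-s hypnogram
#'
#' A hypnogram is a tibble with one row per 30-s polysomnography epoch and
#' columns `subject_id`, `time` and `stage` (one of `W`, `N1`, `N2`, `N3`,
#' `R`).
#'
#' @param time POSIXct vector of epoch start times on a 30-s grid.
#' @param stage Character vector of AASM stages.
#' @param subject_id Subject label.
#' @param lights_out,lights_on Optional POSIXct markers; when present,
#'   `lights_out < lights_on` and both must fall within the recording span.
#' @return A tibble of class `hypnogram` with `lights_out`/`lights_on` stored
#'   as attributes.
#' @export
hypnogram <- function(time, stage, subject_id = "S01",
                      lights_out = NULL, lights_on = NULL) {
  x <- tibble(subject_id = as.character(subject_id), time = time,
              stage = as.character(stage))
  validate_hypnogram(x, lights_out = lights_out, lights_on = lights_on)
}

#' Validate a hypnogram
#'
#' @param x Data frame with columns `subject_id`, `time`, `stage`.
#' @inheritParams hypnogram
#' @return A validated `hypnogram` tibble.
#' @export
validate_hypnogram <- function(x, lights_out = NULL, lights_on = NULL) {
  x <- as_tibble(x)
  miss <- setdiff(c("subject_id", "time", "stage"), names(x))
  if (length(miss) > 0) {
    abort(paste0("hypnogram is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "actiscore_format_error")
  }
  if (nrow(x) < 1) {
    abort("hypnogram must contain at least one epoch",
          class = "actiscore_validation_error")
  }
  bad <- which(!(x$stage %in% AASM_STAGES))
  if (length(bad) > 0) {
    abort(sprintf("unknown sleep stage '%s' at row %d", x$stage[bad[1]], bad[1]),
          class = "actiscore_validation_error")
  }
  if (nrow(x) >= 2) {
    dt <- as.numeric(diff(as.numeric(x$time)))
    off <- which(abs(dt - 30) > 1e-6)
    if (length(off) > 0) {
      abort(sprintf("non-30-s hypnogram spacing at %s",
                    format(x$time[off[1] + 1], "%Y-%m-%d %H:%M:%S")),
            class = "actiscore_gap_error")
    }
  }
  span <- c(x$time[1], x$time[nrow(x)] + 30)
  if (!is.null(lights_out) && !is.null(lights_on)) {
    if (!(lights_out < lights_on)) {
      abort("lights_out must precede lights_on",
            class = "actiscore_validation_error")
    }
  }
  for (m in list(lights_out = lights_out, lights_on = lights_on)) {
    if (!is.null(m) && (m < span[1] || m > span[2])) {
      abort("lights marker outside the recording span",
            class = "actiscore_validation_error")
    }
  }
  attr(x, "epoch_length_s") <- 30
  attr(x, "lights_out") <- lights_out
  attr(x, "lights_on") <- lights_on
  class(x) <- unique(c("hypnogram", class(x)))
  x
}

# Internal: tibble of sleep/wake labels with provenance attributes.
new_sleep_wake <- function(subject_id, time, label, epoch_length_s,
                           algorithm, params = list()) {
  x <- tibble(subject_id = as.character(subject_id), time = time,
              label = label)
  attr(x, "epoch_length_s") <- epoch_length_s
  attr(x, "algorithm") <- algorithm
  attr(x, "params") <- params
  class(x) <- unique(c("sleep_wake", class(x)))
  x
}
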
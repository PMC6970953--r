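# Timestamp helpers: ISO-8601, dot decimal, comma separation throughout.
format_ts <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")

parse_ts <- function(x, what = "timestamp") {
  x <- as.character(x)
  t <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")),
    error = function(e) NULL
  )
  if (is.null(t) || anyNA(t)) {
    # time-of-day only dialect: anchor on a reference date, rolling past
    # midnight when the clock goes backwards
    secs <- vapply(x, function(v) {
      tryCatch(parse_clock(v), error = function(e) NA_real_)
    }, numeric(1), USE.NAMES = FALSE)
    if (anyNA(secs)) {
      abort(sprintf("cannot parse %s '%s' at row %d", what,
                    x[which(is.na(secs))[1]], which(is.na(secs))[1]),
            class = "actiscore_format_error")
    }
    day <- cumsum(c(0, diff(secs) < 0)) * 86400
    t <- as.POSIXct("2000-01-01", tz = "UTC") + secs + day
  }
  t
}

#' Read an activity-count CSV
#'
#' Two dialects are supported. `"plain"`: comma-separated with columns
#' `timestamp` (ISO-8601 datetime or bare clock time) and `count` (or
#' `counts`). `"actilife"`: an export-style file with a metadata banner
#' (terminated by a line of dashes, or skipped explicitly via `skip`) followed
#' by comma-separated data in which the first `Axis1`-like column is taken as
#' the vertical axis; timestamps come from `Date`/`Time` (or
#' `Timestamp`) columns when present, otherwise from `Start Time`/`Start
#' Date`/`Epoch Period` banner fields. Gaps in the timestamp grid are
#' rejected, never imputed.
#'
#' @param path Path to the CSV file.
#' @param dialect `"plain"` or `"actilife"`.
#' @param subject_id,device,site Metadata labels for the resulting series.
#' @param epoch_length_s Epoch length in seconds; required for a single-row
#'   file or an ActiLife-style file without timestamps or banner epoch field.
#' @param skip For the ActiLife dialect: number of banner lines to skip
#'   instead of auto-detecting the dash separator.
#' @return An [epoch_series()].
#' @export
read_counts_csv <- function(path, dialect = c("plain", "actilife"),
                            subject_id = "S01", device = "actigraph",
                            site = "hip", epoch_length_s = NULL,
                            skip = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
          class = "actiscore_format_error")
  }
  if (dialect == "plain") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    names(df) <- tolower(names(df))
    cnt_col <- intersect(c("count", "counts"), names(df))
    if (!"timestamp" %in% names(df) || length(cnt_col) == 0) {
      miss <- if (!"timestamp" %in% names(df)) "timestamp" else "count"
      abort(sprintf("plain count CSV is missing column '%s'", miss),
            class = "actiscore_format_error")
    }
    time <- parse_ts(df$timestamp)
    count <- as.numeric(df[[cnt_col[1]]])
  } else {
    lines <- readLines(path, warn = FALSE)
    if (is.null(skip)) {
      sep <- grep("^-{4,}", lines)
      skip <- if (length(sep) > 0) sep[1] else 0L
    }
    banner <- if (skip > 0) lines[seq_len(skip)] else character()
    body <- lines[-seq_len(skip)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) {
      abort("ActiLife-style file has no data rows",
            class = "actiscore_format_error")
    }
    df <- readr::read_csv(I(paste(body, collapse = "\n")),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    axis_col <- grep("^axis ?1$", tolower(names(df)))
    if (length(axis_col) == 0) {
      abort("ActiLife-style file is missing an 'Axis1' column",
            class = "actiscore_format_error")
    }
    count <- as.numeric(df[[axis_col[1]]])
    lowern <- tolower(names(df))
    if ("timestamp" %in% lowern) {
      time <- parse_ts(df[[which(lowern == "timestamp")[1]]])
    } else if (all(c("date", "time") %in% lowern)) {
      time <- parse_ts(paste(df[[which(lowern == "date")[1]]],
                             df[[which(lowern == "time")[1]]]))
    } else {
      grab <- function(key) {
        hit <- grep(key, banner, ignore.case = TRUE, value = TRUE)
        if (length(hit) == 0) return(NULL)
        trimws(sub(paste0(".*", key, "[^0-9]*"), "", hit[1],
                   ignore.case = TRUE))
      }
      ep <- grab("Epoch Period")
      st <- grab("Start Time")
      sd_ <- grab("Start Date")
      if (!is.null(ep)) epoch_length_s <- epoch_length_s %||% parse_clock(ep)
      if (is.null(epoch_length_s)) {
        abort("cannot determine epoch length for ActiLife-style file",
              class = "actiscore_format_error")
      }
      t0 <- if (!is.null(st) && !is.null(sd_)) {
        d <- as.Date(sd_, tryFormats = c("%m/%d/%Y", "%Y-%m-%d", "%d/%m/%Y"))
        as.POSIXct(paste(d, st), tz = "UTC")
      } else {
        as.POSIXct("2000-01-01", tz = "UTC")
      }
      time <- t0 + (seq_along(count) - 1) * epoch_length_s
    }
  }
  if (anyNA(count)) {
    abort(sprintf("non-numeric count at row %d", which(is.na(count))[1]),
          class = "actiscore_validation_error")
  }
  validate_epoch_series(
    tibble(subject_id = subject_id, device = device, site = site,
           time = time, count = count),
    epoch_length_s = epoch_length_s
  )
}

#' Write an activity-count CSV (plain dialect)
#'
#' @param series An [epoch_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_csv <- function(series, path) {
  readr::write_csv(tibble(timestamp = format_ts(series$time),
                          count = series$count), path)
  invisible(path)
}

#' Read a hypnogram CSV
#'
#' Comma-separated rows `epoch_start,stage` with stages in `W`, `N1`, `N2`,
#' `N3`, `R` on a 30-s grid. Optional leading comment lines of the form
#' `# lights_out: <timestamp>` / `# lights_on: <timestamp>` carry the lights
#' markers.
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject label.
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, subject_id = "S01") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
          class = "actiscore_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  marker <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*[:=]"), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    parse_ts(trimws(sub(paste0("^#\\s*", key, "\\s*[:=]\\s*"), "", hit[1])))
  }
  body <- lines[!grepl("^#", lines)]
  df <- readr::read_csv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  names(df) <- tolower(names(df))
  if (!all(c("epoch_start", "stage") %in% names(df))) {
    abort("hypnogram CSV requires columns 'epoch_start' and 'stage'",
          class = "actiscore_format_error")
  }
  validate_hypnogram(
    tibble(subject_id = subject_id, time = parse_ts(df$epoch_start),
           stage = df$stage),
    lights_out = marker("lights_out"), lights_on = marker("lights_on")
  )
}

#' Write a hypnogram CSV
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hypnogram_csv <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("lights_out", "lights_on")) {
    m <- attr(h, key)
    if (!is.null(m)) writeLines(sprintf("# %s: %s", key, format_ts(m)), con)
  }
  writeLines("epoch_start,stage", con)
  writeLines(paste(format_ts(h$time), h$stage, sep = ","), con)
  invisible(path)
}

#' Write night-level sleep outcomes to CSV
#'
#' One row per subject, device, site and algorithm with the six outcome
#' variables; an empty collection yields a header-only file.
#'
#' @param outcomes Tibble of [sleep_outcomes()] rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  cols <- c("subject_id", "device", "site", "algorithm", "onset", "offset",
            "spt_min", "waso_min", "tst_min", "efficiency_pct")
  out <- as_tibble(outcomes)
  for (c_ in setdiff(cols, names(out))) out[[c_]] <- character()
  out <- out[, cols]
  out <- mutate(out, across(c("onset", "offset"), format_ts))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a sleep-outcomes CSV written by [write_outcomes_csv()]
#'
#' @param path Path to the CSV file.
#' @return A tibble with parsed timestamps and numeric outcomes.
#' @export
read_outcomes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) > 0) {
    df <- mutate(df, across(c("onset", "offset"), parse_ts))
  }
  df
}

#' Write a validation report to JSON
#'
#' Serialises the per-device/site validation blocks (confusion cells,
#' agreement statistics with CIs and the verbal PABAK band, Bland-Altman
#' statistics, paired-test results) at full double precision, so numeric
#' fields round-trip bit-identically.
#'
#' @param report A named list of report blocks (any JSON-representable
#'   structure of tibbles/lists).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  # I(17): 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, POSIXt = "ISO8601", na = "null")
  invisible(path)
}

#' Read a validation report written by [write_validation_report()]
#'
#' @param path Path to the JSON file.
#' @return The report as a list.
#' @export
read_validation_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
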
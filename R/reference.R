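#' Published epoch-by-epoch agreement table
#'
#' Summary statistics reported by a published validation study of hip- and
#' wrist-worn ActiGraph GT3X+ and Actical accelerometers against home
#' polysomnography in 28 school-age children: overall accuracy, sensitivity
#' (sleep agreement) and specificity (wake agreement) with 95% CIs, and the
#' published PABAK for each device/placement. Bundled so that the internal
#' arithmetic of such tables (e.g. `PABAK = 2 * p_o - 1` from the printed
#' accuracy) can be recomputed without access to the raw recordings, which
#' were never deposited. Note the published Actical-wrist row is arithmetically
#' inconsistent with the PABAK formula (accuracy 86.0 alongside PABAK 0.79);
#' the row is reproduced verbatim, not repaired.
#'
#' @return A tibble with one row per device and placement.
#' @export
reference_agreement <- function() {
  readr::read_csv(
    system.file("extdata", "reference_epoch_agreement.csv",
                package = "actiscore"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published night-level sleep-outcome means
#'
#' Per-method summary values (PSG, count-scaled ActiGraph and Actical at hip
#' and wrist) for the six sleep outcomes from the same published validation
#' study, together with the printed device-minus-PSG differences. Clock-time
#' centers are stored as `HH:MM` strings; durations in minutes; efficiency in
#' percent. Mean-summarised variables carry the printed mean difference;
#' median-summarised variables (WASO, efficiency) carry the printed median of
#' paired differences, which is not the difference of the printed medians.
#'
#' @return A tibble with columns `variable`, `tool`, `placement`, `n`,
#'   `summary_kind`, `center`, `delta_printed`.
#' @export
reference_outcomes <- function() {
  readr::read_csv(
    system.file("extdata", "reference_outcome_means.csv",
                package = "actiscore"),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(center = readr::col_character())
  )
}

# "20:37" -> minutes after midnight; plain numbers pass through.
center_to_minutes <- function(x) {
  vapply(as.character(x), function(v) {
    if (grepl(":", v, fixed = TRUE)) parse_clock(v) / 60 else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Device-minus-PSG differences from a published means table
#'
#' Recomputes, for every mean-summarised variable, the device-minus-PSG
#' difference implied by the per-method centers in [reference_outcomes()]
#' (clock times are converted to minutes after midnight first), alongside the
#' difference as printed. Median-summarised rows are excluded: a median of
#' paired differences cannot be recovered from group medians.
#'
#' @param ref A means table in the [reference_outcomes()] schema.
#' @return A tibble with `variable`, `tool`, `placement`, `n`, `delta_min`
#'   (recomputed) and `delta_printed`.
#' @export
outcome_mean_differences <- function(ref = reference_outcomes()) {
  ref <- mutate(ref, center_num = center_to_minutes(.data$center))
  psg <- ref |>
    filter(.data$tool == "psg") |>
    select("variable", psg_center = "center_num")
  ref |>
    filter(.data$tool != "psg", .data$summary_kind == "mean") |>
    left_join(psg, by = "variable") |>
    mutate(delta_min = .data$center_num - .data$psg_center) |>
    select("variable", "tool", "placement", "n", "delta_min", "delta_printed")
}
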
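#' Collapse 30-s PSG sleep/wake labels to 60-s epochs, wake winning
#'
#' Pairs of consecutive 30-s labels become one 1-min label that is wake if
#' either half was scored wake. Used when comparing the 1-min Sadeh scorer
#' with PSG at a shared resolution; a trailing unpaired epoch is dropped.
#'
#' @param labels A 30-s `sleep_wake` tibble.
#' @return A 60-s `sleep_wake` tibble.
#' @export
collapse_psg_to_60s <- function(labels) {
  if (epoch_length_s(labels) != 30) {
    abort("expected 30-s PSG labels", class = "actiscore_validation_error")
  }
  n_min <- floor(nrow(labels) / 2)
  idx <- seq_len(n_min * 2)
  grp <- rep(seq_len(n_min), each = 2)
  wake_any <- tapply(labels$label[idx] == "wake", grp, any)
  new_sleep_wake(
    subject_id = labels$subject_id[1],
    time = labels$time[seq(1, by = 2, length.out = n_min)],
    label = ifelse(as.vector(wake_any), "wake", "sleep"),
    epoch_length_s = 60, algorithm = "psg-60s", params = list()
  )
}

#' Score every night of a cohort
#'
#' Applies [score_night()] to each count series of a simulated (or assembled)
#' cohort and collects the night-level outcomes.
#'
#' @param cohort A [simulate_cohort()] result, or a tibble with columns
#'   `subject_id`, `device`, `site` and a list-column `series` of
#'   [epoch_series()].
#' @param config A [cs_config()].
#' @param algorithm `"count-scaled"` or `"sadeh"`.
#' @param sadeh A [sadeh_params()].
#' @return A tibble with the identifying columns, a list-column `night` of
#'   `scored_night` objects, and the [sleep_outcomes()] columns.
#' @export
score_cohort <- function(cohort, config = cs_config(),
                         algorithm = c("count-scaled", "sadeh"),
                         sadeh = sadeh_params()) {
  algorithm <- match.arg(algorithm)
  counts <- if (inherits(cohort, "sim_cohort")) cohort$counts else cohort
  nights <- purrr::map(counts$series, score_night, config = config,
                       algorithm = algorithm, sadeh = sadeh)
  out <- purrr::map_dfr(nights, sleep_outcomes)
  out$night <- nights
  out
}

#' Validate scored actigraphy against PSG across a cohort
#'
#' The full method-comparison pipeline. Per subject, device and site:
#' collapse the hypnogram to sleep/wake with PSG onset/offset, score the
#' count series, and (count-scaled scorer only, whose labels live on the
#' 15-s grid) align the two label streams epoch-by-epoch over the PSG span
#' and accumulate the confusion cells. Across subjects: pooled and
#' subject-level agreement statistics with PABAK, device-minus-PSG paired
#' tests (t-test, except the Wilcoxon signed-rank for the skewed WASO) and
#' Bland-Altman limits of agreement for TST and sleep efficiency.
#'
#' @param cohort A [simulate_cohort()] result or a counts tibble as in
#'   [score_cohort()].
#' @param hypnograms Named list of [hypnogram()] objects keyed by subject;
#'   defaults to the cohort's own.
#' @param config,algorithm,sadeh Passed to [score_night()].
#' @param min_psg_hours Exclude subjects with less than this many hours of
#'   PSG (NULL keeps everyone).
#' @param boot_seed Seed for the subject-level bootstrap CIs.
#' @return A list of class `cohort_validation`: `epoch` (per-subject
#'   confusion cells per device/site), `agreement` (pooled and subject-level
#'   statistics per device/site), `outcomes` (device and PSG outcomes per
#'   night), `comparison` (per device/site/variable paired tests and
#'   Bland-Altman rows).
#' @export
validate_cohort <- function(cohort, hypnograms = NULL, config = cs_config(),
                            algorithm = c("count-scaled", "sadeh"),
                            sadeh = sadeh_params(), min_psg_hours = NULL,
                            boot_seed = 1L) {
  algorithm <- match.arg(algorithm)
  hypnograms <- hypnograms %||%
    (if (inherits(cohort, "sim_cohort")) cohort$hypnograms else
      abort("hypnograms must be supplied",
            class = "actiscore_validation_error"))
  counts <- if (inherits(cohort, "sim_cohort")) cohort$counts else cohort

  psg <- purrr::map(hypnograms, collapse_hypnogram)
  psg_hours <- vapply(hypnograms, function(h) nrow(h) * 30 / 3600, numeric(1))
  keep <- names(psg)
  if (!is.null(min_psg_hours)) {
    keep <- names(psg)[psg_hours > min_psg_hours]
  }
  counts <- filter(counts, .data$subject_id %in% keep)

  scored <- score_cohort(counts, config = config, algorithm = algorithm,
                         sadeh = sadeh)
  psg_outcomes <- purrr::map_dfr(keep, function(sid) {
    p <- psg[[sid]]
    dplyr::bind_cols(
      tibble(subject_id = sid),
      compute_outcomes(p$labels, p$onset, p$offset,
                       waso_min_bout_min = config$waso_min_bout_min)
    )
  })

  epoch <- NULL
  agreement <- NULL
  if (algorithm == "count-scaled") {
    epoch <- purrr::map_dfr(seq_len(nrow(scored)), function(i) {
      night <- scored$night[[i]]
      p <- psg[[night$subject_id]]
      ct <- confusion_table(align_to_15s(p$labels, night$labels))
      dplyr::bind_cols(tibble(subject_id = night$subject_id,
                              device = night$device, site = night$site), ct)
    })
    agreement <- epoch |>
      group_by(.data$device, .data$site) |>
      dplyr::group_map(function(cells, key) {
        s <- per_subject_summary(cells, seed = boot_seed)
        list(device = key$device, site = key$site,
             pooled = s$pooled, subject_level = s$subject_level)
      })
  }

  dev_out <- select(scored, -"night")
  merged <- left_join(
    dev_out,
    dplyr::rename_with(psg_outcomes, ~ paste0("psg_", .x),
                       -"subject_id"),
    by = "subject_id"
  )
  # with a single usable subject a paired test or Bland-Altman is undefined;
  # report an explanatory row rather than failing the whole validation
  pt_safe <- function(x, y, method, variable) {
    res <- tryCatch(paired_tests(x, y, method),
                    actiscore_insufficient_data_error = function(e) {
                      tibble(method = method, statistic = NA_real_,
                             p_value = NA_real_, n = length(x),
                             note = "insufficient pairs")
                    })
    mutate(res, variable = variable)
  }
  ba_safe <- function(x, y) {
    tryCatch(bland_altman(x, y),
             actiscore_insufficient_data_error = function(e) {
               tibble(mean_diff = if (length(x)) mean(x - y) else NA_real_,
                      sd_diff = NA_real_, loa_low = NA_real_,
                      loa_high = NA_real_, n = length(x))
             })
  }
  comparison <- merged |>
    group_by(.data$device, .data$site) |>
    dplyr::group_map(function(g, key) {
      tests <- bind_rows(
        pt_safe(clock_minutes(g$onset), clock_minutes(g$psg_onset),
                "paired_t", "onset"),
        pt_safe(clock_minutes(g$offset), clock_minutes(g$psg_offset),
                "paired_t", "offset"),
        pt_safe(g$spt_min, g$psg_spt_min, "paired_t", "spt_min"),
        pt_safe(g$waso_min, g$psg_waso_min, "wilcoxon", "waso_min"),
        pt_safe(g$tst_min, g$psg_tst_min, "paired_t", "tst_min"),
        pt_safe(g$efficiency_pct, g$psg_efficiency_pct, "paired_t",
                "efficiency_pct")
      )
      ba <- list(
        tst_min = ba_safe(g$tst_min, g$psg_tst_min),
        efficiency_pct = ba_safe(g$efficiency_pct, g$psg_efficiency_pct)
      )
      list(device = key$device, site = key$site, tests = tests,
           bland_altman = ba)
    })

  structure(list(epoch = epoch, agreement = agreement,
                 outcomes = merged, comparison = comparison,
                 algorithm = algorithm, n_subjects = length(keep)),
            class = "cohort_validation")
}

# Minutes after the recording's first midnight, for paired clock-time tests.
clock_minutes <- function(t) {
  as.numeric(t - trunc(min(t), units = "days"), units = "mins")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("<cohort_validation> %s, %d subjects\n", x$algorithm,
              x$n_subjects))
  if (!is.null(x$agreement)) {
    for (a in x$agreement) {
      p <- a$pooled
      cat(sprintf(
        "  %s/%s: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, PABAK %.2f (%s)\n",
        a$device, a$site, p$accuracy_pct, p$sensitivity_pct,
        p$specificity_pct, p$pabak, p$agreement))
    }
  }
  invisible(x)
}

#' Serialisable form of a cohort validation
#'
#' Flattens a [validate_cohort()] result into plain lists/data frames for
#' [write_validation_report()], attaching the verbal agreement band to each
#' PABAK.
#'
#' @param v A `cohort_validation`.
#' @return A list suitable for JSON serialisation.
#' @export
validation_report <- function(v) {
  blocks <- list()
  combos <- unique(v$outcomes[, c("device", "site")])
  for (i in seq_len(nrow(combos))) {
    d <- combos$device[i]; s <- combos$site[i]
    block <- list(device = d, site = s, algorithm = v$algorithm)
    if (!is.null(v$agreement)) {
      a <- purrr::detect(v$agreement, ~ .x$device == d && .x$site == s)
      block$epoch_agreement <- list(
        pooled = as.list(a$pooled),
        subject_level = a$subject_level,
        confusion = filter(v$epoch, .data$device == d, .data$site == s)
      )
    }
    cmp <- purrr::detect(v$comparison, ~ .x$device == d && .x$site == s)
    block$paired_tests <- cmp$tests
    block$bland_altman <- purrr::map(cmp$bland_altman, as.list)
    blocks[[paste(d, s, sep = "_")]] <- block
  }
  list(algorithm = v$algorithm, n_subjects = v$n_subjects, blocks = blocks)
}
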
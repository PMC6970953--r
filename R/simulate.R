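#' Parameters of the synthetic night generator
#'
#' Describes the generative model of a paired actigraphy/PSG night: a bedtime
#' and a final morning wake drawn from truncated normal clock-time
#' distributions, a settling latency of quiet wake drawn from a lognormal,
#' wake-after-onset bouts with a Poisson count and exponential-tailed
#' durations, and state- and site-dependent count emission. All transition
#' times are rounded to whole minutes. The defaults emulate an overnight
#' recording from a school-age child cohort: bedtime around 20:15, settling
#' latency around 22 min, morning wake around 06:50, about two wake bouts per
#' night, and emission asymmetry in which the trunk lies still while the hands
#' still move during settling (so a hip device sees sleep earlier than a wrist
#' device) and the hands move more freely than the trunk during sleep.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param base_date Calendar date of the evening of the recording.
#' @param record_start,record_end Clock times bounding the recording
#'   (`record_end` falls on the next day).
#' @param bedtime_mean,bedtime_sd_min,bedtime_range Bedtime distribution:
#'   mean clock time, SD in minutes, truncation range (clock times).
#' @param latency_mean_min,latency_sd_min,latency_range_min Settling-latency
#'   lognormal: mean and SD in minutes and a clamp range.
#' @param offset_mean,offset_sd_min,offset_range Final-wake distribution,
#'   as for bedtime.
#' @param waso_bout_rate Mean number of wake bouts per night (Poisson).
#' @param waso_bout_mean_min,waso_bout_min_min Mean and minimum bout duration
#'   in minutes (exponential above the minimum).
#' @param waso_edge_gap_min Minimum gap between a bout and the sleep-period
#'   edges, and between bouts.
#' @param waso_latest_start Latest clock time at which a bout may start.
#' @param emission Nested list `emission[[state]][[site]]` for states
#'   `active_wake`, `settling`, `waso`, `sleep` and sites `hip`, `wrist`;
#'   each entry either `list(mu, size, zero_prob)` for a zero-inflated
#'   negative-binomial per-15-s count or `list(constant = c)` for a
#'   deterministic emission.
#' @param seed Integer seed; per-subject substreams are derived from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 28L,
                       base_date = "2024-03-01",
                       record_start = "19:00", record_end = "08:00",
                       bedtime_mean = "20:15", bedtime_sd_min = 25,
                       bedtime_range = c("19:40", "21:15"),
                       latency_mean_min = 22, latency_sd_min = 12,
                       latency_range_min = c(6, 45),
                       offset_mean = "06:50", offset_sd_min = 25,
                       offset_range = c("05:45", "07:45"),
                       waso_bout_rate = 2, waso_bout_mean_min = 8,
                       waso_bout_min_min = 1,
                       waso_edge_gap_min = 20,
                       waso_latest_start = "05:40",
                       emission = default_emissions(),
                       seed = 42L) {
  stopifnot(n_subjects >= 1, bedtime_sd_min >= 0, latency_mean_min >= 0,
            offset_sd_min >= 0, waso_bout_rate >= 0,
            waso_bout_mean_min >= waso_bout_min_min, waso_bout_min_min >= 0)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

#' Default state- and site-dependent emission parameters
#'
#' Per-15-s activity counts are zero-inflated negative binomial given state
#' and site. Active wake moves both sites hard; during settling the hip
#' (trunk) is mostly still while the wrist keeps moving; during sleep both are
#' mostly zero, the wrist with a slightly higher movement-burst probability.
#'
#' @return Nested emission list, see [sim_params()].
#' @export
default_emissions <- function() {
  list(
    active_wake = list(hip = list(mu = 300, size = 3, zero_prob = 0.05),
                       wrist = list(mu = 300, size = 3, zero_prob = 0.05)),
    settling = list(hip = list(mu = 50, size = 2, zero_prob = 0.85),
                    wrist = list(mu = 250, size = 3, zero_prob = 0.2)),
    waso = list(hip = list(mu = 300, size = 3, zero_prob = 0.05),
                wrist = list(mu = 300, size = 3, zero_prob = 0.05)),
    sleep = list(hip = list(mu = 30, size = 1, zero_prob = 0.98),
                 wrist = list(mu = 60, size = 1, zero_prob = 0.92))
  )
}

#' Preset simulation scenarios
#'
#' Three scenarios used throughout the package: `"default"`, the realistic
#' child-cohort night of [sim_params()]; `"noise-free"`, deterministic
#' constant emissions (wake states emit a constant count, sleep emits exactly
#' zero) with minute-aligned, well-separated wake bouts of at least 5 min, so
#' that scorer error is attributable to the scorer alone; and
#' `"restless-wrist"`, the default night with bursty wrist movement during
#' sleep.
#'
#' @param scenario Scenario name.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
scenario_params <- function(scenario = c("default", "noise-free",
                                         "restless-wrist"), ...) {
  scenario <- match.arg(scenario)
  over <- list(...)
  base <- switch(scenario,
    "default" = list(),
    "noise-free" = {
      const_wake <- list(constant = 100)
      list(
        emission = list(
          active_wake = list(hip = const_wake, wrist = const_wake),
          settling = list(hip = const_wake, wrist = const_wake),
          waso = list(hip = const_wake, wrist = const_wake),
          sleep = list(hip = list(constant = 0), wrist = list(constant = 0))
        ),
        waso_bout_min_min = 5, waso_bout_mean_min = 10
      )
    },
    "restless-wrist" = {
      em <- default_emissions()
      em$sleep$wrist <- list(mu = 150, size = 1, zero_prob = 0.5)
      list(emission = em)
    }
  )
  do.call(sim_params, utils::modifyList(base, over))
}

# Clock helpers on the simulated night's date line.
sim_datetime <- function(base_date, clock, next_day = FALSE) {
  as.POSIXct(paste(base_date, "00:00:00"), tz = "UTC") +
    parse_clock(clock) + if (next_day) 86400 else 0
}

rtruncnorm1 <- function(mean, sd, lo, hi, what = "value") {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  abort(sprintf("could not sample %s within its truncation range", what),
        class = "actiscore_infeasible_error")
}

#' Sample the latent structure of one night
#'
#' Draws bedtime, settling latency (hence true sleep onset), final wake and
#' disjoint wake-after-onset bouts. Bouts keep `waso_edge_gap_min` minutes
#' clear of the sleep-period edges and of each other and start no later than
#' `waso_latest_start`, so a night is always a well-formed
#' settle/sleep/bout/wake sequence; infeasible parameter combinations raise an
#' error after 1000 rejection attempts.
#'
#' @param params A [sim_params()].
#' @return A list of class `night_structure`: `bedtime`, `settle_end` (true
#'   onset), `waso_bouts` (tibble `start`, `duration_min`), `final_wake`
#'   (true offset).
#' @export
sample_night_structure <- function(params) {
  base <- params$base_date
  bed_lo <- sim_datetime(base, params$bedtime_range[1])
  bed_hi <- sim_datetime(base, params$bedtime_range[2])
  bed_mu <- sim_datetime(base, params$bedtime_mean)
  bedtime <- round_minute(bed_mu + 60 * rtruncnorm1(0, params$bedtime_sd_min,
    as.numeric(bed_lo - bed_mu, units = "secs") / 60,
    as.numeric(bed_hi - bed_mu, units = "secs") / 60, "bedtime"))
  lat_mean <- params$latency_mean_min
  lat <- if (lat_mean <= 0) 0 else {
    cv <- params$latency_sd_min / lat_mean
    sdl <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, log(lat_mean) - sdl^2 / 2, sdl)
  }
  lat <- round(min(max(lat, params$latency_range_min[1]),
                   params$latency_range_min[2]))
  settle_end <- bedtime + 60 * lat
  off_lo <- sim_datetime(base, params$offset_range[1], next_day = TRUE)
  off_hi <- sim_datetime(base, params$offset_range[2], next_day = TRUE)
  off_mu <- sim_datetime(base, params$offset_mean, next_day = TRUE)
  final_wake <- round_minute(off_mu + 60 * rtruncnorm1(0, params$offset_sd_min,
    as.numeric(off_lo - off_mu, units = "secs") / 60,
    as.numeric(off_hi - off_mu, units = "secs") / 60, "final wake"))
  opportunity <- as.numeric(final_wake - settle_end, units = "mins")
  if (opportunity <= 2 * params$waso_edge_gap_min) {
    abort("settling latency leaves no sleep opportunity",
          class = "actiscore_infeasible_error")
  }
  n_bouts <- rpois(1, params$waso_bout_rate)
  bouts <- tibble(start = settle_end[0], duration_min = numeric())
  latest <- sim_datetime(base, params$waso_latest_start, next_day = TRUE)
  gap <- params$waso_edge_gap_min
  for (b in seq_len(n_bouts)) {
    dur <- round(params$waso_bout_min_min +
                   rexp(1, 1 / max(params$waso_bout_mean_min -
                                     params$waso_bout_min_min, 0.5)))
    dur <- max(dur, params$waso_bout_min_min, 1)
    placed <- FALSE
    for (try in 1:1000) {
      lo <- settle_end + 60 * gap
      hi <- min(final_wake - 60 * (gap + dur), latest)
      if (hi <= lo) break
      start <- round_minute(lo + runif(1) * as.numeric(hi - lo, units = "secs"))
      end <- start + 60 * dur
      ok <- nrow(bouts) == 0 ||
        all(start >= bouts$start + 60 * (bouts$duration_min + gap) |
              end <= bouts$start - 60 * gap)
      if (ok) {
        bouts <- bind_rows(bouts, tibble(start = start, duration_min = dur))
        placed <- TRUE
        break
      }
    }
    if (!placed && n_bouts > 0) {
      abort("could not place a wake bout within the sleep period",
            class = "actiscore_infeasible_error")
    }
  }
  bouts <- arrange(bouts, .data$start)
  structure(list(bedtime = bedtime, settle_end = settle_end,
                 waso_bouts = bouts, final_wake = final_wake),
            class = "night_structure")
}

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, tz = "UTC",
             origin = "1970-01-01")
}

# State of each epoch start time under a night structure.
night_state <- function(night, t) {
  state <- rep("active_wake", length(t))
  in_bed <- t >= night$bedtime & t < night$final_wake
  state[in_bed & t < night$settle_end] <- "settling"
  state[in_bed & t >= night$settle_end] <- "sleep"
  if (nrow(night$waso_bouts) > 0) {
    for (b in seq_len(nrow(night$waso_bouts))) {
      s <- night$waso_bouts$start[b]
      e <- s + 60 * night$waso_bouts$duration_min[b]
      state[t >= s & t < e] <- "waso"
    }
  }
  state
}

#' Render a night structure as a 30-s hypnogram
#'
#' Wake outside the true sleep period and inside wake bouts; sleep epochs are
#' assigned a repeating N1-N2-N3-N2-R cycle (cosmetic: the stages collapse
#' back to sleep). The bedtime is stored as the lights-out marker.
#'
#' @param night A [sample_night_structure()] result.
#' @param params A [sim_params()] (provides the recording span and date).
#' @param subject_id Subject label.
#' @return A [hypnogram()] spanning the recording.
#' @export
structure_to_hypnogram <- function(night, params, subject_id = "S01") {
  t0 <- sim_datetime(params$base_date, params$record_start)
  t1 <- sim_datetime(params$base_date, params$record_end, next_day = TRUE)
  times <- seq(t0, t1 - 30, by = 30)
  state <- night_state(night, times)
  stage <- rep("W", length(times))
  is_sleep <- state == "sleep"
  cycle <- c("N1", "N2", "N3", "N2", "R")
  stage[is_sleep] <- rep_len(rep(cycle, each = 10), sum(is_sleep))
  hypnogram(times, stage, subject_id = subject_id,
            lights_out = night$bedtime)
}

#' Emit a 15-s device count series for a night
#'
#' Per-epoch counts are conditionally independent given the latent state and
#' the wear site: `list(mu, size, zero_prob)` entries draw zero with
#' probability `zero_prob` and otherwise a negative binomial with mean `mu`
#' and dispersion `size`; `list(constant = c)` entries emit `c` exactly.
#'
#' @param night A [sample_night_structure()] result.
#' @param params A [sim_params()].
#' @param site `"hip"` or `"wrist"`.
#' @param device Device label (tags the series; the emission model is chosen
#'   by state and site).
#' @param subject_id Subject label.
#' @return A 15-s [epoch_series()] spanning the recording.
#' @export
emit_counts <- function(night, params, site = c("hip", "wrist"),
                        device = "actigraph", subject_id = "S01") {
  site <- match.arg(site)
  t0 <- sim_datetime(params$base_date, params$record_start)
  t1 <- sim_datetime(params$base_date, params$record_end, next_day = TRUE)
  times <- seq(t0, t1 - 15, by = 15)
  state <- night_state(night, times)
  counts <- numeric(length(times))
  for (st in unique(state)) {
    e <- params$emission[[st]][[site]]
    idx <- which(state == st)
    if (!is.null(e$constant)) {
      counts[idx] <- e$constant
    } else {
      nz <- rbinom(length(idx), 1, 1 - e$zero_prob)
      counts[idx] <- nz * rnbinom(length(idx), size = e$size, mu = e$mu)
    }
  }
  epoch_series(times, counts, subject_id = subject_id, device = device,
               site = site)
}

#' True sleep outcomes of a night structure
#'
#' Outcomes computed from the generative truth (not from re-scored data), so
#' scorer recovery error is attributable to the scorer alone.
#'
#' @param night A [sample_night_structure()] result.
#' @return A one-row tibble in the [compute_outcomes()] schema.
#' @export
truth_outcomes <- function(night) {
  spt <- as.numeric(night$final_wake - night$settle_end, units = "mins")
  waso <- sum(night$waso_bouts$duration_min)
  tibble(onset = night$settle_end, offset = night$final_wake,
         spt_min = spt, waso_min = waso, tst_min = spt - waso,
         efficiency_pct = 100 * (spt - waso) / spt)
}

#' Simulate a cohort of paired actigraphy/PSG nights
#'
#' Draws `n_subjects` independent nights from one seeded stream (per-subject
#' substreams are derived deterministically from `params$seed`, so partial
#' regeneration is reproducible) and emits, per subject, a hypnogram and four
#' count series (devices `actigraph` and `actical` at hip and wrist; the
#' device label only tags the emission parameter set).
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_cohort`: `truth` (per-subject true outcomes),
#'   `hypnograms` (named list), `counts` (tibble with list-column `series`),
#'   and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  subjects <- sprintf("S%02d", seq_len(params$n_subjects))
  truth <- vector("list", params$n_subjects)
  hyps <- vector("list", params$n_subjects)
  counts <- vector("list", params$n_subjects)
  for (i in seq_len(params$n_subjects)) {
    withr::with_seed(as.integer(params$seed + 7919 * i), {
      night <- sample_night_structure(params)
      hyps[[i]] <- structure_to_hypnogram(night, params, subjects[i])
      grid <- expand.grid(device = c("actigraph", "actical"),
                          site = c("hip", "wrist"),
                          stringsAsFactors = FALSE)
      counts[[i]] <- tibble(
        subject_id = subjects[i], device = grid$device, site = grid$site,
        series = purrr::map2(grid$device, grid$site, function(d, s) {
          emit_counts(night, params, site = s, device = d,
                      subject_id = subjects[i])
        })
      )
      truth[[i]] <- dplyr::bind_cols(tibble(subject_id = subjects[i]),
                                     truth_outcomes(night))
    })
  }
  names(hyps) <- subjects
  structure(list(truth = bind_rows(truth), hypnograms = hyps,
                 counts = bind_rows(counts), params = params),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects, %d count series, seed %d\n",
              nrow(x$truth), nrow(x$counts), x$params$seed))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Per subject: one plain-dialect count CSV per device and site and one
#' hypnogram CSV; plus a truth-outcomes CSV and a JSON manifest listing every
#' written file with the generating seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_len(nrow(cohort$counts))) {
    row <- cohort$counts[i, ]
    f <- file.path(dir, sprintf("%s_%s_%s_counts.csv", row$subject_id,
                                row$device, row$site))
    write_counts_csv(row$series[[1]], f)
    files <- c(files, f)
  }
  for (sid in names(cohort$hypnograms)) {
    f <- file.path(dir, sprintf("%s_hypnogram.csv", sid))
    write_hypnogram_csv(cohort$hypnograms[[sid]], f)
    files <- c(files, f)
  }
  truth_f <- file.path(dir, "truth_outcomes.csv")
  readr::write_csv(mutate(cohort$truth, across(c("onset", "offset"),
                                               format_ts)), truth_f)
  files <- c(files, truth_f)
  manifest <- list(seed = cohort$params$seed,
                   n_subjects = cohort$params$n_subjects,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
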
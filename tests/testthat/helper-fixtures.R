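# Shared fixtures and independent oracles. Oracles deliberately use naive
# element-wise loops so they stay independent of the vectorised package code.

T0 <- as.POSIXct("2024-03-01 20:00:00", tz = "UTC")

mk_series <- function(counts, epoch = 15, start = T0, subject = "S01",
                      device = "actigraph", site = "hip") {
  epoch_series(start + (seq_along(counts) - 1) * epoch, counts,
               subject_id = subject, device = device, site = site)
}

mk_labels <- function(labels, epoch = 60, start = T0, subject = "S01") {
  actiscore:::new_sleep_wake(subject, start + (seq_along(labels) - 1) * epoch,
                             labels, epoch, "manual")
}

# Compact run-length shorthand: lab_seq(5, "wake", 15, "sleep") -> 20 labels.
lab_seq <- function(...) {
  a <- list(...)
  unlist(purrr::map2(a[seq(1, length(a), 2)], a[seq(2, length(a), 2)],
                     function(n, l) rep(l, n)))
}

# Brute-force event scan: tests every index against the run-length
# definitions verbatim.
brute_events <- function(labels, sleep_run = 15, wake_run = 5) {
  s <- labels == "sleep"
  n <- length(s)
  onsets <- integer()
  wakes <- integer()
  for (i in seq_len(n)) {
    if (i - wake_run >= 1 && i + sleep_run - 1 <= n &&
        all(s[i:(i + sleep_run - 1)]) && all(!s[(i - wake_run):(i - 1)])) {
      onsets <- c(onsets, i - 1L)
    }
    if (i - sleep_run + 1 >= 1 && i + wake_run <= n &&
        all(s[(i - sleep_run + 1):i]) && all(!s[(i + 1):(i + wake_run)])) {
      wakes <- c(wakes, i - 1L)
    }
  }
  list(onset = onsets, wake = wakes)
}

# Naive scalar Sadeh index with explicit index sets.
naive_sadeh <- function(x, p = sadeh_params()) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    win <- max(1, t - p$window_half_width_min):min(n, t + p$window_half_width_min)
    mu <- mean(x[win])
    nat <- sum(x[win] >= 50 & x[win] < 100)
    sig_win <- max(1, t - (p$sigma_lookback_min - 1)):t
    sigma <- if (length(sig_win) < 2) 0 else sd(x[sig_win])
    p$intercept + p$coef_mu * mu + p$coef_nat * nat +
      p$coef_sigma * sigma + p$coef_logact * log(x[t] + 1)
  }, numeric(1))
}
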
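---
title: "Methods: count-scaled sleep-wake scoring and PSG validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-scaled sleep-wake scoring and PSG validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiscore)
```

## The model

Actigraphic sleep scoring treats per-epoch movement counts as a noisy,
indirect readout of a latent sleep/wake state. Two families of scorers are
implemented.

The **count-scaled** scorer makes one structural assumption: the *relative*
movement level within a recording is informative even though the absolute
count scale differs by device, firmware and wear site. Each recording is
therefore normalised by the mean of its non-zero minute values before any
threshold is applied, which is what lets a single threshold of 1 serve hip
and wrist, ActiGraph and Actical alike. Classification is a weighted sum over
a 7-minute window (4 minutes back, the current minute, 2 minutes forward)
compared against that threshold, with "below threshold" meaning sleep.
Onset and offset are not read off the raw label sequence but off *events*
that require sustained state runs (15 min of sleep adjacent to 5 min of
wake), searched around user-supplied clock anchors: 3 h forward from the
bedtime flag, then 2 h backward, then the flag itself as a fallback. The
defaults (19:30 and 06:00) suit early-school-age children and are plain
parameters for any other population.

The **Sadeh** comparator is the standard per-minute linear index
`SI = 7.601 − 0.065·μ − 1.08·nat − 0.056·σ − 0.703·ln(a_t + 1)` with sleep
scored when `SI ≥ 0`. The published description of the study context names
these variables but the printed equation itself is not recoverable from the
available text, so the coefficients are exposed in `sadeh_params()` with the
1994 literature values as defaults, together with the conventional 300-count
cap. If a particular deployment used a variant coefficient set, supplying it
reproduces that deployment exactly.

Night-level outcomes follow the standard definitions on the scored interval:
`SPT = offset − onset`, `WASO` the wake minutes strictly inside it,
`TST = SPT − WASO`, `efficiency = 100·TST/SPT`. The implementation keeps the
identity `SE = 100·TST/SPT`; a table footnote of the form
`(TST − WASO)/SPT` sometimes seen in print is internally inconsistent (TST
already excludes WASO) and is deliberately not implemented.

## The classification weights

The window weights are the one place where this package had to make a
substantive choice. A uniform `1/7` vector (a plain moving average) has a
structural defect at state boundaries: once counts are scaled so that a
typical wake minute sits at 1, any window containing even one quiet minute
averages below 1, so the last two wake minutes before a genuine sleep onset
are absorbed into sleep and the sleep period is extended three to four
minutes past the true offset — for *any* emission level, because the scaling
pins sustained wake at exactly the threshold. No constant vector of equal
weights can recover a sharp transition to the minute.

The default weights `(0.1, 0.1, 0.1, 0.1, 0.8, 0.15, 0.15)` fix this while
remaining a genuine smoother:

* the current minute carries 0.8, so a minute of average wake movement
  flanked by any further movement reaches the threshold (0.8 + ≥ 0.2) and
  stays wake;
* the preceding window sums to 0.4 < 1 and the following window to 0.3 < 1,
  so the first quiet minute after sustained movement already scores sleep,
  and the last quiet minute before morning movement stays asleep;
* an *isolated* movement burst (0.8 alone) does not by itself break sleep,
  preserving the smoothing role of the window.

With these weights the scorer reproduces state transitions exactly on
noiseless input, which is what makes the parameter-recovery tests sharp
(± 1 min). `weights = rep(1/7, 7)` remains available, and the weight vector
is recorded in every scored night's provenance.

## Numerical and edge-case conventions

* **Edges.** Where the 7-min window runs off the recording, the surviving
  weights are renormalised to the full-window weight sum; padding would bias
  edge minutes toward sleep. Sadeh windows truncate without renormalisation
  (the index is a regression, not an average); σ over fewer than two minutes
  is 0.
* **All-zero recordings** scale by 1 (the mean of an empty set is
  undefined; identity is the only neutral choice), score all-sleep, and fall
  back to both flags for onset and offset.
* **Strictness.** The sleep condition is strictly `< threshold`, so constant
  scaled activity of exactly 1 scores wake everywhere.
* **Flag searches** use a closed forward window and a half-open backward
  window `[flag − 2 h, flag)`, so an event exactly at the flag is matched by
  the forward pass only and can never double-match.
* **Event timestamps.** Onset events carry the start of their minute; wake
  events the end of theirs (the first wake minute), so a sleep period that
  truly ends at 06:30 yields offset 06:30, not 06:29.
* **Resolutions.** Classification is per minute (the algorithm is defined in
  minutes) and labels are broadcast back to the native 15-s epochs for
  epoch-by-epoch comparison, where each PSG 30-s epoch is split into two
  15-s epochs. Scaling is by the mean non-zero *minute* by default;
  `scaling_resolution = "epoch"` scales at the native resolution instead,
  since "non-zero epochs" is ambiguous once resolutions differ. The Sadeh
  scorer stays at 60 s and is compared with PSG at outcome level only; for
  any shared-grid comparison `collapse_psg_to_60s()` collapses PSG minutes
  with wake winning.
* **WASO** counts every wake epoch between onset and offset by default
  (`waso_min_bout_min = 1`); setting 5 gives the consecutive-awakenings
  convention used in parts of the field. Quantiles for median (IQR)
  summaries use linear interpolation (type 7); a single-value SD is reported
  as 0 with `n = 1` visible rather than as a missing value.
* **Tests and intervals.** The Wilcoxon signed-rank drops zero differences
  and uses the normal approximation with continuity correction; all-zero
  differences return p = 1 with an explicit note. PABAK intervals are normal
  approximations on the observed agreement, transformed and clipped to
  `[−1, 1]`; sensitivity/specificity/accuracy additionally get subject-level
  bootstrap percentile intervals (default 2000 resamples, seeded), because
  published agreement tables rarely say whether their intervals are pooled
  or subject-level — both are reported.
* **Published-table arithmetic.** The bundled reference tables reproduce a
  published validation study's summary rows verbatim, including one
  internally inconsistent row (Actical wrist: accuracy 86.0 alongside PABAK
  0.79, impossible under PABAK = 2·p₀ − 1). The package follows the formula
  and documents the discrepancy rather than emulating it. Recomputed
  device-minus-PSG differences agree with the printed ones only for
  complete-pair rows; where a device has fewer usable nights than PSG the
  printed difference is over complete pairs and cannot be recovered from
  group means.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws, per child: a bedtime (truncated normal around
20:15), a lognormal settling latency (~22 min) of quiet wake, Poisson wake
bouts with exponential-tailed durations inside the sleep period, and a
truncated-normal final wake (~06:50), all rounded to whole minutes. Counts
are then emitted per 15-s epoch conditionally on the latent state and wear
site: zero-inflated negative binomials whose defaults encode the placement
asymmetry that motivates hip/wrist comparisons — during settling the trunk
is still (hip mostly zeros) while the hands keep moving (wrist near wake
level), and during sleep the wrist bursts slightly more often than the hip.
Truth outcomes come from the generative structure itself, never from
re-scored data, so recovery error is attributable to the scorer alone.

Three presets are fixed: `"default"` (above, 28 subjects — the cohort size
of the motivating study), `"noise-free"` (deterministic constant emissions,
wake bouts of at least 5 min kept 20 min clear of the period edges and of
each other and starting before 05:40, i.e. a clean well-separated night on
which an exact scorer should be exact), and `"restless-wrist"` (bursty wrist
movement during sleep, which inflates wrist WASO).

The generator deliberately omits: autocorrelated movement bouts (emissions
are conditionally independent given state; a bout-duration hook is left in
the parameter map), realistic stage dynamics (the N1–N2–N3–N2–R cycle is
cosmetic and collapses to sleep), circadian structure beyond one night, naps,
non-wear, and device noise floors. Passing recovery tests therefore shows
the scorer implements its stated rules exactly and behaves sensibly under
the modelled placement asymmetry — not that it attains any particular
accuracy on field recordings, whose agreement statistics are systematically
lower than on synthetic nights.

## Problem sizes

The shipped tests run the oracle-equivalence suites at 1000 random label
sequences (≤ 500 min) and 100 random count series, parameter recovery at 20
noise-free nights, the placement sign test at 50 nights, and the
Bland–Altman coverage check at 10 000 seeded normal differences — sizes at
which every Monte-Carlo check is stable at its stated tolerance while the
whole suite stays interactive (< 1 min).

## Known limitations

* The weight vector of the originally published count-scaled implementation
  is not public; the default here is this package's own boundary-exact
  choice, so absolute agreement with that implementation on noisy data is
  not guaranteed (provenance records the weights used).
* Whether the offset search mirrors the onset search exactly
  (forward-then-backward) is a documented interpretation, as is locating
  Sadeh onset/offset with the same event-and-flag machinery.
* The automated mode computes no sleep latency (there is no lights-out
  marker in a device-only workflow) and detects no daytime naps.
* Epoch-level inference treats epochs as exchangeable; no cluster-robust or
  mixed-effects correction is applied to the epoch-by-epoch statistics, and
  no multiplicity correction to the outcome tests.
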
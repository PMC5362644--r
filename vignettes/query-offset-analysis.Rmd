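---
title: "Methods: within-song timing analysis of audio identification queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-song timing analysis of audio identification queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(querytiming)
```

## The problem

An audio identification query records two facts this package cares about:
the *offset* — the second of the matched track at which the user initiated
the query — and the calendar day of the query. Offsets concentrate where
musical content compels listeners to act (typically a few seconds *after*
the compelling moment, because retrieving and unlocking a device takes
time), and the shape of the offset distribution changes as a song moves
from release through chart peak to the end of its run. The package provides
the full chain from raw per-song CSV logs to the statistical summaries of
these phenomena, plus a generator of synthetic logs with the same structure
so every stage can be validated end to end.

## Data model and cleaning

A usable record has both fields present and an offset in `(0, L]` for track
length `L`: an offset of exactly zero is treated as a failed measurement
(removed), an offset exactly at the track end is legitimate (kept). Records
dated before the release date are *retained*: a single's listed release may
postdate the album that contains it, so early queries are genuine.
`clean_queries()` is order-preserving and idempotent, and its report always
reconciles (`usable + missing + out-of-range = input`).

Offsets are stored in the CSV dialect at six decimal places
(sub-millisecond precision). The generator canonicalizes its offsets to the
same precision, which makes write/read round trips bit-exact and — exactly
as in real logs at this scale — produces occasional exact ties, which is
why the uniformity stage perturbs.

## The synthetic generator

`simulate_song_queries()` draws each offset from a mixture on `(0, L]`:

* a **baseline** with density proportional to `exp(-r t)`, truncated to the
  track (default `r = 0.02` s⁻¹, so baseline mass concentrates in roughly
  the first minute — the overall downward trend of real offset histograms,
  driven by listeners who only need to query a song once);
* one **burst per musical event** (song start, first vocals, first chorus;
  default weights 0.15 / 0.20 / 0.15, leaving 0.5 for the baseline), at
  `onset + latency`;
* an **intent-to-query latency** distributed as
  `mode + Exp(1/spread)` (defaults: mode 9 s, spread 3 s) — a deterministic
  floor at the most probable retrieve-unlock-launch time followed by an
  exponential tail of slower reactions. The density is maximal at the mode
  and right-skewed. The sharp onset is deliberate: it is what makes the
  latency mode *identifiable* from histogram slopes. A smooth bump (e.g. a
  gamma density with interior mode) has its steepest rise at an inflection
  point several seconds before its mode, so no slope-based readout could
  ever localize the mode itself; a density that jumps to its maximum rises
  steepest exactly at the mode, and the slope estimator recovers it to the
  grid resolution.

Dates come from three life-cycle phases — release (`[release, peak)`),
peak (`[peak, midpoint)`), and end (`[midpoint, end-of-observation]`) —
with default phase fractions 0.25 / 0.45 / 0.30 (query volume is largest
around the chart peak). Default anchors place the peak 127 days after
release and the end of observation 374 days after the peak, typical spans
for year-end chart hits. The **life-cycle drift** multiplies the offset
density in a phase with exposure `g` (release 0, peak ½, end 1) by
`exp(-λ g t / L)` and renormalizes; `λ` is `drift_strength` (default 2, a
clearly visible shift; 0 disables drift). Sampling uses exact rejection
against the taper, so the drawn law is the renormalized tilted density, not
an approximation.

What the generator does *not* emulate: repeated structural sections (second
choruses, bridges), per-user behavior and repeat queries, geography and
time-of-day structure, platform artifacts such as pre-recording offsets, or
any coupling between a song's musical content and its popularity
trajectory. Passing tests therefore validate the *statistical machinery*
under the assumed event-locked mixture structure — they do not certify
conclusions about any real catalog.

## Uniformity stage

`ks_uniformity_test()` compares offsets with Uniform(0, L) by a two-sided
Kolmogorov–Smirnov test. Ties from the six-decimal storage precision are
broken first by adding i.i.d. Uniform[−5·10⁻⁶, +5·10⁻⁶] perturbations;
perturbed values are clamped back to `(0, L]` rather than discarded (bias
at most 5·10⁻⁶ s, preserving the sample size and support). The p-value is
the asymptotic approximation — intended sample sizes are 10³–10⁶, where
exact computation is both infeasible and unnecessary. No multiple-testing
correction is applied across songs.

## Life-cycle proportion sweep

`select_phase_subsets()` takes the first `k` events dated on/after release,
the first `k` on/after the chart peak, and the last `k` by date (default
`k` = 100,000). Dates are day-resolved, so within a day the stable input
order is used, with an optional seeded shuffle; the release and peak
subsets may legitimately overlap when a song peaks quickly, and an overlap
of release and end subsets triggers a warning since it means the phases are
not distinct.

For each integer beginning-window length `d_b`, `proportion_sweep()` tests
whether the later sample has a larger share of offsets in `[0, d_b)` than
the earlier one, using the pooled two-sample χ² statistic with Yates
continuity correction by default (matching the default of `prop.test()`,
the likely tool of the original computation); `correct = FALSE` gives the
textbook statistic, which is zero exactly when the sample proportions
coincide — the implementation computes the `|O − E|` deviation as
`|a·n₂ − b·n₁|/(n₁+n₂)` in integer arithmetic so this identity holds
exactly. One-sided p-values come from the signed normal root of the
statistic; degenerate windows (both samples entirely inside or outside)
report statistic 0 and p = 0.5. Because p-values at these sample sizes are
uninformatively small, cross-song reporting uses within-song *percentiles*
of the χ² values (average-rank convention), aggregated as median/quartile
curves over songs whose length reaches each `d_b`, plus a raster of windows
with `p < 10⁻¹⁰` — a threshold conservative enough to stand in for a formal
multiplicity correction across the several-thousand tests of a corpus
sweep.

## Event-locked slope profiles

Offsets (by default the first 1,000,000 queries by date, taken before the
life-cycle drift dominates) are binned at 1 s; `estimate_slopes()` fits a
degree-1 local polynomial (local linear regression, tricube weights) to the
per-bin probability mass and reports the fitted derivative at every whole
second. Local linear fits reproduce linear densities exactly, including at
the boundaries, which fixes the estimator's behavior on the flat and ramp
segments that dominate these histograms.

The **bandwidth default is 3 s**. This is a deliberate, load-bearing
choice: the quantity of interest is the *location* of slope maxima relative
to event onsets at 1-s resolution. A wide kernel (say 10 s) averages the
derivative over its whole support, and for a sharp event-locked rise the
resulting maximum sits 2–4 s before the true rise — wide enough to swallow
the effect being measured. At 3 s the estimate still pools three to six
bins per grid point, but a jump-onset burst's slope maximum lands on the
onset second itself (verified against exact binned densities during
development). The bandwidth is configurable for users smoothing noisier,
smaller logs.

Slopes are rank-transformed to within-song percentiles (invariant to any
monotone rescaling), and 15-s windows — 16 grid points, both endpoints
included — are extracted with `t = 0` at the event onset (fractional onsets
snap to the nearest grid second). Songs whose window would cross the track
end are skipped with a warning. Aggregation reports median and quartile
curves across songs; `random_window_baseline()` repeats the extraction at
one uniformly random start per song, giving a null reference whose median
fluctuates around the 50th percentile. `shift_histogram()` translates a
histogram back in time (dropping and renormalizing mass shifted past zero)
for aligning histograms with structural boundaries once a latency estimate
is in hand.

## Consistency stage

`tv_curve()` asks how many queries are needed before a song's offset
distribution is stable: the (optionally capped, default 8 million) queries
are randomly split into two disjoint halves; for each subsample size `s` on
the grid, the first `s` events of each shuffled half are binned at 1 s and
normalized, and the total variation distance between the two densities is
recorded; the whole partition is redrawn 100 times and the curves averaged.
"Growing subsamples" is implemented as prefix accumulation within each
shuffled half — prefixes of a shuffled half are uniform subsamples, and
cumulative counts make the whole grid computable in one pass. The default
grid steps by 1,000, and `threshold_crossing()` interpolates linearly
between grid points so reported crossing sizes are not quantized to the
grid. `cross_song_median()` reduces per-song curves (on a shared grid) to a
pointwise median and the median of per-song crossing sizes; a target no
song attains propagates as `NA` with a "not attained" status rather than a
fabricated size.

## Orchestration and reproducibility

`run_pipeline()` runs clean → uniformity → lifecycle → slopes → consistency
over a corpus from one configuration (R list or YAML), writing one CSV per
stage plus a log of parameters and seeds. Every random choice in the
package flows through an explicit seed; seeded code paths save and restore
the caller's RNG state, and the pipeline derives per-stage, per-song seeds
as `master + 101·stage + song`, recorded in the log, so reruns are
byte-identical.

## Validation scale

The test suite exercises the pipeline at sizes chosen to make Monte-Carlo
checks sharp while keeping a full run interactive: KS type-I calibration
uses 1,000 replicates of n = 1,000; the no-drift specificity check uses 100
replicate 3-song corpora (6,000 queries per song, `k` = 1,000); latency-mode
recovery uses 20-song corpora of 100,000 queries per song at modes 5, 9 and
12 s; the drift-localization check uses 10 songs of 30,000 queries
(`k` = 5,000, `drift_strength` = 8 as the strong-drift condition); TV curves
are validated against exact hypergeometric enumeration on two-bin toys and
for monotonicity on 5-song corpora of 20,000 queries. Monte-Carlo
tolerances are stated in standard errors of the quantity checked.

## Limitations

* Offsets are analyzed marginally; no user-level or session-level structure
  is modeled or recoverable from the two stored fields.
* The latency readout identifies the *mode* of the intent-to-query delay
  only under a sharp-onset latency law; for smooth latency distributions the
  slope peak systematically precedes the mode and should be read as a lower
  bound.
* Day-resolved dates make "first k queries" ambiguous within a day; both
  tie-break policies (stable, seeded-random) are provided, and at the
  intended subset sizes the choice is immaterial.
* The asymptotic KS p-value is inaccurate below a few dozen observations —
  irrelevant for query logs, but worth noting for toy inputs.
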
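# querytiming

Tools for studying **when, within a song, listeners reach for an audio
identification app** (a Shazam-style service). Every successful query leaves
an *offset* — the second of the track at which the query was initiated — and
a day-resolved date. Aggregated over millions of queries, offset histograms
encode which musical moments drive listeners to act, how that behavior
evolves over a hit's life cycle, and how much data is needed before a song's
query-timing profile stabilizes. The package is aimed at music-informatics
and behavioral-analytics researchers working with such event-time logs.

## What it computes

For each song with query offsets `x_1, …, x_n ∈ (0, L]` (track length `L`):

* **Cleaning and summaries** — drop records with a missing offset or date,
  offsets ≤ 0, or offsets > `L`; report usable counts per song and corpus
  totals.
* **Uniformity** — a two-sided Kolmogorov–Smirnov test of the offsets
  against Uniform(0, L), after adding i.i.d. Uniform[−5·10⁻⁶, +5·10⁻⁶]
  perturbations to break ties introduced by the logs' finite precision.
* **Life-cycle shift** — extract the first `k` queries after the release
  date, the first `k` after the chart-peak date, and the final `k` by date;
  for every beginning-window length `d_b = 1, …, ⌈L⌉` s, a one-sided
  two-sample χ² test of proportions of `P(x < d_b)`, with the alternative
  that the *later* sample concentrates more mass near the song start.
  Per-song χ² values are rank-transformed to percentiles
  (`100·rank/n`, average ranks for ties) and aggregated across songs as
  median and quartile curves, plus a per-song raster of windows with
  one-sided `p < 10⁻¹⁰`.
* **Event-locked slopes** — bin offsets at 1 s, estimate the density's
  derivative at every whole second by degree-1 local polynomial regression
  (tricube weights), rank-transform to within-song percentiles, and
  aggregate 15-s windows time-locked to the song start, first vocal onset,
  and first chorus onset, against a random-window baseline whose median
  hovers near the 50th percentile.
* **Consistency** — split a song's queries into random disjoint halves,
  compare binned densities of growing subsamples with total variation
  distance `TV(p, q) = ½ Σᵢ |pᵢ − qᵢ|`, average over 100 re-partitions, and
  report the subsample sizes at which TV reaches targets such as 0.1 and
  0.05.

A seeded synthetic generator ([`simulate_corpus()`]) produces query logs
with the structure these analyses assume — an exponentially decaying
baseline, event-locked bursts delayed by an intent-to-query latency, and a
life-cycle drift of mass toward the song beginning — so the full pipeline is
testable without any proprietary data.

## Worked example

```r
library(querytiming)

md  <- song_metadata("demo", length_s = 220, release_date = "2014-09-01",
                     peak_date = "2015-01-06", vocal_onset_s = 30,
                     chorus_onset_s = 75)
cfg <- synth_config(seed = 42, n_queries = 100000)
ds  <- clean_queries(simulate_song_queries(md, cfg))$dataset
ds
#> <query_dataset> demo: 100000 queries, dates 2014-09-01 to 2016-01-15

ks_uniformity_test(ds$events$offset_s, 220, seed = 1)
#> <uniformity_test> n = 100000, D = 0.522, p = 0

subs <- select_phase_subsets(ds, k = 10000)
sw   <- proportion_sweep(subs$release_set, subs$end_set, 220)
sw[which.max(sw$chi2), ]
#>    d_b     chi2 p_one_sided percentile
#> 71  71 360.4652 1.11498e-80        100

prof <- estimate_slopes(build_histogram(ds$events$offset_s, 220))
w    <- extract_event_windows(prof, md$vocal_onset_s, "vocal_onset")
w$rel_time_s[which.max(w$slope_percentile)]
#> [1] 9

cv <- tv_curve(ds, seed = 9)
threshold_crossing(cv, 0.1)
#> [1] 3520
```

Reading the output: the KS statistic `D = 0.52` with `p ≈ 0` says the
synthetic song's offsets are far from uniform. The proportion sweep finds
its largest χ² at a 71-s beginning window — by the end of the data the
distribution has drifted toward the song's start. The slope-percentile
window peaks 9 s after the vocal onset, recovering the generator's 9-s
intent-to-query latency mode, and about 3,500 queries per half suffice for
two independent halves of this log to agree within total variation 0.1.

`run_pipeline()` runs all stages over a corpus from one seeded
configuration (an R list or YAML file) and writes per-stage CSV tables and
a run log; see `?run_pipeline` and the methods vignette
(`vignettes/query-offset-analysis.Rmd`) for the statistical details and
design choices.

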
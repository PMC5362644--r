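test_that("histogram binning is half-open with a closed last bin", {
  h <- build_histogram(c(0.5, 1.5, 1.7, 2.5), 3, 1)
  expect_equal(h$counts, c(1, 2, 1))
  expect_equal(sum(h$density), 1)
  expect_equal(h$bin_edges, 0:3)

  # offset exactly at the track end lands in the last bin
  h2 <- build_histogram(c(1, 200), 200, 1)
  expect_equal(h2$counts[200], 1)
  expect_equal(h2$counts[1], 0) # offset exactly 1 is in bin [1, 2)
  expect_equal(h2$counts[2], 1)

  expect_error(build_histogram(c(1, 2), 200, 0), "positive")
  expect_error(build_histogram(c(-1, 2), 200), "within")
  u <- build_histogram(runif(50000, 0, 200), 200)
  expect_lt(max(abs(u$density - 1 / 200)), 0.002) # roughly flat
})

test_that("earliest-query truncation keeps the first m by date", {
  md <- make_md()
  dates <- as.Date("2015-01-01") + c(5, 1, 3, 1, 9, 0, 3, 2, 7, 4)
  ds <- query_dataset(1:10, dates, md)
  tr <- truncate_earliest(ds, m = 3)
  expect_equal(tr$events$offset_s, c(6, 2, 4)) # stable within-day order
  all10 <- truncate_earliest(ds, m = 50) # m >= n keeps everything
  expect_equal(all10$events$offset_s, ds$events$offset_s[order(dates)])
  expect_equal(nrow(all10$events), 10L)
  # seeded tie-breaking is reproducible
  expect_identical(truncate_earliest(ds, 5, seed = 1)$events,
                   truncate_earliest(ds, 5, seed = 1)$events)
})

test_that("local linear slopes are exact on linear and constant densities", {
  # counts linear in bin index -> density linear in time
  counts <- 10 + 0:29
  offs <- rep(0:29 + 0.5, counts)
  h <- build_histogram(offs, 30, 1)
  prof <- estimate_slopes(h, bandwidth_s = 3)
  true_slope <- 1 / sum(counts) # density rises 1/n per second
  expect_true(all(abs(prof$slope - true_slope) < 1e-9))

  h0 <- build_histogram(rep(0:29 + 0.5, each = 4), 30, 1)
  prof0 <- estimate_slopes(h0, bandwidth_s = 3)
  expect_true(all(abs(prof0$slope) < 1e-12))

  expect_error(estimate_slopes(h, bandwidth_s = 0.5), "exceed")
})

test_that("slopes change sign within one grid step of a triangular peak", {
  peak_bin <- 40
  counts <- c(1:peak_bin, (peak_bin - 1):1) # triangle over 79 bins
  offs <- rep(seq_along(counts) - 0.5, counts)
  h <- build_histogram(offs, length(counts), 1)
  prof <- estimate_slopes(h, bandwidth_s = 3)
  interior <- prof$grid_s >= 3 & prof$grid_s <= length(counts) - 3
  before <- interior & prof$grid_s < peak_bin - 1.5
  after <- interior & prof$grid_s > peak_bin - 0.5 + 1
  expect_true(all(prof$slope[before] > 0))
  expect_true(all(prof$slope[after] < 0))
})

test_that("slope percentiles are a rank transform of the slopes", {
  offs <- simulate_song_queries(make_md(), make_cfg(seed = 8))$events$offset_s
  prof <- estimate_slopes(build_histogram(offs, 220))
  expect_equal(prof$slope_percentile,
               100 * rank(prof$slope, ties.method = "average") / nrow(prof))
  # invariant under monotone rescaling of the slopes (power-of-two scale
  # factors keep the comparison exact in floating point)
  expect_equal(percentile_transform(4 * prof$slope), prof$slope_percentile)
  expect_equal(percentile_transform(prof$slope / 8), prof$slope_percentile)
})

test_that("event windows extract 16 aligned percentile values unchanged", {
  offs <- simulate_song_queries(make_md(), make_cfg(seed = 12))$events$offset_s
  prof <- estimate_slopes(build_histogram(offs, 220))
  w0 <- extract_event_windows(prof, 0, "song_start")
  expect_equal(w0$slope_percentile, prof$slope_percentile[1:16])
  expect_equal(w0$rel_time_s, 0:15)
  wL <- extract_event_windows(prof, 220 - 15, "random")
  expect_equal(wL$slope_percentile,
               prof$slope_percentile[(221 - 15):221])
  expect_error(extract_event_windows(prof, 210, "random"), "exceeds")
})

test_that("window aggregation reduces to quartile curves of one kind", {
  mk <- function(vals, kind = "vocal_onset") {
    structure(list(event_kind = kind, onset_s = 0, rel_time_s = 0:15,
                   slope_percentile = vals), class = "event_window")
  }
  one <- mk(runif(16, 0, 100))
  expect_equal(aggregate_windows(list(one))$median, one$slope_percentile)
  agg <- aggregate_windows(list(mk(rep(10, 16)), mk(rep(50, 16)),
                                mk(rep(90, 16))))
  expect_equal(agg$median, rep(50, 16))
  expect_equal(agg$q1, rep(30, 16))
  expect_equal(agg$q3, rep(70, 16))
  expect_error(aggregate_windows(list(one, mk(runif(16), "random"))),
               "mixed")
})

test_that("random-window baseline starts are seeded and in range", {
  profs <- lapply(synthetic_song_set(5, seed = 3), function(md) {
    offs <- simulate_song_queries(md, make_cfg(seed = 14, n_queries = 2000))
    estimate_slopes(build_histogram(offs$events$offset_s, md$length_s))
  })
  b1 <- random_window_baseline(profs, seed = 9)
  b2 <- random_window_baseline(profs, seed = 9)
  expect_identical(b1, b2)
  for (i in seq_along(b1)) {
    L <- attr(profs[[i]], "length_s")
    expect_true(b1[[i]]$onset_s >= 0 && b1[[i]]$onset_s <= L - 15)
    expect_equal(b1[[i]]$event_kind, "random")
  }
})

test_that("histogram shifts translate mass, drop spillover, renormalize", {
  h <- build_histogram(rep(20.5, 10), 100, 1) # spike in bin [20, 21)
  expect_identical(shift_histogram(h, 0), h)
  s6 <- shift_histogram(h, 6)
  expect_equal(which(s6$density > 0), 15) # spike now in [14, 15)
  expect_equal(sum(s6$density), 1)

  # fractional shift splits a bin's mass proportionally
  sh <- shift_histogram(h, 6.25)
  expect_equal(sh$density[14], 0.25)
  expect_equal(sh$density[15], 0.75)

  # mass shifted below zero is dropped and the rest renormalized
  mix <- build_histogram(c(rep(2.5, 5), rep(50.5, 5)), 100, 1)
  s10 <- shift_histogram(mix, 10)
  expect_equal(sum(s10$density), 1)
  expect_equal(which(s10$density > 0), 41)
  expect_error(shift_histogram(h, 200), "smaller than")
})
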
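test_that("phase subsets pick first-k by date and last-k overall", {
  md <- make_md(release = "2015-01-10", peak = "2015-01-15")
  dates <- as.Date("2015-01-08") + 0:9 # two days precede release
  ds <- query_dataset(1:10, dates, md)
  subs <- suppressWarnings(select_phase_subsets(ds, k = 3))
  expect_equal(subs$release_set$offset_s, 3:5) # first 3 on/after Jan 10
  expect_equal(subs$peak_set$offset_s, 8:10)   # first 3 on/after Jan 15
  expect_equal(subs$end_set$offset_s, 8:10)    # last 3 overall
  # end and peak may overlap; end and release should not here
  expect_length(intersect(subs$release_set$offset_s,
                          subs$end_set$offset_s), 0)

  # all events before release: empty subset with warning
  ds_pre <- query_dataset(1:5, as.Date("2014-01-01") + 0:4, md)
  w <- capture_warnings(s2 <- select_phase_subsets(ds_pre, k = 3))
  expect_match(w, "release", all = FALSE)
  expect_equal(nrow(s2$release_set), 0L)

  expect_error(select_phase_subsets(toy_dataset(numeric(0),
                                                as.Date(character(0))), 3),
               "no events")
})

test_that("sweep chi-squared matches closed forms and prop.test", {
  # 60/100 vs 40/100 below the window
  later <- c(runif(60, 0, 10), runif(40, 11, 200))
  earlier <- c(runif(40, 0, 10), runif(60, 11, 200))
  sw_plain <- proportion_sweep(earlier, later, 220, correct = FALSE)
  sw_yates <- proportion_sweep(earlier, later, 220, correct = TRUE)
  row <- function(sw, d) sw[sw$d_b == d, ]
  expect_equal(row(sw_plain, 11)$chi2, 8.0, tolerance = 1e-12)
  expect_equal(row(sw_plain, 11)$p_one_sided, pnorm(sqrt(8), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(row(sw_yates, 11)$chi2, 7.22, tolerance = 1e-12)

  # agreement with stats::prop.test across assorted window lengths
  for (d in c(5, 11, 50, 150)) {
    a <- sum(later < d); b <- sum(earlier < d)
    for (corr in c(TRUE, FALSE)) {
      pt <- prop.test(c(a, b), c(100, 100), alternative = "greater",
                      correct = corr)
      sw <- if (corr) sw_yates else sw_plain
      expect_equal(row(sw, d)$chi2, unname(pt$statistic), tolerance = 1e-9)
      expect_equal(row(sw, d)$p_one_sided, pt$p.value, tolerance = 1e-9)
    }
  }
})

test_that("identical samples give a null sweep, and chi2 is nonnegative", {
  x <- runif(300, 0, 100)
  sw <- proportion_sweep(x, x, 100, correct = FALSE)
  expect_true(all(sw$chi2 == 0))
  expect_true(all(sw$p_one_sided == 0.5))

  y <- runif(200, 0, 100)^2 / 100
  sw2 <- proportion_sweep(x, y, 100)
  expect_true(all(sw2$chi2 >= 0))
  # uncorrected chi2 is zero iff proportions are exactly equal
  sw3 <- proportion_sweep(x, y, 100, correct = FALSE)
  d <- sw3$d_b
  eq <- vapply(d, function(dd) sum(y < dd) / 200 == sum(x < dd) / 300,
               logical(1))
  expect_equal(sw3$chi2 == 0, eq)

  expect_error(proportion_sweep(numeric(0), x, 100), "non-empty")
})

test_that("strict below-window counting matches a direct comparison", {
  x <- c(0.5, 1, 1.5, 2, 2.0000001, 99.9, 100)
  for (d in 1:100) {
    expect_equal(querytiming:::count_below(x, d), sum(x < d))
  }
})

test_that("percentile transform follows the average-rank convention", {
  expect_equal(percentile_transform(c(3, 1, 2)),
               c(100, 100 / 3, 200 / 3))
  expect_equal(percentile_transform(rep(7, 2)), c(75, 75))
  n <- 5
  expect_equal(percentile_transform(rep(1, n)), rep(50 + 50 / n, n))
  v <- sort(runif(50))
  expect_true(all(diff(percentile_transform(v)) > 0)) # order preserving
  expect_true(all(percentile_transform(rnorm(100)) <= 100))
})

test_that("sweep aggregation takes quartiles over available songs", {
  mk <- function(pct, L) {
    out <- data.frame(d_b = seq_len(L), chi2 = 1, p_one_sided = 0.5,
                      percentile = pct)
    class(out) <- c("proportion_sweep", "data.frame")
    out
  }
  one <- mk(runif(100, 0, 100), 100)
  agg1 <- aggregate_sweeps(list(one))
  expect_equal(agg1$median, one$percentile)

  three <- list(mk(10, 100), mk(50, 100), mk(90, 80))
  agg <- aggregate_sweeps(three)
  expect_equal(agg$median[1:80], rep(50, 80))
  expect_equal(agg$q1[1:80], rep(30, 80))
  expect_equal(agg$q3[1:80], rep(70, 80))
  # beyond the shortest song only two curves remain
  expect_equal(agg$n_songs[81:100], rep(2, 20))
  expect_true(all(agg$q1 <= agg$median & agg$median <= agg$q3))
})

test_that("significance raster flags exactly the sub-threshold windows", {
  x <- runif(400, 0, 100)
  sw_null <- proportion_sweep(x, x, 100)
  expect_length(significance_raster(list(a = sw_null))$a, 0)

  y <- c(runif(300, 0, 10), runif(100, 10, 100)) # strong beginning excess
  sw_alt <- proportion_sweep(x, y, 100)
  ras <- significance_raster(list(a = sw_alt), threshold = 1e-10)
  expect_true(length(ras$a) > 0)
  expect_true(all(sw_alt$p_one_sided[sw_alt$d_b %in% ras$a] < 1e-10))
  # degenerate threshold flags every window
  all_flagged <- significance_raster(list(a = sw_alt), threshold = 1)
  expect_equal(all_flagged$a, sw_alt$d_b)
})
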
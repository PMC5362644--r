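test_that("capping subsamples uniformly without replacement", {
  md <- make_md()
  ds <- query_dataset(1:10, as.Date("2015-01-01") + 1:10, md)
  cap5 <- cap_sample(ds, cap = 5, seed = 1)
  expect_equal(nrow(cap5$events), 5L)
  expect_length(unique(cap5$events$offset_s), 5L)
  expect_true(all(cap5$events$offset_s %in% 1:10))
  expect_false(is.unsorted(cap5$events$date)) # original order kept
  expect_identical(cap_sample(ds, 5, seed = 1)$events, cap5$events)
  expect_identical(cap_sample(ds, 20, seed = 1), ds) # under cap: identity
})

test_that("half splits are disjoint, exhaustive, and seeded", {
  x <- runif(10)
  h <- split_halves(x, seed = 2)
  expect_length(h$half_a, 5); expect_length(h$half_b, 5)
  expect_setequal(c(h$half_a, h$half_b), x)
  h11 <- split_halves(runif(11), seed = 2)
  expect_equal(sort(c(length(h11$half_a), length(h11$half_b))), c(5, 6))
  expect_identical(split_halves(x, seed = 7), split_halves(x, seed = 7))
  expect_error(split_halves(1), "at least 2")

  md <- make_md()
  ds <- query_dataset(1:9, "2015-01-01", md)
  hd <- split_halves(ds, seed = 1)
  expect_s3_class(hd$half_a, "query_dataset")
  expect_setequal(c(hd$half_a$events$offset_s, hd$half_b$events$offset_s), 1:9)
})

test_that("TV distance satisfies its identities and metric properties", {
  expect_equal(tv_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(tv_distance(c(1, 0), c(0, 1)), 1) # disjoint supports
  expect_equal(tv_distance(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(tv_distance(c(1, 0), c(0.5, 0.5, 0)), "mismatched")
  expect_error(tv_distance(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")

  set.seed(5)
  for (i in 1:20) {
    p <- as.vector(rmultinom(1, 500, runif(6))) / 500
    q <- as.vector(rmultinom(1, 500, runif(6))) / 500
    r <- as.vector(rmultinom(1, 500, runif(6))) / 500
    expect_gte(tv_distance(p, q), 0)
    expect_lte(tv_distance(p, q), 1)
    expect_equal(tv_distance(p, q), tv_distance(q, p))
    expect_lte(tv_distance(p, r), tv_distance(p, q) + tv_distance(q, r) + 1e-12)
  }
})

test_that("prefix TV profile is zero for duplicated halves", {
  x <- runif(1000, 0, 100)
  tv <- tv_profile(x, x, c(10, 100, 500), 100)
  expect_equal(tv, c(0, 0, 0))
  expect_error(tv_profile(x, x, c(10, 2000), 100), "exceeds")
})

test_that("TV curves decrease with subsample size on i.i.d. data", {
  x <- runif(20000, 0, 200)
  cv <- tv_curve(x, size_grid = seq(500, 10000, by = 500), length_s = 200,
                 n_iterations = 40, seed = 3)
  expect_true(all(cv$tv >= 0 & cv$tv <= 1))
  # monotone nonincreasing in expectation; allow small Monte-Carlo wiggle
  expect_true(all(diff(cv$tv) < 0.004))
  expect_lt(cv$tv[nrow(cv)], cv$tv[1])
  expect_identical(cv$tv,
                   tv_curve(x, size_grid = seq(500, 10000, by = 500),
                            length_s = 200, n_iterations = 40, seed = 3)$tv)
})

test_that("two-bin toy TV matches exact hypergeometric enumeration", {
  # dataset: N0 offsets in bin [0,1), N1 in [1,2]; prefixes of the two
  # shuffled halves are jointly a simple random sample without replacement
  N0 <- N1 <- 300
  x <- c(rep(0.5, N0), rep(1.5, N1))
  exact_tv <- function(s) {
    N <- N0 + N1
    val <- 0
    for (k in 0:min(2 * s, N0)) {
      pk <- dhyper(k, N0, N1, 2 * s)
      if (pk == 0) next
      a <- 0:min(s, k)
      pa <- dhyper(a, k, 2 * s - k, s)
      val <- val + pk * sum(pa * abs(2 * a - k) / s)
    }
    val
  }
  cv <- tv_curve(x, size_grid = c(2, 4), length_s = 2,
                 n_iterations = 4000, seed = 11)
  for (i in 1:2) {
    s <- cv$subsample_size[i]
    expect_lt(abs(cv$tv[i] - exact_tv(s)), 3 * 0.5 / sqrt(4000))
  }
})

test_that("threshold crossings interpolate linearly and report misses", {
  cv <- data.frame(subsample_size = c(1000, 2000, 3000), tv = c(0.3, 0.1, 0.05))
  expect_equal(threshold_crossing(cv, 0.1), 2000)
  expect_equal(threshold_crossing(cv, 0.075), 2500)
  miss <- threshold_crossing(cv, 0.01)
  expect_true(is.na(miss))
  expect_equal(attr(miss, "status"), "not attained")
  # already below target at the first grid point
  expect_equal(threshold_crossing(cv, 0.5), 1000)
})

test_that("cross-song medians require a shared grid and reduce pointwise", {
  mk <- function(tv) {
    out <- data.frame(subsample_size = c(1000, 2000, 3000), tv = tv)
    class(out) <- c("tv_curve", "data.frame")
    out
  }
  one <- mk(c(0.3, 0.2, 0.1))
  m1 <- cross_song_median(list(one), targets = 0.2)
  expect_equal(m1$median_curve$tv, one$tv)
  expect_equal(unname(m1$median_crossings), 2000)

  med <- cross_song_median(list(mk(rep(0.2, 3)), mk(rep(0.1, 3)),
                                mk(rep(0.05, 3))))
  expect_equal(med$median_curve$tv, rep(0.1, 3))
  bad <- mk(c(0.3, 0.2, 0.1)); bad$subsample_size <- c(1, 2, 3)
  expect_error(cross_song_median(list(one, bad)), "share")
})
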
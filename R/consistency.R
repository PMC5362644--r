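#' Cap a dataset at a maximum number of queries
#'
#' If the dataset exceeds `cap` events, draws a uniform random subsample of
#' exactly `cap` events without replacement (keeping the original event
#' order among those retained); otherwise returns the dataset unchanged.
#' Caps the per-song workload of the consistency analysis.
#'
#' @param dataset A cleaned [query_dataset()].
#' @param cap Maximum number of events (default 8,000,000).
#' @param seed Optional seed.
#' @return A [query_dataset()] with at most `cap` events.
#' @export
cap_sample <- function(dataset, cap = 8000000L, seed = NULL) {
  stopifnot(inherits(dataset, "query_dataset"), is_count(cap))
  n <- nrow(dataset$events)
  if (n <= cap) return(dataset)
  keep <- with_seed(seed, sort(sample.int(n, cap)))
  out <- dataset
  out$events <- dataset$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' Randomly split a dataset into two disjoint halves
#'
#' Partitions the events uniformly at random into two disjoint, exhaustive
#' halves of sizes `floor(n/2)` and `ceiling(n/2)`. The returned halves are
#' in random (shuffled) order, so prefixes of a half are themselves uniform
#' subsamples — the property [tv_curve()] exploits.
#'
#' @param dataset A [query_dataset()], or a numeric vector of offsets.
#' @param seed Optional seed.
#' @return A list with elements `half_a` and `half_b` (same type as the
#'   input: datasets or offset vectors).
#' @export
split_halves <- function(dataset, seed = NULL) {
  offsets_only <- !inherits(dataset, "query_dataset")
  n <- if (offsets_only) length(dataset) else nrow(dataset$events)
  if (n < 2L) stop("need at least 2 events to split into halves")
  perm <- with_seed(seed, sample.int(n))
  ia <- perm[seq_len(n %/% 2L)]
  ib <- perm[(n %/% 2L + 1L):n]
  if (offsets_only) {
    return(list(half_a = dataset[ia], half_b = dataset[ib]))
  }
  grab <- function(i) {
    out <- dataset
    out$events <- dataset$events[i, , drop = FALSE]
    rownames(out$events) <- NULL
    out
  }
  list(half_a = grab(ia), half_b = grab(ib))
}

#' Total variation distance between discrete densities
#'
#' Computes `TV(p, q) = 0.5 * sum(|p_i - q_i|)` for two probability
#' densities on the same bins. TV is 0 for identical densities, 1 for
#' densities with disjoint support, symmetric, and satisfies the triangle
#' inequality.
#'
#' @param p,q Numeric densities of equal length, each summing to 1 within
#'   `1e-9`.
#' @return The distance, in `[0, 1]`.
#' @examples
#' tv_distance(c(0.5, 0.5), c(1, 0)) # 0.5
#' @export
tv_distance <- function(p, q) {
  if (length(p) != length(q)) stop("densities are on mismatched bins")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("densities must each sum to 1")
  }
  0.5 * sum(abs(p - q))
}

#' Total variation profile between prefixes of two fixed halves
#'
#' For one partition into halves (in shuffled order, see [split_halves()]),
#' computes the TV distance between the binned, normalized densities of the
#' first `s` events of each half, for each subsample size `s` in
#' `size_grid`. [tv_curve()] averages this profile over repeated random
#' partitions.
#'
#' @param half_a,half_b Numeric offset vectors (or [query_dataset()]s) in
#'   the order in which prefixes should accumulate.
#' @param size_grid Strictly increasing subsample sizes, each at most
#'   `min(length(half_a), length(half_b))`.
#' @param length_s Track length in seconds (shared binning domain).
#' @param bin_width_s Histogram bin width in seconds (default 1).
#' @return Numeric vector of TV distances, one per grid size.
#' @export
tv_profile <- function(half_a, half_b, size_grid, length_s, bin_width_s = 1) {
  if (inherits(half_a, "query_dataset")) half_a <- half_a$events$offset_s
  if (inherits(half_b, "query_dataset")) half_b <- half_b$events$offset_s
  stopifnot(length(size_grid) >= 1L, all(diff(size_grid) > 0),
            size_grid[1] >= 1)
  if (max(size_grid) > min(length(half_a), length(half_b))) {
    stop("size_grid exceeds the size of a half")
  }
  nb <- ceiling(length_s / bin_width_s)
  bin_of <- function(x) pmin(floor(x / bin_width_s) + 1L, nb)
  ba <- bin_of(half_a); bb <- bin_of(half_b)
  ca <- numeric(nb); cb <- numeric(nb)
  prev <- 0L
  vapply(size_grid, function(s) {
    idx <- (prev + 1L):s
    ca <<- ca + tabulate(ba[idx], nbins = nb)
    cb <<- cb + tabulate(bb[idx], nbins = nb)
    prev <<- s
    0.5 * sum(abs(ca / s - cb / s))
  }, numeric(1))
}

#' Total variation consistency curve
#'
#' Quantifies how fast a song's offset distribution stabilizes with sample
#' size: the dataset is randomly partitioned into two disjoint halves, the
#' first `s` events of each (shuffled) half are binned into densities, and
#' their TV distance is recorded for each subsample size `s` on the grid.
#' The partition is redrawn `n_iterations` times (default 100) and the TV
#' values averaged.
#'
#' @param dataset A cleaned [query_dataset()], or a numeric offset vector
#'   (then `length_s` must be given).
#' @param size_grid Strictly increasing subsample sizes; default is a
#'   1,000-step grid from 1,000 to `floor(n/2)` (or a 10-point grid for
#'   small datasets).
#' @param bin_width_s Histogram bin width in seconds (default 1).
#' @param n_iterations Number of random re-partitions to average over.
#' @param seed Optional seed.
#' @param length_s Track length; taken from the dataset metadata if absent.
#' @return An object of class `tv_curve`: a data frame with columns
#'   `subsample_size` and `tv` (mean over iterations), with attributes
#'   `n_iterations`, `bin_width_s`, `n_total`.
#' @export
tv_curve <- function(dataset, size_grid = NULL, bin_width_s = 1,
                     n_iterations = 100L, seed = NULL, length_s = NULL) {
  if (inherits(dataset, "query_dataset")) {
    if (is.null(length_s)) length_s <- dataset$metadata$length_s
    offsets <- dataset$events$offset_s
  } else {
    offsets <- dataset
    if (is.null(length_s)) stop("length_s is required for raw offset input")
  }
  stopifnot(is_count(n_iterations), n_iterations >= 1)
  n <- length(offsets)
  if (n < 2L) stop("need at least 2 events")
  half <- n %/% 2L
  if (is.null(size_grid)) {
    size_grid <- if (half >= 2000L) seq(1000L, half, by = 1000L)
                 else unique(pmax(1L, round(seq(1, half, length.out = 10L))))
  }
  if (max(size_grid) > half) stop("size_grid exceeds the half size")
  tv <- with_seed(seed, {
    acc <- numeric(length(size_grid))
    for (it in seq_len(n_iterations)) {
      halves <- split_halves(offsets)
      acc <- acc + tv_profile(halves$half_a, halves$half_b, size_grid,
                              length_s, bin_width_s)
    }
    acc / n_iterations
  })
  out <- data.frame(subsample_size = size_grid, tv = tv)
  attr(out, "n_iterations") <- as.integer(n_iterations)
  attr(out, "bin_width_s") <- bin_width_s
  attr(out, "n_total") <- n
  class(out) <- c("tv_curve", "data.frame")
  out
}

#' Subsample size at which a TV curve crosses a target
#'
#' Returns the smallest subsample size at which the (linearly interpolated)
#' TV curve reaches a target distance. If the target is never reached the
#' result is `NA` with a `"not attained"` status.
#'
#' @param curve A `tv_curve` (or data frame with `subsample_size`, `tv`).
#' @param target Target TV distance.
#' @return Numeric crossing size (possibly interpolated between grid
#'   points), or `NA_real_` with attribute `status = "not attained"`.
#' @examples
#' cv <- data.frame(subsample_size = c(1000, 2000, 3000), tv = c(0.3, 0.1, 0.05))
#' threshold_crossing(cv, 0.1)   # 2000
#' threshold_crossing(cv, 0.075) # 2500
#' @export
threshold_crossing <- function(curve, target) {
  stopifnot(is_scalar_num(target))
  s <- curve$subsample_size
  v <- curve$tv
  i <- which(v <= target)[1]
  if (is.na(i)) {
    return(structure(NA_real_, status = "not attained"))
  }
  if (i == 1L) return(s[1])
  s[i - 1L] + (v[i - 1L] - target) * (s[i] - s[i - 1L]) / (v[i - 1L] - v[i])
}

#' Median TV curve and crossings across songs
#'
#' Aggregates per-song [tv_curve()]s (computed on a shared size grid) into
#' the pointwise median curve, and the median across songs of the per-song
#' [threshold_crossing()] sizes for each target.
#'
#' @param curves Non-empty list of `tv_curve`s with identical size grids.
#' @param targets TV targets for crossing sizes (default 0.1 and 0.05).
#' @return A list with `median_curve` (data frame `subsample_size`, `tv`)
#'   and `median_crossings` (named numeric, one entry per target; `NA` if
#'   any song never attains the target).
#' @export
cross_song_median <- function(curves, targets = c(0.1, 0.05)) {
  stopifnot(length(curves) >= 1L)
  grid <- curves[[1]]$subsample_size
  same <- vapply(curves, function(cv) {
    length(cv$subsample_size) == length(grid) && all(cv$subsample_size == grid)
  }, logical(1))
  if (!all(same)) stop("all TV curves must share the same size grid")
  mat <- vapply(curves, function(cv) cv$tv, numeric(length(grid)))
  med <- apply(as.matrix(mat), 1, stats::median)
  crossings <- vapply(targets, function(tg) {
    per_song <- vapply(curves, function(cv) as.numeric(threshold_crossing(cv, tg)),
                       numeric(1))
    stats::median(per_song)
  }, numeric(1))
  names(crossings) <- paste0("tv_", targets)
  list(median_curve = data.frame(subsample_size = grid, tv = med),
       median_crossings = crossings)
}
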
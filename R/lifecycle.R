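#' Extract life-cycle phase subsets of a query dataset
#'
#' Slices a cleaned dataset into the three samples the life-cycle analysis
#' compares: the first `k` queries dated on or after the release date, the
#' first `k` on or after the chart-peak date, and the final `k` by date.
#' Dates are day-resolved, so within a day events keep their input order
#' (stable); pass a `seed` to randomize within-day order instead. If fewer
#' than `k` events qualify for a subset, all of them are taken with a
#' warning. The release and end subsets are expected to be disjoint for a
#' hit's life cycle; overlap triggers a warning (overlap with the peak subset
#' is normal when a song peaks soon after release).
#'
#' @param dataset A cleaned [query_dataset()].
#' @param k Target subset size (default 100,000).
#' @param seed Optional seed for random within-day tie-breaking.
#' @return An object of class `phase_subsets`: a list with data frames
#'   `release_set`, `peak_set`, `end_set` and the requested `k`.
#' @export
select_phase_subsets <- function(dataset, k = 100000L, seed = NULL) {
  stopifnot(inherits(dataset, "query_dataset"), is_count(k), k >= 1)
  ev <- dataset$events
  if (nrow(ev) == 0L) stop("dataset has no events")
  idx <- seq_len(nrow(ev))
  if (!is.null(seed)) {
    idx <- with_seed(seed, {
      o <- sample.int(nrow(ev))
      o[order(ev$date[o])]
    })
  } else {
    idx <- idx[order(ev$date)] # stable sort: input order within a day
  }
  take_first <- function(from_date, label) {
    sel <- idx[ev$date[idx] >= from_date]
    if (length(sel) < k) {
      warning(sprintf("only %d events available for %s subset (k = %d)",
                      length(sel), label, k))
    }
    utils::head(sel, k)
  }
  release_idx <- take_first(dataset$metadata$release_date, "release")
  peak_idx <- take_first(dataset$metadata$peak_date, "peak")
  end_idx <- utils::tail(idx, k)
  if (length(end_idx) < k) {
    warning(sprintf("only %d events available for end subset (k = %d)",
                    length(end_idx), k))
  }
  if (length(intersect(release_idx, end_idx))) {
    warning("release and end subsets overlap; life-cycle phases are not distinct")
  }
  grab <- function(i) { d <- ev[i, , drop = FALSE]; rownames(d) <- NULL; d }
  structure(
    list(release_set = grab(release_idx), peak_set = grab(peak_idx),
         end_set = grab(end_idx), k = as.integer(k)),
    class = "phase_subsets"
  )
}

#' @export
print.phase_subsets <- function(x, ...) {
  cat(sprintf("<phase_subsets> k = %d: release %d, peak %d, end %d events\n",
              x$k, nrow(x$release_set), nrow(x$peak_set), nrow(x$end_set)))
  invisible(x)
}

# count of offsets strictly below each integer threshold d (vectorized)
count_below <- function(offsets, d) {
  findInterval(d, sort(offsets), left.open = TRUE)
}

#' Chi-squared proportion sweep over beginning-window lengths
#'
#' For every beginning-window length `d_b` on the integer grid `1..ceiling(L)`
#' seconds, compares the proportion of queries with offset below `d_b`
#' (window `[0, d_b)`) between an earlier and a later life-cycle sample with
#' a two-sample chi-squared test of proportions, one-sided with the
#' alternative that the *later* sample has the greater beginning proportion
#' (query mass migrating toward the song start). Per-song chi-squared
#' statistics are also rank-transformed to percentiles
#' ([percentile_transform()]) to give songs a common scale.
#'
#' Yates continuity correction is applied by default, mirroring the default
#' of R's `prop.test()`; set `correct = FALSE` for the textbook statistic,
#' which is zero exactly when the sample proportions coincide. Degenerate
#' grid points where both samples lie entirely inside (or outside) the
#' window yield a statistic of 0 and a one-sided p of 0.5.
#'
#' @param earlier,later Numeric offset vectors (seconds), or data frames with
#'   an `offset_s` column; both non-empty.
#' @param length_s Track length in seconds.
#' @param correct Logical; apply the continuity correction?
#' @return A data frame of class `proportion_sweep` with columns `d_b`,
#'   `chi2`, `p_one_sided`, `percentile`, and attributes `n_earlier`,
#'   `n_later`, `correct`.
#' @examples
#' sw <- proportion_sweep(runif(500, 0, 100), runif(500, 0, 100)^1.5 / 10, 100)
#' sw[which.max(sw$chi2), ]
#' @export
proportion_sweep <- function(earlier, later, length_s, correct = TRUE) {
  if (is.data.frame(earlier)) earlier <- earlier$offset_s
  if (is.data.frame(later)) later <- later$offset_s
  if (!length(earlier) || !length(later)) {
    stop("both samples must be non-empty")
  }
  stopifnot(is_scalar_num(length_s), length_s > 0)
  d_b <- seq_len(ceiling(length_s))
  n1 <- length(later); n2 <- length(earlier)
  a <- count_below(later, d_b)   # later sample in [0, d_b)
  b <- count_below(earlier, d_b) # earlier sample in [0, d_b)
  # pooled 2x2 chi-squared with optional Yates correction, as prop.test
  p_pool <- (a + b) / (n1 + n2)
  # |O - E|, equal in all four cells of the 2x2 table; the integer form
  # keeps the statistic exactly zero when the sample proportions coincide
  dev <- abs(a * n2 - b * n1) / (n1 + n2)
  yates <- if (correct) pmin(0.5, dev) else 0
  pq <- p_pool * (1 - p_pool)
  chi2 <- ifelse(pq > 0, (dev - yates)^2 * (1 / n1 + 1 / n2) / pq, 0)
  delta <- a / n1 - b / n2
  p_one <- ifelse(chi2 == 0, 0.5,
                  stats::pnorm(sign(delta) * sqrt(chi2), lower.tail = FALSE))
  out <- data.frame(d_b = d_b, chi2 = chi2, p_one_sided = p_one,
                    percentile = percentile_transform(chi2))
  attr(out, "n_earlier") <- n2
  attr(out, "n_later") <- n1
  attr(out, "correct") <- correct
  class(out) <- c("proportion_sweep", "data.frame")
  out
}

#' Rank-to-percentile transform
#'
#' Converts values to within-vector percentiles, `100 * rank / n`, using
#' average ranks for ties. Used to bring per-song chi-squared statistics and
#' histogram slopes to a common scale across songs.
#'
#' @param values Non-empty numeric vector.
#' @return Percentiles in `(0, 100]`, order-preserving.
#' @examples
#' percentile_transform(c(3, 1, 2)) # 100, 33.3, 66.7
#' @export
percentile_transform <- function(values) {
  if (!length(values)) stop("values must be non-empty")
  100 * rank(values, ties.method = "average") / length(values)
}

#' Aggregate proportion sweeps across songs
#'
#' Combines per-song [proportion_sweep()] percentile curves into median,
#' first-quartile and third-quartile curves over the beginning-window grid.
#' Songs differ in length, so each `d_b` aggregates only the songs whose
#' grid extends that far.
#'
#' @param per_song A non-empty list of `proportion_sweep` data frames.
#' @return A data frame with columns `d_b`, `median`, `q1`, `q3`, `n_songs`.
#' @export
aggregate_sweeps <- function(per_song) {
  stopifnot(length(per_song) >= 1L)
  max_d <- max(vapply(per_song, nrow, integer(1)))
  rows <- lapply(seq_len(max_d), function(d) {
    v <- unlist(lapply(per_song, function(s) {
      if (nrow(s) >= d) s$percentile[d] else NULL
    }))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(d_b = d, median = q[2], q1 = q[1], q3 = q[3],
               n_songs = length(v))
  })
  do.call(rbind, rows)
}

#' Per-song significance raster of the proportion sweep
#'
#' Flags, for each song, the beginning-window lengths whose one-sided
#' p-value falls below a conservative threshold (default `1e-10`, chosen to
#' stay stringent without a formal multiple-comparison correction across the
#' thousands of sweep tests).
#'
#' @param per_song A named list of `proportion_sweep` data frames.
#' @param threshold Significance threshold on the one-sided p-value.
#' @return A named list (one element per song) of integer vectors of
#'   significant `d_b` values; attribute `threshold` records the cutoff.
#' @export
significance_raster <- function(per_song, threshold = 1e-10) {
  stopifnot(length(per_song) >= 1L, is_scalar_num(threshold))
  out <- lapply(per_song, function(s) s$d_b[s$p_one_sided < threshold])
  attr(out, "threshold") <- threshold
  out
}
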
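#' Bin query offsets into a histogram
#'
#' Bins offsets over `[0, length_s]` into uniform bins (default 1 s wide);
#' bins are half-open `[e_i, e_{i+1})` with the last bin closed so an offset
#' exactly at the track end is counted. `density` is per-bin probability
#' mass, `counts / n`, summing to one.
#'
#' @param offsets Numeric offsets in seconds, all within `(0, length_s]`.
#' @param length_s Track length in seconds.
#' @param bin_width_s Bin width in seconds (> 0, default 1).
#' @return An object of class `offset_histogram`: a list with `bin_edges`,
#'   `counts`, `density`, `n`, `length_s`.
#' @export
build_histogram <- function(offsets, length_s, bin_width_s = 1) {
  stopifnot(is_scalar_num(length_s), length_s > 0)
  if (!is_scalar_num(bin_width_s) || bin_width_s <= 0) {
    stop("bin_width_s must be positive")
  }
  if (length(offsets) && (min(offsets) <= 0 || max(offsets) > length_s)) {
    stop("offsets must lie within (0, length_s]; clean the dataset first")
  }
  nb <- ceiling(length_s / bin_width_s)
  idx <- pmin(floor(offsets / bin_width_s) + 1L, nb) # last bin closed
  counts <- tabulate(idx, nbins = nb)
  n <- length(offsets)
  structure(
    list(bin_edges = bin_width_s * (0:nb), counts = counts,
         density = if (n > 0) counts / n else rep(0, nb),
         n = n, length_s = length_s),
    class = "offset_histogram"
  )
}

#' @export
print.offset_histogram <- function(x, ...) {
  cat(sprintf("<offset_histogram> %d queries in %d bins of %.3g s over [0, %.6g]\n",
              x$n, length(x$counts), diff(x$bin_edges[1:2]), x$length_s))
  invisible(x)
}

#' Keep the earliest queries of a dataset
#'
#' Restricts a cleaned dataset to its first `m` events by date (all events if
#' fewer). Dates are day-resolved; within a day the stable input order is
#' kept, or randomized reproducibly when `seed` is given. Used to compute
#' slope profiles from early-life-cycle data, before the drift of query mass
#' toward the song beginning sets in.
#'
#' @param dataset A cleaned [query_dataset()].
#' @param m Number of earliest events to keep (default 1,000,000).
#' @param seed Optional within-day tie-breaking seed.
#' @return A [query_dataset()] of at most `m` events.
#' @export
truncate_earliest <- function(dataset, m = 1000000L, seed = NULL) {
  stopifnot(inherits(dataset, "query_dataset"), is_count(m))
  ev <- dataset$events
  idx <- seq_len(nrow(ev))
  if (!is.null(seed)) {
    idx <- with_seed(seed, { o <- sample.int(nrow(ev)); o[order(ev$date[o])] })
  } else {
    idx <- idx[order(ev$date)]
  }
  keep <- utils::head(idx, m)
  out <- dataset
  out$events <- ev[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

#' Estimate histogram slopes by local polynomial regression
#'
#' Estimates the derivative of the binned offset density at every whole
#' second of the song with degree-1 local polynomial regression (local
#' linear fit, tricube weights): at each grid point the slope is the
#' first-order coefficient of a weighted linear fit of per-bin density
#' against bin center within the bandwidth. Local linear fits reproduce
#' linear densities exactly, and the reported slope percentile
#' ([percentile_transform()]) is invariant to any monotone rescaling of the
#' slopes.
#'
#' The default bandwidth of 3 s resolves event-locked rises at the 1-s scale
#' of the grid; wide bandwidths smear a sharp rise backward in time and bias
#' its apparent peak early (see the package vignette).
#'
#' @param histogram An [build_histogram()] result with at least 3 bins.
#' @param bandwidth_s Tricube bandwidth in seconds; must exceed the bin
#'   width and cover at least 3 bin centers at every grid point.
#' @return An object of class `slope_profile`: a data frame with columns
#'   `grid_s` (0, 1, ..., `floor(length_s)`), `slope` (density change per
#'   second of song time, per second), `slope_percentile`; attributes
#'   `bandwidth_s`, `length_s`.
#' @export
estimate_slopes <- function(histogram, bandwidth_s = 3) {
  stopifnot(inherits(histogram, "offset_histogram"))
  nb <- length(histogram$counts)
  if (nb < 3L) stop("histogram must have at least 3 bins")
  bw_bin <- diff(histogram$bin_edges[1:2])
  if (!is_scalar_num(bandwidth_s) || bandwidth_s <= bw_bin) {
    stop("bandwidth_s must exceed the histogram bin width")
  }
  centers <- (histogram$bin_edges[-1] + histogram$bin_edges[-(nb + 1)]) / 2
  y <- histogram$density
  grid_s <- 0:floor(histogram$length_s)
  slope <- vapply(grid_s, function(t0) {
    u <- (centers - t0) / bandwidth_s
    in_win <- abs(u) < 1
    if (sum(in_win) < 3L) {
      stop("bandwidth too small: fewer than 3 bins inside the window at t = ",
           t0)
    }
    w <- (1 - abs(u[in_win])^3)^3
    xc <- centers[in_win]
    yc <- y[in_win]
    xbar <- sum(w * xc) / sum(w)
    ybar <- sum(w * yc) / sum(w)
    sxx <- sum(w * (xc - xbar)^2)
    if (sxx == 0) return(0)
    sum(w * (xc - xbar) * (yc - ybar)) / sxx
  }, numeric(1))
  out <- data.frame(grid_s = grid_s, slope = slope,
                    slope_percentile = percentile_transform(slope))
  attr(out, "bandwidth_s") <- bandwidth_s
  attr(out, "length_s") <- histogram$length_s
  class(out) <- c("slope_profile", "data.frame")
  out
}

#' Extract a 15-s event-locked window of slope percentiles
#'
#' Takes the slope-percentile values of a [estimate_slopes()] profile at the
#' 16 one-second grid points spanning the 15 s that follow an event onset
#' (both endpoints included), aligned so relative time 0 is the onset.
#' Fractional onsets snap to the nearest grid point. Values are extracted
#' as-is — no renormalization.
#'
#' @param profile A `slope_profile`.
#' @param onset_s Event onset in seconds; `onset_s + 15` must not pass the
#'   track end.
#' @param event_kind One of `"song_start"`, `"vocal_onset"`,
#'   `"chorus_onset"`, `"random"`.
#' @return An object of class `event_window`: a list with `event_kind`,
#'   `onset_s`, `rel_time_s` (0:15) and `slope_percentile` (16 values).
#' @export
extract_event_windows <- function(profile, onset_s,
                                  event_kind = c("song_start", "vocal_onset",
                                                 "chorus_onset", "random")) {
  stopifnot(inherits(profile, "slope_profile"), is_scalar_num(onset_s))
  event_kind <- match.arg(event_kind)
  L <- attr(profile, "length_s")
  if (onset_s < 0 || onset_s + 15 > L) {
    stop(sprintf("window [%.1f, %.1f] exceeds the song (length %.1f s)",
                 onset_s, onset_s + 15, L))
  }
  start <- round(onset_s)
  i <- match(start, profile$grid_s)
  if (is.na(i) || i + 15L > nrow(profile)) {
    stop("event window does not fit on the profile grid")
  }
  structure(
    list(event_kind = event_kind, onset_s = onset_s, rel_time_s = 0:15,
         slope_percentile = profile$slope_percentile[i:(i + 15L)]),
    class = "event_window"
  )
}

#' Aggregate event-locked windows across songs
#'
#' Reduces a collection of same-kind [extract_event_windows()] windows to
#' median, first-quartile and third-quartile slope-percentile curves over
#' relative time.
#'
#' @param windows Non-empty list of `event_window` objects of one kind.
#' @return A data frame with columns `rel_time_s`, `median`, `q1`, `q3` and
#'   attribute `event_kind`.
#' @export
aggregate_windows <- function(windows) {
  stopifnot(length(windows) >= 1L)
  kinds <- unique(vapply(windows, function(w) w$event_kind, character(1)))
  if (length(kinds) != 1L) {
    stop("cannot aggregate windows of mixed event kinds: ",
         paste(kinds, collapse = ", "))
  }
  mat <- vapply(windows, function(w) w$slope_percentile, numeric(16))
  qs <- apply(mat, 1, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  out <- data.frame(rel_time_s = 0:15, median = qs[2, ], q1 = qs[1, ],
                    q3 = qs[3, ])
  attr(out, "event_kind") <- kinds
  out
}

#' Random-window baseline for the event-locked analysis
#'
#' Draws one uniformly random 15-s window start per song on
#' `[0, length - 15]` and extracts the corresponding slope-percentile
#' windows. Because percentiles are a rank transform, these baseline curves
#' fluctuate around the 50th percentile, giving a null reference against
#' which event-locked elevation is judged.
#'
#' @param profiles Non-empty list of `slope_profile` objects, each for a
#'   song of length at least 15 s.
#' @param seed Optional seed for the window starts.
#' @return A list of `event_window` objects with `event_kind = "random"`.
#' @export
random_window_baseline <- function(profiles, seed = NULL) {
  stopifnot(length(profiles) >= 1L)
  with_seed(seed, {
    lapply(profiles, function(p) {
      L <- attr(p, "length_s")
      if (L < 15) stop("song shorter than the 15-s analysis window")
      extract_event_windows(p, stats::runif(1, 0, L - 15), "random")
    })
  })
}

#' Shift a histogram back in time
#'
#' Translates all histogram mass by `-delta_s` seconds (positive `delta_s`
#' moves mass toward the song beginning), e.g. to undo an estimated
#' intent-to-query latency when aligning a histogram with structural song
#' boundaries. Mass shifted below zero (or past the last bin edge, for
#' negative shifts) is dropped and the density renormalized; fractional
#' shifts split each bin's mass proportionally between the two target bins.
#'
#' @param histogram An `offset_histogram`.
#' @param delta_s Shift in seconds, `|delta_s| < length_s`.
#' @return An `offset_histogram` on the same bin edges; `counts` are scaled
#'   to fractional equivalents of the retained mass.
#' @export
shift_histogram <- function(histogram, delta_s) {
  stopifnot(inherits(histogram, "offset_histogram"), is_scalar_num(delta_s))
  if (abs(delta_s) >= histogram$length_s) {
    stop("|delta_s| must be smaller than the track length")
  }
  if (delta_s == 0) return(histogram)
  nb <- length(histogram$counts)
  w <- diff(histogram$bin_edges[1:2])
  shift_bins <- delta_s / w
  lo <- floor(shift_bins)
  frac <- shift_bins - lo
  # source bin i lands on target bins i - lo - 1 and i - lo (uniform-in-bin)
  dens <- numeric(nb)
  src <- seq_len(nb)
  add <- function(target, mass) {
    ok <- target >= 1L & target <= nb & mass > 0
    if (any(ok)) {
      dens[target[ok]] <<- dens[target[ok]] + mass[ok]
    }
  }
  add(src - lo, histogram$density * (1 - frac))
  add(src - lo - 1L, histogram$density * frac)
  total <- sum(dens)
  if (total == 0) stop("shift drops all histogram mass")
  out <- histogram
  out$density <- dens / total
  out$counts <- out$density * histogram$n
  out
}
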
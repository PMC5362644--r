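#' Song metadata record
#'
#' Bundles the per-song information the analyses condition on: track length,
#' release and chart-peak dates, and the annotated onset times of the first
#' vocals and first chorus/hook.
#'
#' @param song_id Character identifier for the song.
#' @param length_s Track length in seconds (> 0).
#' @param release_date,peak_date Calendar days (anything [as.Date()] accepts).
#'   The release date must not be after the chart-peak date.
#' @param vocal_onset_s,chorus_onset_s Onset times, in seconds from track
#'   start, of the first vocals and the first chorus; both must lie in
#'   `[0, length_s)`.
#'
#' @return An object of class `song_metadata`.
#' @examples
#' song_metadata("song01", 220, "2014-09-01", "2015-01-06", 25, 60)
#' @export
song_metadata <- function(song_id, length_s, release_date, peak_date,
                          vocal_onset_s, chorus_onset_s) {
  stopifnot(is.character(song_id) || is.numeric(song_id), length(song_id) == 1L)
  if (!is_scalar_num(length_s) || length_s <= 0) {
    stop("length_s must be a positive number of seconds")
  }
  release_date <- as_day(release_date, "release_date")
  peak_date <- as_day(peak_date, "peak_date")
  if (release_date > peak_date) stop("release_date must be <= peak_date")
  for (on in c(vocal_onset_s = vocal_onset_s, chorus_onset_s = chorus_onset_s)) {
    if (!is_scalar_num(on) || on < 0 || on >= length_s) {
      stop("event onsets must lie in [0, length_s)")
    }
  }
  structure(
    list(song_id = as.character(song_id), length_s = as.numeric(length_s),
         release_date = release_date, peak_date = peak_date,
         vocal_onset_s = as.numeric(vocal_onset_s),
         chorus_onset_s = as.numeric(chorus_onset_s)),
    class = "song_metadata"
  )
}

#' @export
print.song_metadata <- function(x, ...) {
  cat(sprintf("<song_metadata> %s: %.1f s, released %s, peaked %s\n",
              x$song_id, x$length_s, format(x$release_date),
              format(x$peak_date)))
  cat(sprintf("  vocal onset %.1f s, chorus onset %.1f s\n",
              x$vocal_onset_s, x$chorus_onset_s))
  invisible(x)
}

#' Query dataset: offsets and dates for one song
#'
#' A `query_dataset` holds one song's metadata together with its query
#' events. Each event has an offset in seconds from track start and a
#' day-resolved calendar date. Events with missing fields are representable
#' (they are what [clean_queries()] removes).
#'
#' @param offset_s Numeric vector of offsets in seconds (`NA` allowed before
#'   cleaning).
#' @param date Vector of calendar days, recycled against `offset_s` if scalar.
#' @param metadata A [song_metadata()] object.
#'
#' @return An object of class `query_dataset` with elements `metadata` and
#'   `events` (a data frame with columns `offset_s`, `date`).
#' @export
query_dataset <- function(offset_s, date, metadata) {
  stopifnot(inherits(metadata, "song_metadata"))
  date <- as_day(date)
  if (length(date) == 1L) date <- rep(date, length(offset_s))
  if (length(date) != length(offset_s)) {
    stop("offset_s and date must have equal length")
  }
  structure(
    list(metadata = metadata,
         events = data.frame(offset_s = as.numeric(offset_s), date = date)),
    class = "query_dataset"
  )
}

#' @export
print.query_dataset <- function(x, ...) {
  cat(sprintf("<query_dataset> %s: %d queries", x$metadata$song_id,
              nrow(x$events)))
  if (nrow(x$events)) {
    dr <- range(x$events$date, na.rm = TRUE)
    cat(sprintf(", dates %s to %s", format(dr[1]), format(dr[2])))
  }
  cat("\n")
  invisible(x)
}

n_queries <- function(dataset) nrow(dataset$events)

#' Read a query-offset log
#'
#' Reads one song's query log from CSV. The default dialect has a header row
#' and two columns, `offset` (decimal seconds) and `date` (ISO `YYYY-MM-DD`);
#' both column names are configurable since deposited logs vary. Unparseable
#' offsets or dates are kept as `NA` so that [clean_queries()] can count them.
#'
#' @param path Path to an existing CSV file.
#' @param metadata A [song_metadata()] object for the song.
#' @param offset_col,date_col Column names of the offset and date fields.
#'
#' @return A [query_dataset()] with one event per data row, in file order.
#' @seealso [write_queries()] for the inverse operation.
#' @export
read_queries <- function(path, metadata, offset_col = "offset",
                         date_col = "date") {
  if (!file.exists(path)) stop("query log not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(c(offset_col, date_col), names(raw))
  if (length(missing_cols)) {
    stop(sprintf(
      "malformed header in %s: missing column(s) %s; expected dialect has columns '%s' (decimal seconds) and '%s' (YYYY-MM-DD)",
      path, paste(sQuote(missing_cols), collapse = ", "),
      offset_col, date_col))
  }
  offs <- suppressWarnings(as.numeric(raw[[offset_col]]))
  offs[!nzchar(raw[[offset_col]])] <- NA_real_
  dates <- as.Date(raw[[date_col]], format = "%Y-%m-%d")
  query_dataset(offs, dates, metadata)
}

#' Write a query-offset log
#'
#' Writes a [query_dataset()] in the CSV dialect read by [read_queries()].
#' Offsets are stored with six decimal places (sub-millisecond precision, the
#' resolution of the logs this dialect models), so a write/read round trip is
#' lossless for offsets at that stored precision and for dates.
#'
#' @param dataset A [query_dataset()].
#' @param path Output file path.
#' @param offset_col,date_col Column names to write.
#' @return `path`, invisibly.
#' @export
write_queries <- function(dataset, path, offset_col = "offset",
                          date_col = "date") {
  stopifnot(inherits(dataset, "query_dataset"))
  ev <- dataset$events
  out <- data.frame(
    offset = ifelse(is.na(ev$offset_s), "", sprintf("%.6f", ev$offset_s)),
    date = ifelse(is.na(ev$date), "", format(ev$date, "%Y-%m-%d")),
    stringsAsFactors = FALSE
  )
  names(out) <- c(offset_col, date_col)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write query log to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Clean a query dataset
#'
#' Applies the cleaning rules for query logs: remove incomplete records
#' (missing offset or date), then remove records whose offset is at or below
#' zero or strictly greater than the track length. Records dated before the
#' song's release date are deliberately retained, since a single's listed
#' release can postdate the album release. Cleaning preserves event order and
#' is idempotent.
#'
#' @param dataset A [query_dataset()].
#' @return A list with elements `dataset` (the cleaned [query_dataset()]) and
#'   `report` (a `cleaning_report` whose counts `n_usable +
#'   n_removed_missing + n_removed_range` reconcile to `n_input`).
#' @examples
#' md <- song_metadata("s", 200, "2015-01-01", "2015-03-01", 10, 50)
#' ds <- query_dataset(c(-1, 0, 5, 200, 201, NA), "2015-02-01", md)
#' clean_queries(ds)$report
#' @export
clean_queries <- function(dataset) {
  stopifnot(inherits(dataset, "query_dataset"))
  ev <- dataset$events
  L <- dataset$metadata$length_s
  n_input <- nrow(ev)
  complete <- !is.na(ev$offset_s) & !is.na(ev$date)
  in_range <- complete & ev$offset_s > 0 & ev$offset_s <= L
  n_removed_missing <- sum(!complete)
  n_removed_range <- sum(complete & !in_range)
  kept <- ev[in_range, , drop = FALSE]
  rownames(kept) <- NULL
  cleaned <- dataset
  cleaned$events <- kept
  report <- structure(
    list(n_input = n_input, n_usable = nrow(kept),
         pct_usable = if (n_input > 0) 100 * nrow(kept) / n_input else 100,
         n_removed_missing = n_removed_missing,
         n_removed_range = n_removed_range),
    class = "cleaning_report"
  )
  list(dataset = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d input, %d usable (%.2f%%); removed: %d missing, %d out-of-range\n",
    x$n_input, x$n_usable, x$pct_usable, x$n_removed_missing,
    x$n_removed_range))
  invisible(x)
}

#' Summarize per-song usable-query counts
#'
#' Corpus-level summary of the usable query counts of a song set: total,
#' median (midpoint of the two middle values for an even number of songs),
#' minimum and maximum.
#'
#' @param usable_counts Numeric vector with one count per song (non-empty).
#' @return A named list with elements `total`, `median`, `minimum`, `maximum`.
#' @examples
#' summarize_counts(c(1, 2, 3))
#' @export
summarize_counts <- function(usable_counts) {
  if (length(usable_counts) == 0L || !is.numeric(usable_counts)) {
    stop("usable_counts must be a non-empty numeric vector")
  }
  if (anyNA(usable_counts)) stop("usable_counts must not contain NA")
  list(total = sum(usable_counts),
       median = stats::median(usable_counts),
       minimum = min(usable_counts),
       maximum = max(usable_counts))
}

#' Read a song-metadata configuration file
#'
#' Reads per-song metadata from a CSV with columns `song_id`, `length_s`,
#' `release_date`, `peak_date`, `vocal_onset_s`, `chorus_onset_s` (one row
#' per song).
#'
#' @param path Path to the metadata CSV.
#' @return A named list of [song_metadata()] objects, keyed by `song_id`.
#' @export
read_song_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("song_id", "length_s", "release_date", "peak_date",
            "vocal_onset_s", "chorus_onset_s")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("metadata file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    song_metadata(tab$song_id[i], tab$length_s[i], tab$release_date[i],
                  tab$peak_date[i], tab$vocal_onset_s[i], tab$chorus_onset_s[i])
  })
  names(out) <- tab$song_id
  out
}

#' Published per-song summary of the hit-song query corpus
#'
#' Returns the published summary table for the 20-song hit corpus this
#' package's analyses were designed around: Billboard year-end rank, title,
#' artist, track length, and the percentage and number of usable queries per
#' song after cleaning. These printed counts are the inputs to
#' [summarize_counts()] at corpus scale.
#'
#' @return A data frame with columns `rank`, `title`, `artist`, `length_s`,
#'   `pct_usable`, `n_usable` (20 rows).
#' @export
hit_song_table <- function() {
  path <- system.file("extdata", "hit_song_summary.csv",
                      package = "querytiming", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
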
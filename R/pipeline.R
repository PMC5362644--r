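#' Run the full query-timing pipeline over a corpus
#'
#' Orchestrates every analysis stage over a set of songs: cleaning,
#' uniformity testing, life-cycle proportion sweep, event-locked slope
#' profiling, and TV-distance consistency, in that order. Each stage writes
#' a CSV table to `out_dir` and appends its parameters to a run log; the
#' whole run is deterministic given the master seed, with per-stage,
#' per-song seeds derived as `master_seed + 101 * stage_index + song_index`
#' (recorded in the log).
#'
#' The configuration is a named list (or the path of a YAML file with the
#' same structure) with elements:
#' \describe{
#'   \item{songs}{A list of per-song entries, each with `metadata` (a
#'     [song_metadata()] or a named list of its fields) and either `csv`
#'     (path of a query log to read) or `simulate = TRUE` to generate the
#'     log with [simulate_song_queries()].}
#'   \item{stages}{Character vector of stages to run; default all of
#'     `clean`, `uniformity`, `lifecycle`, `slopes`, `consistency`. `clean`
#'     always runs first.}
#'   \item{seed}{Master seed (integer).}
#'   \item{out_dir}{Output directory; created if missing.}
#'   \item{params}{Optional list of stage parameters: `k` (phase-subset
#'     size), `threshold` (raster p cutoff), `m` (earliest-query cap for
#'     slopes), `bandwidth_s`, `cap` (consistency sample cap),
#'     `n_iterations`, `targets`, `synth` (arguments for [synth_config()]).}
#' }
#'
#' @param config Named list or YAML file path, as above.
#' @return Invisibly, a named list of the per-stage result tables plus
#'   `log_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$songs) >= 1L)
  stages_all <- c("clean", "uniformity", "lifecycle", "slopes", "consistency")
  stages <- if (is.null(config$stages)) stages_all else
    match.arg(config$stages, stages_all, several.ok = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- config$params
  if (is.null(p)) p <- list()
  par_def <- list(k = 100000L, threshold = 1e-10, m = 1000000L,
                  bandwidth_s = 3, cap = 8000000L, n_iterations = 100L,
                  targets = c(0.1, 0.05))
  p <- utils::modifyList(par_def, p[intersect(names(p), c(names(par_def), "synth"))])
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("querytiming pipeline run %s", format(Sys.time())),
                 sprintf("master seed: %d", seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")),
                 sprintf("seed derivation: master + 101*stage_index + song_index"),
                 sprintf("params: %s", paste(
                   vapply(setdiff(names(p), "synth"), function(nm)
                     sprintf("%s=%s", nm, paste(p[[nm]], collapse = "/")),
                     character(1)), collapse = ", ")))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage_seed <- function(stage, song) seed + 101L * stage + song

  as_meta <- function(m) {
    if (inherits(m, "song_metadata")) return(m)
    song_metadata(m$song_id, m$length_s, m$release_date, m$peak_date,
                  m$vocal_onset_s, m$chorus_onset_s)
  }
  run_stage <- function(stage_name, song_id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed for song '%s': %s", stage_name,
                   song_id, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- load / simulate, then clean (always) -------------------------------
  synth_args <- if (is.null(p$synth)) list() else p$synth
  datasets <- list()
  reports <- list()
  for (i in seq_along(config$songs)) {
    entry <- config$songs[[i]]
    md <- as_meta(entry$metadata)
    ds <- run_stage("clean", md$song_id, {
      if (!is.null(entry$csv)) {
        read_queries(entry$csv, md)
      } else if (isTRUE(entry$simulate)) {
        sc <- do.call(synth_config, utils::modifyList(
          synth_args, list(seed = stage_seed(0L, i))))
        simulate_song_queries(md, sc)
      } else {
        stop("song entry needs either 'csv' or 'simulate: true'")
      }
    })
    cl <- run_stage("clean", md$song_id, clean_queries(ds))
    datasets[[md$song_id]] <- cl$dataset
    reports[[md$song_id]] <- cl$report
  }
  clean_tab <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(song_id = id, n_input = r$n_input, n_usable = r$n_usable,
               pct_usable = r$pct_usable,
               n_removed_missing = r$n_removed_missing,
               n_removed_range = r$n_removed_range)
  }))
  utils::write.csv(clean_tab, file.path(out_dir, "cleaning.csv"),
                   row.names = FALSE)
  note("clean: %d songs, %s total usable queries", nrow(clean_tab),
       format(sum(clean_tab$n_usable), big.mark = ","))
  results <- list(cleaning = clean_tab)

  # ---- uniformity ---------------------------------------------------------
  if ("uniformity" %in% stages) {
    tab <- do.call(rbind, lapply(seq_along(datasets), function(i) {
      ds <- datasets[[i]]
      r <- run_stage("uniformity", ds$metadata$song_id,
                     ks_uniformity_test(ds$events$offset_s,
                                        ds$metadata$length_s,
                                        seed = stage_seed(1L, i)))
      data.frame(song_id = ds$metadata$song_id, n = r$n,
                 ks_statistic = r$ks_statistic, p_value = r$p_value,
                 seed = stage_seed(1L, i))
    }))
    utils::write.csv(tab, file.path(out_dir, "uniformity.csv"),
                     row.names = FALSE)
    note("uniformity: max p = %.3g", max(tab$p_value))
    results$uniformity <- tab
  } else note("uniformity: skipped")

  # ---- lifecycle ----------------------------------------------------------
  if ("lifecycle" %in% stages) {
    pairs <- list(peak_vs_release = c("release_set", "peak_set"),
                  end_vs_release = c("release_set", "end_set"),
                  end_vs_peak = c("peak_set", "end_set"))
    sweep_rows <- list()
    raster_rows <- list()
    for (i in seq_along(datasets)) {
      ds <- datasets[[i]]
      id <- ds$metadata$song_id
      subs <- run_stage("lifecycle", id,
                        select_phase_subsets(ds, k = p$k,
                                             seed = stage_seed(2L, i)))
      for (cmp in names(pairs)) {
        sw <- run_stage("lifecycle", id,
                        proportion_sweep(subs[[pairs[[cmp]][1]]],
                                         subs[[pairs[[cmp]][2]]],
                                         ds$metadata$length_s))
        sweep_rows[[paste(id, cmp)]] <- data.frame(
          song_id = id, comparison = cmp, sw)
        sig <- sw$d_b[sw$p_one_sided < p$threshold]
        if (length(sig)) {
          raster_rows[[paste(id, cmp)]] <- data.frame(
            song_id = id, comparison = cmp, d_b = sig)
        }
      }
    }
    sweep_tab <- do.call(rbind, sweep_rows)
    raster_tab <- if (length(raster_rows)) do.call(rbind, raster_rows) else
      data.frame(song_id = character(0), comparison = character(0),
                 d_b = integer(0))
    rownames(sweep_tab) <- rownames(raster_tab) <- NULL
    utils::write.csv(sweep_tab, file.path(out_dir, "lifecycle_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(raster_tab, file.path(out_dir, "lifecycle_raster.csv"),
                     row.names = FALSE)
    note("lifecycle: k = %d, %d raster cells below p = %g", p$k,
         nrow(raster_tab), p$threshold)
    results$lifecycle_sweep <- sweep_tab
    results$lifecycle_raster <- raster_tab
  } else note("lifecycle: skipped")

  # ---- slopes -------------------------------------------------------------
  if ("slopes" %in% stages) {
    profiles <- list()
    windows <- list(song_start = list(), vocal_onset = list(),
                    chorus_onset = list())
    for (i in seq_along(datasets)) {
      ds <- datasets[[i]]
      id <- ds$metadata$song_id
      prof <- run_stage("slopes", id, {
        early <- truncate_earliest(ds, m = p$m)
        h <- build_histogram(early$events$offset_s, ds$metadata$length_s)
        estimate_slopes(h, bandwidth_s = p$bandwidth_s)
      })
      profiles[[id]] <- prof
      onsets <- c(song_start = 0, vocal_onset = ds$metadata$vocal_onset_s,
                  chorus_onset = ds$metadata$chorus_onset_s)
      for (ev in names(onsets)) {
        wnd <- tryCatch(extract_event_windows(prof, onsets[[ev]], ev),
                        error = function(e) {
                          warning(sprintf("song '%s': %s window skipped (%s)",
                                          id, ev, conditionMessage(e)))
                          NULL
                        })
        if (!is.null(wnd)) windows[[ev]] <- c(windows[[ev]], list(wnd))
      }
    }
    prof_tab <- do.call(rbind, lapply(names(profiles), function(id)
      data.frame(song_id = id, profiles[[id]])))
    utils::write.csv(prof_tab, file.path(out_dir, "slope_profiles.csv"),
                     row.names = FALSE)
    rnd <- random_window_baseline(profiles, seed = stage_seed(3L, 0L))
    agg <- do.call(rbind, lapply(names(windows), function(ev) {
      if (!length(windows[[ev]])) return(NULL)
      data.frame(event_kind = ev, aggregate_windows(windows[[ev]]))
    }))
    agg <- rbind(agg, data.frame(event_kind = "random",
                                 aggregate_windows(rnd)))
    utils::write.csv(agg, file.path(out_dir, "event_slopes.csv"),
                     row.names = FALSE)
    note("slopes: bandwidth %.1f s, first %d queries per song", p$bandwidth_s,
         p$m)
    results$slope_profiles <- prof_tab
    results$event_slopes <- agg
  } else note("slopes: skipped")

  # ---- consistency --------------------------------------------------------
  if ("consistency" %in% stages) {
    curves <- list()
    for (i in seq_along(datasets)) {
      ds <- datasets[[i]]
      id <- ds$metadata$song_id
      curves[[id]] <- run_stage("consistency", id, {
        capped <- cap_sample(ds, cap = p$cap, seed = stage_seed(4L, i))
        tv_curve(capped, n_iterations = p$n_iterations,
                 seed = stage_seed(4L, i) + 1L)
      })
    }
    # harmonize on the shortest shared grid before taking the median
    min_len <- min(vapply(curves, nrow, integer(1)))
    shared <- lapply(curves, function(cv) {
      out <- cv[seq_len(min_len), , drop = FALSE]
      class(out) <- class(cv)
      out
    })
    med <- cross_song_median(shared, targets = p$targets)
    curve_tab <- do.call(rbind, lapply(names(curves), function(id)
      data.frame(song_id = id, curves[[id]])))
    utils::write.csv(curve_tab, file.path(out_dir, "tv_curves.csv"),
                     row.names = FALSE)
    cross_tab <- data.frame(target = p$targets,
                            median_crossing = unname(med$median_crossings))
    utils::write.csv(cross_tab, file.path(out_dir, "tv_crossings.csv"),
                     row.names = FALSE)
    note("consistency: %d iterations; median crossings %s", p$n_iterations,
         paste(sprintf("%.3g@%g", cross_tab$median_crossing, cross_tab$target),
               collapse = ", "))
    results$tv_curves <- curve_tab
    results$tv_crossings <- cross_tab
    results$tv_median_curve <- med$median_curve
  } else note("consistency: skipped")

  writeLines(log_lines, log_path)
  results$log_path <- log_path
  invisible(results)
}
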
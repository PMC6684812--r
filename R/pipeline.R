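#' Configuration of a full weekly-cycle analysis
#'
#' Bundles every tunable of [run_pipeline()]: input sources (record and
#' grid files, or synthetic specifications), screening filters, the
#' harmonic frequency set, AR order, band level, Monte-Carlo sizes, the
#' report window and the master seed.
#'
#' @param records_path path to an MCD14ML-style record file, or `NULL`.
#' @param grid_path path to an ESRI ASCII anthrome grid, or `NULL`.
#' @param synthetic named list of [simulation_spec()] per anthrome group
#'   (used with a toy grid when no files are given), or a single spec for
#'   a counts-only run.
#' @param grid an [anthrome_grid()] object (alternative to `grid_path`).
#' @param min_confidence,keep_types screening filters
#'   (see [screen_records()]).
#' @param freqs harmonic [frequency_set()] for the regression.
#' @param ar_order AR order of the noise model.
#' @param alpha joint band miscoverage.
#' @param detect_alpha significance level of the diagnostic cycle scan.
#' @param n_mc Monte-Carlo sample size for bands and tables.
#' @param window_weeks length of the report window in weeks (default 52).
#' @param anthrome_mapping code-to-group mapping.
#' @param per_group run the per-anthrome analyses as well as the global
#'   one.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for CSVs and the manifest, or `NULL`
#'   to skip writing.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(records_path = NULL, grid_path = NULL,
                            synthetic = NULL, grid = NULL,
                            min_confidence = 0, keep_types = 0L,
                            freqs = nominal_frequencies(),
                            ar_order = 7L, alpha = 0.05,
                            detect_alpha = 0.01, n_mc = 20000L,
                            window_weeks = 52L,
                            anthrome_mapping = default_anthrome_mapping(),
                            per_group = TRUE, seed = 1L,
                            out_dir = NULL) {
  if ((window_weeks * 7L) %% 7L != 0L || window_weeks < 1L)
    stop("'window_weeks' must be a positive whole number of weeks")
  structure(list(records_path = records_path, grid_path = grid_path,
                 synthetic = synthetic, grid = grid,
                 min_confidence = min_confidence,
                 keep_types = keep_types, freqs = freqs,
                 ar_order = ar_order, alpha = alpha,
                 detect_alpha = detect_alpha, n_mc = n_mc,
                 window_weeks = as.integer(window_weeks),
                 anthrome_mapping = anthrome_mapping,
                 per_group = per_group, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Analyse one daily count series for weekly cycles
#'
#' The per-series core of the pipeline: trim to full weeks, log-transform
#' (offset 1 with a flag when the series has zero-count days), fit the
#' harmonic-AR model, evaluate the mean-function posterior over the
#' report window, build the simultaneous band, partition by weekday and
#' compute the membership and exceedance tables and the strongest-cycle
#' window. A diagnostic spectral scan ([detect_cycles()]) is run on the
#' log series and reported but does not alter the fitted frequency set.
#'
#' @param series a [daily_counts()].
#' @param config an [analysis_config()].
#' @param seed seed for this series' stochastic stages.
#' @return A list of class `series_report` with elements `label`,
#'   `log_offset`, `detected` (diagnostic [frequency_set()]), `fit`,
#'   `posterior`, `band`, `partition`, `membership`, `exceedance`,
#'   `cycle_window`.
#' @export
analyze_series <- function(series, config = analysis_config(),
                           seed = config$seed) {
  stopifnot(inherits(series, "daily_counts"))
  trimmed <- trim_to_full_weeks(series)
  offset <- if (any(trimmed$counts == 0)) 1 else 0
  y <- log_transform(trimmed, offset = offset)
  detected <- detect_cycles(y, alpha = config$detect_alpha)
  fit <- fit_bayes_harmonic_ar(y, freqs = config$freqs,
                               ar_order = config$ar_order)
  # report window capped at the data: extrapolated weekday comparisons
  # would reflect the harmonic extrapolation, not observed fire activity
  weeks <- min(config$window_weeks, length(y$values) %/% 7L)
  window <- seq_len(weeks * 7L)
  mfp <- mean_function_posterior(fit, window = window)
  band <- simultaneous_band(mfp, alpha = config$alpha,
                            n_mc = config$n_mc, seed = seed)
  part <- partition_by_weekday(mfp, band,
                               start_weekday = iso_weekday(y$start_date))
  membership <- membership_table(part, n_mc = config$n_mc,
                                 seed = seed + 100L)
  exceedance <- exceedance_table(part, n_mc = config$n_mc,
                                 seed = seed + 200L)
  window_report <- strongest_cycle_window(part)
  structure(list(label = series$label, log_offset = offset,
                 detected = detected, fit = fit, posterior = mfp,
                 band = band, partition = part,
                 membership = membership, exceedance = exceedance,
                 cycle_window = window_report),
            class = "series_report")
}

#' @export
print.series_report <- function(x, ...) {
  cat(sprintf("<series_report> '%s'%s\n", x$label,
              if (x$log_offset == 1) " (log offset 1: zero-count days)"
              else ""))
  print(x$membership)
  print(x$cycle_window)
  invisible(x)
}

pipeline_inputs <- function(config) {
  grid <- NULL
  if (!is.null(config$grid)) grid <- config$grid
  else if (!is.null(config$grid_path))
    grid <- read_anthrome_grid(config$grid_path)
  if (!is.null(config$records_path)) {
    records <- read_mcd14ml(config$records_path, quiet = TRUE)
  } else if (!is.null(config$synthetic)) {
    if (inherits(config$synthetic, "simulation_spec")) {
      # counts-only synthetic run: no spatial component
      return(list(records = NULL, grid = grid,
                  series = simulate_count_series(config$synthetic)))
    }
    if (is.null(grid))
      stop("synthetic per-group runs need a grid (grid or grid_path)")
    records <- simulate_fire_records(config$synthetic, grid,
                                     seed = config$seed,
                                     mapping = config$anthrome_mapping)
  } else {
    stop("no input: set records_path, or synthetic (+ grid)")
  }
  list(records = records, grid = grid, series = NULL)
}

#' Run the full weekly-cycle pipeline
#'
#' End-to-end orchestration: ingest (file or synthetic) -> screening ->
#' anthrome labelling -> daily aggregation -> per-series analysis
#' ([analyze_series()]) for the global series and, optionally, each
#' anthrome group. When `config$out_dir` is set, writes the share table,
#' fixed-effects summary, membership/exceedance tables (global and
#' per-anthrome), band, cycle windows and a JSON run manifest.
#'
#' @param config an [analysis_config()].
#' @return A list of class `pipeline_result` with `global` (a
#'   `series_report`), `groups` (named list of reports), `shares`,
#'   `config`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  inputs <- pipeline_inputs(config)
  if (!is.null(inputs$series)) {
    global <- analyze_series(inputs$series, config, seed = config$seed)
    result <- structure(list(global = global, groups = list(),
                             shares = NULL, config = config),
                        class = "pipeline_result")
    write_pipeline_outputs(result)
    return(result)
  }
  records <- screen_records(inputs$records,
                            min_confidence = config$min_confidence,
                            keep_types = config$keep_types)
  if (!is.null(inputs$grid))
    records <- assign_anthromes(records, inputs$grid,
                                mapping = config$anthrome_mapping)
  if (nrow(records) == 0) stop("no records remain after screening")
  start <- min(records$acq_date); end <- max(records$acq_date)
  global_series <- aggregate_daily(records, start, end)
  global_series$label <- "global"
  global <- analyze_series(global_series, config, seed = config$seed)
  groups <- list()
  shares <- NULL
  if (config$per_group && !all(is.na(records$anthrome_group))) {
    shares <- anthrome_share_table(records)
    by_group <- aggregate_daily(records, start, end,
                                group_by = "anthrome_group")
    by_group <- by_group[setdiff(names(by_group), "Unlabeled")]
    for (g in names(by_group)) {
      groups[[g]] <- analyze_series(by_group[[g]], config,
                                    seed = config$seed +
                                      1000L * match(g, names(by_group)))
    }
  }
  result <- structure(list(global = global, groups = groups,
                           shares = shares, config = config),
                      class = "pipeline_result")
  write_pipeline_outputs(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n== global ==\n")
  print(x$global)
  for (g in names(x$groups)) {
    cat("==", g, "==\n")
    print(x$groups[[g]])
  }
  invisible(x)
}

write_weekday_table_csv <- function(tab, path, extra = NULL) {
  df <- as.data.frame(tab)
  if (!is.null(extra)) df <- cbind(extra, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_pipeline_outputs <- function(result) {
  out <- result$config$out_dir
  if (is.null(out)) return(invisible(NULL))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)
  if (!is.null(result$shares))
    utils::write.csv(result$shares, p("table1_shares.csv"),
                     row.names = FALSE, quote = FALSE)
  write_fixed_effects_csv(result$global$fit, p("table2_fixed_effects.csv"))
  write_weekday_table_csv(result$global$membership,
                          p("table3_membership.csv"))
  write_weekday_table_csv(result$global$exceedance,
                          p("table4_exceedance.csv"))
  if (length(result$groups) > 0) {
    mem <- do.call(rbind, lapply(names(result$groups), function(g)
      cbind(data.frame(group = g),
            as.data.frame(result$groups[[g]]$membership))))
    exc <- do.call(rbind, lapply(names(result$groups), function(g)
      cbind(data.frame(group = g),
            as.data.frame(result$groups[[g]]$exceedance))))
    utils::write.csv(mem, p("table5_membership_by_anthrome.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(exc, p("table6_exceedance_by_anthrome.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  write_band_csv(result$global$band, p("band.csv"))
  windows <- do.call(rbind, lapply(
    c(list(global = result$global), result$groups), function(r) {
      w <- r$cycle_window
      data.frame(label = r$label, start_week = w$start_week,
                 end_week = w$end_week, length = w$length,
                 start_date = format(w$start_date),
                 end_date = format(w$end_date))
    }))
  utils::write.csv(windows, p("cycle_window.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("firecycles")),
    r_version = R.version.string,
    seed = result$config$seed,
    alpha = result$config$alpha,
    n_mc = result$config$n_mc,
    window_weeks = result$config$window_weeks,
    ar_order = result$config$ar_order,
    omega = result$config$freqs$omega,
    groups = names(result$groups))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}
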
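# End-to-end orchestration: (synthetic or CSV) SST grid -> per-pixel
# climatology + event detection -> per-pixel period metrics -> realm/season
# strata -> trend suite -> classified results, written as tidy CSVs plus a
# JSON run manifest. Re-running an identical configuration reproduces
# byte-identical outputs.

#' Pipeline run configuration
#'
#' Defaults follow the study design: analysis span 1982-01-01..2021-12-31,
#' climatology baseline 1983-01-01..2012-12-31, Hobday-default detection
#' parameters, alpha = 0.05, seasonal stratification.
#'
#' @param sst_path,realm_path input CSVs (long-format SST and realm table);
#'   leave NULL to generate a synthetic grid instead.
#' @param synthetic list describing the synthetic grid:
#'   `n_pixels_per_realm`, optional `config` ([synth_config()]), optional
#'   `per_realm_overrides`, optional `events`.
#' @param baseline_start,baseline_end climatology baseline window.
#' @param analysis_start,analysis_end analysis span (must contain the
#'   baseline).
#' @param percentile,window_half_width,smooth_width climatology parameters
#'   (see [compute_climatology()]).
#' @param min_duration,max_gap detection parameters (see [detect_events()]).
#' @param alpha significance level for direction classification.
#' @param seasonal stratify by hemisphere-dependent season (TRUE) or run
#'   annual-only (FALSE).
#' @param out_dir output directory (created if needed); NULL disables file
#'   output.
#' @param seed integer seed controlling synthetic generation.
#' @return a `run_config` list.
#' @export
run_config <- function(sst_path = NULL, realm_path = NULL, synthetic = NULL,
                       baseline_start = "1983-01-01",
                       baseline_end = "2012-12-31",
                       analysis_start = "1982-01-01",
                       analysis_end = "2021-12-31",
                       percentile = 90, window_half_width = 5L,
                       smooth_width = 31L, min_duration = 5L, max_gap = 2L,
                       alpha = 0.05, seasonal = TRUE, out_dir = NULL,
                       seed = 1L) {
  cfg <- list(sst_path = sst_path, realm_path = realm_path,
              synthetic = synthetic,
              baseline_start = as.Date(baseline_start),
              baseline_end = as.Date(baseline_end),
              analysis_start = as.Date(analysis_start),
              analysis_end = as.Date(analysis_end),
              percentile = percentile,
              window_half_width = as.integer(window_half_width),
              smooth_width = as.integer(smooth_width),
              min_duration = as.integer(min_duration),
              max_gap = as.integer(max_gap),
              alpha = alpha, seasonal = isTRUE(seasonal),
              out_dir = out_dir, seed = as.integer(seed))
  if (cfg$baseline_start < cfg$analysis_start ||
      cfg$baseline_end > cfg$analysis_end) {
    stop("baseline window must lie within the analysis span")
  }
  if (is.null(cfg$synthetic) && (is.null(sst_path) || is.null(realm_path))) {
    stop("provide either input paths or a synthetic grid description")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline inputs
#'
#' Report-only checks: pixels missing from the realm table (and vice versa),
#' calendar gaps inside each series, SST values outside the plausible
#' -5..45 C range, and hemisphere labels inconsistent with latitude sign.
#'
#' @param series named list of `sst_series` (or a long-format SST CSV path).
#' @param realm_table realm assignment data frame (or its CSV path).
#' @return data frame of issues (`pixel_id`, `issue`, `detail`); zero rows
#'   when the inputs are clean.
#' @export
validate_inputs <- function(series, realm_table) {
  if (is.character(series)) series <- read_sst_csv(series)
  if (is.character(realm_table)) realm_table <- read_realm_csv(realm_table)
  issues <- list()
  note <- function(pixel, issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      pixel_id = pixel, issue = issue, detail = detail)
  }
  for (pid in setdiff(names(series), realm_table$pixel_id)) {
    note(pid, "missing_from_realm_table", "pixel has SST but no realm")
  }
  for (pid in setdiff(realm_table$pixel_id, names(series))) {
    note(pid, "missing_sst", "pixel in realm table but no SST series")
  }
  for (pid in names(series)) {
    s <- series[[pid]]
    gaps <- find_gaps(s$date)
    for (i in seq_len(nrow(gaps))) {
      note(pid, "calendar_gap", sprintf("%d missing day(s) %s..%s",
           gaps$n_days[i], format(gaps$gap_start[i]), format(gaps$gap_end[i])))
    }
    bad <- which(!is.na(s$sst) & (s$sst < -5 | s$sst > 45))
    if (length(bad) > 0) {
      note(pid, "sst_out_of_range", sprintf("%d day(s) outside -5..45 C",
                                            length(bad)))
    }
  }
  if (all(c("latitude", "hemisphere") %in% names(realm_table))) {
    conflict <- (realm_table$latitude < 0 & realm_table$hemisphere == "north") |
      (realm_table$latitude >= 0 & realm_table$hemisphere == "south")
    for (pid in realm_table$pixel_id[which(conflict)]) {
      note(pid, "hemisphere_latitude_conflict",
           "hemisphere label inconsistent with latitude sign")
    }
  }
  if (length(issues) == 0) {
    return(data.frame(pixel_id = character(), issue = character(),
                      detail = character()))
  }
  do.call(rbind, c(issues, make.row.names = FALSE))
}

# deterministic CSV writer (fixed field order, no quoting surprises)
write_tidy_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Loads or generates the SST grid, validates it, computes per-pixel
#' climatologies and detects heatwaves over the analysis span, aggregates
#' per-pixel period metrics into realm x season x metric strata (plus
#' global strata), fits the trend suite to every stratum, and classifies
#' directions. When `config$out_dir` is set, writes `events.csv`,
#' `metric_series.csv`, `strata_results.csv` (realm strata),
#' `global_results.csv`, `direction_summary.csv` and `manifest.json`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return (invisibly) a list: `grid_pixels`, `events`, `strata`,
#'   `results` (realm strata fits), `global_results`, `direction_summary`,
#'   `validation`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gen_cfg <- if (!is.null(syn$config)) syn$config else synth_config()
    gen_cfg$rng_seed <- config$seed
    say("generating synthetic grid (%d realms)",
        length(syn$n_pixels_per_realm))
    grid <- generate_grid(syn$n_pixels_per_realm, gen_cfg,
                          per_realm_overrides = syn$per_realm_overrides,
                          events = syn$events)
    series <- grid$series
    realm_table <- grid$pixels
  } else {
    say("reading %s", config$sst_path)
    series <- read_sst_csv(config$sst_path)
    realm_table <- read_realm_csv(config$realm_path)
  }

  validation <- validate_inputs(series, realm_table)
  fatal <- validation$issue %in% c("missing_from_realm_table", "missing_sst")
  if (any(fatal)) {
    stop("pixels and realm table disagree: ",
         paste(unique(validation$pixel_id[fatal]), collapse = ", "))
  }

  hemi <- realm_table$hemisphere[match(names(series), realm_table$pixel_id)]
  all_events <- list(); pm_season <- list(); pm_annual <- list()
  for (i in seq_along(series)) {
    s <- series[[i]]
    span <- s[s$date >= config$analysis_start & s$date <= config$analysis_end,
              , drop = FALSE]
    s_span <- sst_series(pixel_id_of(s), span$date, span$sst)
    clim <- compute_climatology(s_span, config$baseline_start,
                                config$baseline_end, config$percentile,
                                config$window_half_width, config$smooth_width)
    ev <- detect_events(s_span, clim, config$min_duration, config$max_gap)
    all_events[[i]] <- ev
    pm_annual[[i]] <- summarize_period(s_span, clim, ev, "year")
    if (config$seasonal) {
      pm_season[[i]] <- summarize_period(s_span, clim, ev, "season",
                                         hemisphere = hemi[i])
    }
    say("pixel %s: %d events", pixel_id_of(s), nrow(ev))
  }
  events <- do.call(rbind, c(all_events, make.row.names = FALSE))
  annual <- do.call(rbind, c(pm_annual, make.row.names = FALSE))

  if (config$seasonal) {
    seasonal_pm <- do.call(rbind, c(pm_season, make.row.names = FALSE))
    strata <- build_strata(seasonal_pm, realm_table,
                           annual_period_metrics = annual)
  } else {
    strata <- build_strata(annual, realm_table)
  }

  realm_strata <- strata[strata$scope == "realm", , drop = FALSE]
  global_strata <- strata[strata$scope == "global", , drop = FALSE]
  say("fitting %d realm strata", length(unique(realm_strata$stratum)))
  results <- fit_strata(realm_strata, alpha = config$alpha)
  global_results <- fit_strata(global_strata, alpha = config$alpha)

  dir_summary <- as.data.frame(summarize_directions(results$direction))
  dir_summary$n_strata <- nrow(results)

  out <- list(grid_pixels = realm_table, events = events, strata = strata,
              results = results, global_results = global_results,
              direction_summary = dir_summary, validation = validation)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_events_csv(events, p("events.csv"))
    write_tidy_csv(strata, p("metric_series.csv"))
    res_out <- results; attr(res_out, "fits") <- NULL
    write_tidy_csv(res_out, p("strata_results.csv"))
    glob_out <- global_results; attr(glob_out, "fits") <- NULL
    write_tidy_csv(glob_out, p("global_results.csv"))
    write_tidy_csv(dir_summary, p("direction_summary.csv"))
    manifest <- list(
      package = "mhwtrends",
      package_version = as.character(utils::packageVersion("mhwtrends")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      config = config_to_json(config))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(out)
}

config_to_json <- function(config) {
  lapply(unclass(config), function(v) {
    if (inherits(v, "Date")) format(v)
    else if (inherits(v, "synth_config")) lapply(unclass(v), function(w) {
      if (inherits(w, "Date")) format(w) else w
    })
    else if (is.list(v)) lapply(v, function(w) {
      if (inherits(w, "Date")) format(w)
      else if (is.data.frame(w) && "onset_date" %in% names(w)) {
        w$onset_date <- format(w$onset_date); w
      } else if (inherits(w, "synth_config")) lapply(unclass(w), function(u) {
        if (inherits(u, "Date")) format(u) else u
      }) else w
    })
    else v
  })
}
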
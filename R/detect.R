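# Marine heatwave detection (Hobday-style definition): days with SST
# strictly above the day-of-year threshold form candidate runs; runs of at
# least min_duration days are events; events separated by at most max_gap
# below-threshold days are joined into one event, with the gap days counting
# towards duration and intensity metrics. Daily intensity is always
# SST minus the climatological (seasonally varying) mean.

# Expand a series onto the full daily grid of its span; absent or NA days
# stay NA and can never be flagged.
full_daily <- function(series) {
  all_dates <- seq(min(series$date), max(series$date), by = "day")
  sst <- rep(NA_real_, length(all_dates))
  sst[match(series$date, all_dates)] <- series$sst
  list(date = all_dates, sst = sst)
}

#' Detect marine heatwave events
#'
#' Flags days with SST strictly above the climatological threshold, keeps
#' maximal runs of at least `min_duration` flagged days, and (when
#' `join_across_gaps`) merges consecutive runs separated by at most
#' `max_gap` non-flagged days into a single event; gap days count towards
#' the event's duration and intensity metrics. A missing day breaks a run
#' and prevents joining across it.
#'
#' @param series an `sst_series`.
#' @param clim an [compute_climatology()] result.
#' @param min_duration minimum event length in days (default 5).
#' @param max_gap maximum below-threshold gap, in days, bridged when joining
#'   (default 2).
#' @param join_across_gaps join events across short gaps (default TRUE).
#' @return data frame of events: `pixel_id`, `start_date`, `end_date`,
#'   `duration` (days), `intensity_mean`, `intensity_max` (degrees C),
#'   `intensity_cumulative` (degree C days). Zero rows when no event.
#' @export
detect_events <- function(series, clim, min_duration = 5L, max_gap = 2L,
                          join_across_gaps = TRUE) {
  stopifnot(inherits(series, "sst_series"), inherits(clim, "mhw_climatology"))
  grid <- full_daily(series)
  slots <- doy_slot(grid$date)
  thr <- clim$clim_threshold[slots]
  mu <- clim$clim_mean[slots]
  anom <- grid$sst - mu
  flagged <- !is.na(grid$sst) & grid$sst > thr

  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  ev_start <- starts[keep]
  ev_end <- ends[keep]

  if (join_across_gaps && length(ev_start) > 1L) {
    merged_start <- ev_start[1]; merged_end <- ev_end[1]
    out_s <- integer(); out_e <- integer()
    for (k in 2:length(ev_start)) {
      gap_idx <- seq(merged_end + 1L, ev_start[k] - 1L)
      gap_len <- length(gap_idx)
      if (gap_len <= max_gap && !anyNA(grid$sst[gap_idx])) {
        merged_end <- ev_end[k]
      } else {
        out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
        merged_start <- ev_start[k]; merged_end <- ev_end[k]
      }
    }
    out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
    ev_start <- out_s; ev_end <- out_e
  }

  n_ev <- length(ev_start)
  if (n_ev == 0L) {
    return(data.frame(pixel_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()), duration = integer(),
                      intensity_mean = numeric(), intensity_max = numeric(),
                      intensity_cumulative = numeric()))
  }
  res <- lapply(seq_len(n_ev), function(k) {
    idx <- ev_start[k]:ev_end[k]
    a <- anom[idx]
    data.frame(pixel_id = pixel_id_of(series),
               start_date = grid$date[ev_start[k]],
               end_date = grid$date[ev_end[k]],
               duration = length(idx),
               intensity_mean = mean(a),
               intensity_max = max(a),
               intensity_cumulative = sum(a))
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

# Expected calendar extent of a (season, season_year, hemisphere) block.
season_window <- function(season, season_year, hemisphere) {
  first_month <- switch(hemisphere,
    north = c(summer = 6, autumn = 9, winter = 12, spring = 3),
    south = c(winter = 6, spring = 9, summer = 12, autumn = 3))[[season]]
  if (first_month == 12) {
    start <- as.Date(sprintf("%d-12-01", season_year - 1L))
    end <- as.Date(sprintf("%d-03-01", season_year)) - 1L
  } else {
    start <- as.Date(sprintf("%d-%02d-01", season_year, first_month))
    nm <- first_month + 3L
    end <- as.Date(sprintf("%d-%02d-01", season_year, nm)) - 1L
  }
  c(start, end)
}

#' Summarise MHW metrics per year or per season
#'
#' Event days are partitioned by the period each day falls in: MHW days,
#' cumulative intensity, and the per-period mean and maximum intensity are
#' computed from the daily anomalies (SST minus climatological mean) of the
#' event days inside the period, while the event count is attributed to the
#' period containing the event's start date. Periods with no event days get
#' zero days/events/cumulative intensity and undefined (NA) mean and
#' maximum intensity.
#'
#' @param series an `sst_series` (already restricted to the analysis span).
#' @param clim an [compute_climatology()] result.
#' @param events [detect_events()] output for this series.
#' @param period `"year"` for calendar-year periods or `"season"` for
#'   hemisphere-dependent 3-month seasons.
#' @param hemisphere `"north"` or `"south"`; needed when `period = "season"`.
#' @param drop_partial drop periods not fully contained in the series span
#'   (default TRUE; e.g. a winter whose December falls before the record
#'   starts).
#' @return data frame with one row per period: `pixel_id`, `year`, `season`
#'   (`"annual"` for yearly periods), `mhw_days`, `n_events`,
#'   `mean_intensity`, `max_intensity`, `cumulative_intensity`.
#' @export
summarize_period <- function(series, clim, events, period = c("year", "season"),
                             hemisphere = "north", drop_partial = TRUE) {
  period <- match.arg(period)
  stopifnot(hemisphere %in% c("north", "south"))
  grid <- full_daily(series)
  slots <- doy_slot(grid$date)
  anom <- grid$sst - clim$clim_mean[slots]

  in_event <- rep(FALSE, length(grid$date))
  if (nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      idx <- which(grid$date >= events$start_date[k] &
                   grid$date <= events$end_date[k])
      in_event[idx] <- TRUE
    }
  }

  if (period == "year") {
    yr <- year_of(grid$date)
    season <- rep("annual", length(yr))
    ev_year <- year_of(events$start_date)
    ev_season <- rep("annual", nrow(events))
  } else {
    lab <- assign_season(grid$date, hemisphere)
    yr <- lab$season_year
    season <- lab$season
    ev_lab <- assign_season(events$start_date, hemisphere)
    ev_year <- ev_lab$season_year
    ev_season <- ev_lab$season
  }

  key <- paste(yr, season, sep = "|")
  periods <- unique(data.frame(year = yr, season = season, key = key))

  if (drop_partial) {
    span <- range(grid$date)
    ok <- vapply(seq_len(nrow(periods)), function(i) {
      if (period == "year") {
        w <- c(as.Date(sprintf("%d-01-01", periods$year[i])),
               as.Date(sprintf("%d-12-31", periods$year[i])))
      } else {
        w <- season_window(periods$season[i], periods$year[i], hemisphere)
      }
      w[1] >= span[1] && w[2] <= span[2]
    }, logical(1))
    periods <- periods[ok, , drop = FALSE]
  }

  if (nrow(periods) == 0L) {
    return(data.frame(pixel_id = character(), year = integer(),
                      season = character(), mhw_days = integer(),
                      n_events = integer(), mean_intensity = numeric(),
                      max_intensity = numeric(),
                      cumulative_intensity = numeric()))
  }
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    sel <- key == periods$key[i] & in_event
    a <- anom[sel]
    a <- a[!is.na(a)]
    nd <- sum(sel)
    ne <- if (nrow(events) > 0) {
      sum(paste(ev_year, ev_season, sep = "|") == periods$key[i])
    } else 0L
    data.frame(pixel_id = pixel_id_of(series),
               year = periods$year[i], season = periods$season[i],
               mhw_days = nd, n_events = ne,
               mean_intensity = if (nd > 0) mean(a) else NA_real_,
               max_intensity = if (nd > 0) max(a) else NA_real_,
               cumulative_intensity = if (nd > 0) sum(a) else 0)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$year, out$season), , drop = FALSE]
}
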
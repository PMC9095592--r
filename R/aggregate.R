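# Hemisphere-dependent seasonal classification and realm-level aggregation.
# Seasons are the traditional 3-month blocks, mirrored between hemispheres;
# December belongs to the season year of the following January so each
# season is one contiguous run. Realm values are pixel-averaged: summed
# metrics (days, events, cumulative intensity) are divided by the realm's
# total pixel count; intensity metrics are averaged over event-bearing
# pixels only.

MHW_METRICS <- c("mhw_days", "n_events", "mean_intensity", "max_intensity",
                 "cumulative_intensity")
SUM_METRICS <- c("mhw_days", "n_events", "cumulative_intensity")

#' Assign dates to hemisphere-dependent seasons
#'
#' Northern hemisphere: June-August is summer, September-November autumn,
#' December-February winter, March-May spring; the southern hemisphere uses
#' the opposite seasons for the same months. December is labelled with the
#' season year of the following January, keeping every season a contiguous
#' 3-month block.
#'
#' @param date a `Date` vector.
#' @param hemisphere `"north"` or `"south"` (equator pixels use the northern
#'   convention).
#' @return data frame with `season` (summer/autumn/winter/spring) and
#'   `season_year`.
#' @export
assign_season <- function(date, hemisphere) {
  stopifnot(hemisphere %in% c("north", "south"))
  m <- month_of(date)
  y <- year_of(date)
  north <- c("winter", "winter", "spring", "spring", "spring", "summer",
             "summer", "summer", "autumn", "autumn", "autumn", "winter")
  south <- c("summer", "summer", "autumn", "autumn", "autumn", "winter",
             "winter", "winter", "spring", "spring", "spring", "summer")
  season <- if (hemisphere == "north") north[m] else south[m]
  data.frame(season = as.character(season),
             season_year = as.integer(y + (m == 12L)))
}

#' Pixel-averaged realm-level yearly metric series
#'
#' For the summed metrics (MHW days, event count, cumulative intensity) the
#' realm value is the pixel sum divided by the realm's total pixel count, so
#' realms of different sizes are directly comparable. For mean and maximum
#' intensity the realm value is the average over pixels that had at least
#' one MHW day in the period (an event-free pixel carries no intensity
#' information; imputing 0 would mean "event at the climatological mean").
#'
#' @param period_metrics row-bound [summarize_period()] output across pixels.
#' @param realm_table pixel table with `pixel_id` and `realm` columns; every
#'   pixel in `period_metrics` must appear, and realm pixel counts are taken
#'   from this table (not from the metrics).
#' @param metric one of `"mhw_days"`, `"n_events"`, `"mean_intensity"`,
#'   `"max_intensity"`, `"cumulative_intensity"`, or `NULL` for all five.
#' @return long data frame: `realm`, `season`, `year`, `metric`, `value`,
#'   `n_pixels`.
#' @export
realm_average <- function(period_metrics, realm_table, metric = NULL) {
  metrics <- if (is.null(metric)) MHW_METRICS else match.arg(metric, MHW_METRICS)
  missing_px <- setdiff(unique(period_metrics$pixel_id), realm_table$pixel_id)
  if (length(missing_px) > 0) {
    stop("pixels absent from realm table: ",
         paste(head(missing_px, 5), collapse = ", "))
  }
  pm <- period_metrics
  pm$realm <- realm_table$realm[match(pm$pixel_id, realm_table$pixel_id)]
  counts <- table(realm_table$realm)
  if (any(counts == 0)) stop("realm with zero pixels")

  out <- list()
  for (met in metrics) {
    for (realm in unique(pm$realm)) {
      sub <- pm[pm$realm == realm, , drop = FALSE]
      n_px <- as.integer(counts[[realm]])
      agg <- lapply(split(sub, paste(sub$year, sub$season, sep = "|")),
                    function(d) {
        v <- d[[met]]
        value <- if (met %in% SUM_METRICS) {
          sum(v, na.rm = TRUE) / n_px
        } else {
          active <- d$mhw_days >= 1 & !is.na(v)
          if (any(active)) mean(v[active]) else NA_real_
        }
        data.frame(realm = realm, season = d$season[1], year = d$year[1],
                   metric = met, value = value, n_pixels = n_px)
      })
      out[[length(out) + 1L]] <- do.call(rbind, c(agg, make.row.names = FALSE))
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$metric, res$realm, res$season, res$year), , drop = FALSE]
}

#' Assemble the trend-analysis strata
#'
#' Emits one yearly metric series per realm x season x metric combination
#' (12 realms x 4 seasons x 5 metrics gives the 240 strata of the full
#' seasonal design), plus, when `include_global` is TRUE, global (all-pixel)
#' series for each metric: annual and, in seasonal mode, one per season.
#'
#' @param period_metrics row-bound per-pixel [summarize_period()] output
#'   (seasonal or annual, matching `seasonal`).
#' @param realm_table pixel table with `pixel_id` and `realm`.
#' @param metrics metric names (default all five).
#' @param include_global add global strata computed over all pixels as one
#'   realm (default TRUE).
#' @param annual_period_metrics optional annual per-pixel metrics used for
#'   the global annual stratum when `period_metrics` is seasonal.
#' @return long data frame: `scope` (`"realm"`/`"global"`), `stratum` id,
#'   `realm`, `season`, `metric`, `year`, `value`, `n_pixels`.
#' @export
build_strata <- function(period_metrics, realm_table, metrics = MHW_METRICS,
                         include_global = TRUE,
                         annual_period_metrics = NULL) {
  realm_part <- realm_average(period_metrics, realm_table)
  realm_part <- realm_part[realm_part$metric %in% metrics, , drop = FALSE]
  realm_part$scope <- "realm"

  parts <- list(realm_part)
  if (include_global) {
    global_table <- realm_table
    global_table$realm <- "global"
    glob <- realm_average(period_metrics, global_table)
    glob <- glob[glob$metric %in% metrics, , drop = FALSE]
    glob$scope <- "global"
    parts[[2]] <- glob
    if (!is.null(annual_period_metrics)) {
      ga <- realm_average(annual_period_metrics, global_table)
      ga <- ga[ga$metric %in% metrics, , drop = FALSE]
      ga$scope <- "global"
      parts[[3]] <- ga
    }
  }
  res <- do.call(rbind, c(parts, make.row.names = FALSE))
  res$stratum <- paste(res$realm, res$season, res$metric, sep = ":")
  res[, c("scope", "stratum", "realm", "season", "metric", "year", "value",
          "n_pixels")]
}

#' Extract one stratum's (year, value) series
#'
#' @param strata [build_strata()] output.
#' @param realm,season,metric stratum coordinates.
#' @return data frame with `year` and `value`, ordered by year.
#' @export
metric_series <- function(strata, realm, season, metric) {
  sub <- strata[strata$realm == realm & strata$season == season &
                strata$metric == metric, c("year", "value")]
  sub[order(sub$year), , drop = FALSE]
}
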
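# Fixed-baseline day-of-year climatology: for each of 366 day-of-year slots,
# pool all baseline observations within a +/- 5-day window of that slot
# across all baseline years, take the mean and the 90th percentile, then
# smooth both with a 31-day circular moving average. 29 February (slot 60)
# is filled afterwards as the average of the smoothed 28 Feb and 1 Mar
# values, so leap days never distort the neighbouring slots.

circular_smooth <- function(x, width) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) stop("smooth_width must be odd")
  half <- (width - 1L) / 2L
  padded <- c(tail(x, half), x, head(x, half))
  sm <- stats::filter(padded, rep(1 / width, width), sides = 2)
  as.numeric(sm[(half + 1L):(half + length(x))])
}

#' Compute a day-of-year climatology (mean and percentile threshold)
#'
#' For each day-of-year slot d, all baseline observations whose slot lies
#' within `window_half_width` days of d (circularly) are pooled across
#' baseline years; the climatological mean is the pooled mean and the
#' threshold the pooled `percentile`-th percentile. Both curves are then
#' smoothed with a `smooth_width`-day circular moving average. Slot 60
#' (29 Feb) is set to the average of the smoothed slot-59 and slot-61
#' values.
#'
#' @param series an `sst_series` covering the baseline window.
#' @param baseline_start,baseline_end baseline window (default the 30-year
#'   window 1983-01-01 to 2012-12-31).
#' @param percentile threshold percentile (default 90).
#' @param window_half_width half-width, in days, of the day-of-year pooling
#'   window (default 5, i.e. an 11-day window).
#' @param smooth_width width, in days, of the circular moving-average
#'   smoother applied to both curves (odd; default 31; 1 disables).
#' @return an `mhw_climatology`: list with `slot` (1:366), `clim_mean`,
#'   `clim_threshold` (degrees C per slot), and the baseline metadata.
#' @export
compute_climatology <- function(series,
                                baseline_start = as.Date("1983-01-01"),
                                baseline_end = as.Date("2012-12-31"),
                                percentile = 90,
                                window_half_width = 5L,
                                smooth_width = 31L) {
  stopifnot(inherits(series, "sst_series"))
  baseline_start <- as.Date(baseline_start)
  baseline_end <- as.Date(baseline_end)
  if (min(series$date) > baseline_start || max(series$date) < baseline_end) {
    stop("series does not cover the baseline window")
  }
  if (as.numeric(baseline_end - baseline_start) < 2 * 365) {
    stop("baseline must span at least 2 years")
  }
  sel <- series$date >= baseline_start & series$date <= baseline_end
  dates <- series$date[sel]
  sst <- series$sst[sel]
  n_expected <- as.numeric(baseline_end - baseline_start) + 1
  n_missing <- n_expected - sum(!is.na(sst))
  if (n_missing / n_expected > 0.10) {
    stop(sprintf("baseline has %.1f%% missing days (> 10%%); series rejected",
                 100 * n_missing / n_expected))
  }
  keep <- !is.na(sst)
  dates <- dates[keep]; sst <- sst[keep]
  slots <- doy_slot(dates)

  # each observation contributes to every target slot within the window
  w <- as.integer(window_half_width)
  offs <- -w:w
  target <- as.integer(outer(slots - 1L, offs, "+")) %% 366L + 1L
  vals <- rep(sst, times = length(offs))
  pooled <- split(vals, target)

  active <- setdiff(1:366, 60L)
  missing_bins <- setdiff(as.character(active), names(pooled))
  if (length(missing_bins) > 0) {
    stop("all-missing day-of-year bin(s): ",
         paste(head(missing_bins, 5), collapse = ", "))
  }
  raw_mean <- vapply(pooled[as.character(active)], mean, numeric(1))
  raw_thr <- vapply(pooled[as.character(active)], quantile, numeric(1),
                    probs = percentile / 100, names = FALSE, type = 7)

  sm_mean <- circular_smooth(raw_mean, smooth_width)
  sm_thr <- circular_smooth(raw_thr, smooth_width)

  clim_mean <- clim_thr <- rep(NA_real_, 366)
  clim_mean[active] <- sm_mean
  clim_thr[active] <- sm_thr
  clim_mean[60] <- (clim_mean[59] + clim_mean[61]) / 2
  clim_thr[60] <- (clim_thr[59] + clim_thr[61]) / 2

  if (any(clim_thr < clim_mean - 1e-9)) {
    stop("climatological threshold fell below the climatological mean; ",
         "input distribution is pathological for a percentile climatology")
  }

  out <- list(slot = 1:366, clim_mean = clim_mean, clim_threshold = clim_thr,
              baseline_start = baseline_start, baseline_end = baseline_end,
              percentile = percentile, window_half_width = w,
              smooth_width = smooth_width, pixel_id = pixel_id_of(series))
  class(out) <- "mhw_climatology"
  out
}

#' @export
print.mhw_climatology <- function(x, ...) {
  cat(sprintf(
    "<mhw_climatology> pixel %s, baseline %s..%s, p%g threshold\n  mean range %.2f..%.2f C, threshold range %.2f..%.2f C\n",
    x$pixel_id, format(x$baseline_start), format(x$baseline_end),
    x$percentile, min(x$clim_mean), max(x$clim_mean),
    min(x$clim_threshold), max(x$clim_threshold)))
  invisible(x)
}
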
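# Synthetic daily-SST generator: seasonal harmonic + piecewise-linear warming
# trend (optionally with a level step at the change year) + AR(1) noise, plus
# injectable discrete warm events with trapezoidal shape. Ground truth
# (configuration and injected events) travels with the generated objects so
# downstream stages can be validated against it.

# Run expr with a private, fully specified RNG state; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Deterministic 31-bit hash of (master_seed, pixel_id): pixels keep their
# noise realisation when a grid is extended with new pixels.
pixel_seed <- function(master_seed, pixel_id) {
  h <- 0
  for (k in utf8ToInt(as.character(pixel_id))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((h * 69069 + (as.numeric(master_seed) %% 2147483647)) %% 2147483647)
}

#' Construct a daily SST series
#'
#' A light container for one pixel's dated daily temperatures: a data frame
#' with columns `date` and `sst` (degrees C), a `pixel_id` attribute and
#' class `sst_series`. Dates must be strictly increasing; gaps are permitted
#' (they are flagged by [validate_inputs()] and break heatwave runs).
#'
#' @param pixel_id scalar identifier.
#' @param date `Date` vector, strictly increasing.
#' @param sst numeric vector of temperatures in degrees C.
#' @return an `sst_series` object.
#' @export
sst_series <- function(pixel_id, date, sst) {
  stopifnot(inherits(date, "Date"), length(date) == length(sst))
  if (is.unsorted(date, strictly = TRUE)) {
    stop("`date` must be strictly increasing")
  }
  out <- data.frame(date = date, sst = as.numeric(sst))
  attr(out, "pixel_id") <- as.character(pixel_id)
  class(out) <- c("sst_series", "data.frame")
  out
}

pixel_id_of <- function(series) attr(series, "pixel_id")

#' Configuration for the synthetic SST generator
#'
#' Defaults emulate a 40-year coastal SST record (1982--2021): a mid-latitude
#' mean of 14 C with a 4 C seasonal harmonic, a modest warming trend that
#' steepens at a 2002 change year, and AR(1) daily residuals with
#' autocorrelation 0.7.
#'
#' @param start_date,end_date series span (coerced to `Date`); the span must
#'   cover at least 2 years.
#' @param mean_level long-term mean SST, degrees C.
#' @param seasonal_amplitude half peak-to-trough amplitude of the annual
#'   harmonic, degrees C.
#' @param seasonal_phase phase of the harmonic, radians.
#' @param trend_before,trend_after warming rates in degrees C per year before
#'   and after the change year (the trend is continuous at the joint).
#' @param change_year first calendar year of the "after" regime, or `NA` for
#'   a single linear trend at `trend_before`.
#' @param level_step optional step, degrees C, added from the change year on
#'   (a shift in central tendency, distinct from a slope change).
#' @param ar_coefficient lag-1 autocorrelation of daily residuals, in (-1, 1).
#' @param noise_sd innovation standard deviation of the AR(1) noise, degrees
#'   C; 0 gives a noise-free series.
#' @param rng_seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(start_date = "1982-01-01", end_date = "2021-12-31",
                         mean_level = 14, seasonal_amplitude = 4,
                         seasonal_phase = 0, trend_before = 0.01,
                         trend_after = 0.03, change_year = 2002,
                         level_step = 0, ar_coefficient = 0.7,
                         noise_sd = 0.4, rng_seed = 1L) {
  cfg <- list(start_date = as.Date(start_date), end_date = as.Date(end_date),
              mean_level = mean_level, seasonal_amplitude = seasonal_amplitude,
              seasonal_phase = seasonal_phase, trend_before = trend_before,
              trend_after = trend_after,
              change_year = if (is.null(change_year)) NA_integer_ else change_year,
              level_step = level_step, ar_coefficient = ar_coefficient,
              noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (is.na(cfg$start_date) || is.na(cfg$end_date)) stop("invalid dates")
  if (as.numeric(cfg$end_date - cfg$start_date) < 2 * 365) {
    stop("span must be at least 2 years (climatology needs multi-year data)")
  }
  if (abs(cfg$ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(cfg)
}

#' Generate one pixel's synthetic daily SST series
#'
#' SST(t) = mean_level + seasonal_amplitude * sin(2*pi*doy(t)/365.25 + phase)
#' + trend(t) + AR(1) noise. The trend is piecewise linear: slope
#' `trend_before` up to 31 December of `change_year - 1` and `trend_after`
#' thereafter, continuous at the joint, plus an optional `level_step` from
#' the change year on. Deterministic given `rng_seed`.
#'
#' @param config a [synth_config()].
#' @param pixel_id identifier stored on the series.
#' @param seed optional seed overriding `config$rng_seed` (used for per-pixel
#'   seed derivation in [generate_grid()]).
#' @return an `sst_series`.
#' @export
generate_series <- function(config, pixel_id = "px1", seed = NULL) {
  validate_synth_config(config)
  dates <- seq(config$start_date, config$end_date, by = "day")
  n <- length(dates)
  doy <- doy_slot(dates)
  seasonal <- config$seasonal_amplitude *
    sin(2 * pi * doy / 365.25 + config$seasonal_phase)
  t_years <- as.numeric(dates - config$start_date) / 365.25
  if (is.na(config$change_year)) {
    trend <- config$trend_before * t_years
  } else {
    joint <- as.Date(sprintf("%d-12-31", config$change_year - 1L))
    t_c <- as.numeric(joint - config$start_date) / 365.25
    trend <- config$trend_before * pmin(t_years, t_c) +
      config$trend_after * pmax(0, t_years - t_c) +
      config$level_step * (t_years > t_c)
  }
  noise <- if (config$noise_sd == 0) {
    numeric(n)
  } else {
    with_seed(if (is.null(seed)) config$rng_seed else seed, {
      innov <- rnorm(n, sd = config$noise_sd)
      x0 <- rnorm(1, sd = config$noise_sd /
                       sqrt(1 - config$ar_coefficient^2))
      as.numeric(stats::filter(innov, config$ar_coefficient,
                               method = "recursive",
                               init = x0))
    })
  }
  out <- sst_series(pixel_id, dates, config$mean_level + seasonal + trend + noise)
  attr(out, "config") <- config
  out
}

#' Define an injectable discrete warm (or cold) event
#'
#' @param pixel_id pixel the event targets (matched against the series).
#' @param onset_date first day of the plateau ramp-up (`Date`).
#' @param duration plateau length in days (>= 1).
#' @param amplitude degrees C added at the plateau; negative values give a
#'   cold spell.
#' @param ramp_days days of linear onset before and offset after the plateau.
#' @return a one-row data frame describing the event.
#' @export
injected_event <- function(pixel_id, onset_date, duration, amplitude,
                           ramp_days = 0L) {
  if (duration < 1) stop("duration must be >= 1")
  if (ramp_days < 0) stop("ramp_days must be >= 0")
  data.frame(pixel_id = as.character(pixel_id),
             onset_date = as.Date(onset_date),
             duration = as.integer(duration),
             amplitude = as.numeric(amplitude),
             ramp_days = as.integer(ramp_days))
}

#' Add discrete events to a series
#'
#' Each event perturbs the series by a trapezoid: `ramp_days` of linear
#' onset, a `duration`-day plateau at `amplitude`, then `ramp_days` of linear
#' offset. The input series is not modified; the applied events are recorded
#' on the returned series as ground truth.
#'
#' @param series an `sst_series`.
#' @param events a data frame of [injected_event()] rows (possibly several,
#'   row-bound); events for other pixel ids are ignored.
#' @return a new `sst_series` with the perturbation applied and a `truth`
#'   attribute listing the applied events.
#' @export
inject_events <- function(series, events) {
  stopifnot(inherits(series, "sst_series"))
  out <- series
  applied <- list()
  if (!is.null(events) && nrow(events) > 0) {
    mine <- events[events$pixel_id == pixel_id_of(series), , drop = FALSE]
    for (i in seq_len(nrow(mine))) {
      ev <- mine[i, ]
      ramp <- ev$ramp_days
      total <- 2L * ramp + ev$duration
      offsets <- seq_len(total) - 1L - ramp
      # trapezoid: fractions k/(ramp+1) on the ramps, 1 on the plateau
      shape <- c(if (ramp > 0) seq_len(ramp) / (ramp + 1),
                 rep(1, ev$duration),
                 if (ramp > 0) rev(seq_len(ramp) / (ramp + 1)))
      days <- ev$onset_date + (seq_len(total) - 1L) - ramp
      idx <- match(days, out$date)
      if (anyNA(idx)) stop("injected event extends outside the series span")
      out$sst[idx] <- out$sst[idx] + ev$amplitude * shape
      applied[[length(applied) + 1L]] <- ev
    }
  }
  truth <- attr(series, "truth")
  attr(out, "truth") <- rbind(truth,
                              if (length(applied)) do.call(rbind, applied))
  out
}

#' The 12 coastal biogeographical realms
#'
#' Representative latitude/longitude anchors for the 12 top-level coastal
#' realms of the Marine Ecoregions of the World scheme, used by
#' [generate_grid()] to place synthetic pixels and derive hemispheres.
#'
#' @return data frame with columns `realm`, `latitude`, `longitude`.
#' @export
meow_realms <- function() {
  data.frame(
    realm = c("Arctic", "Temperate Northern Atlantic",
              "Temperate Northern Pacific", "Tropical Atlantic",
              "Western Indo-Pacific", "Central Indo-Pacific",
              "Eastern Indo-Pacific", "Tropical Eastern Pacific",
              "Temperate South America", "Temperate Southern Africa",
              "Temperate Australasia", "Southern Ocean"),
    latitude = c(75, 45, 45, 10, -10, -5, -10, 10, -40, -35, -40, -60),
    longitude = c(-20, -30, 160, -40, 60, 120, -150, -90, -70, 20, 150, 0)
  )
}

realm_slug <- function(realm) {
  gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(realm)))
}

#' Generate a multi-pixel synthetic SST grid
#'
#' Generates one series per pixel, grouped into realms. Each pixel gets an
#' independent noise realisation via a seed derived deterministically from
#' the master seed and the pixel id, so extending a grid never reshuffles
#' existing pixels. Realm-level overrides replace configuration fields (e.g.
#' a steeper `trend_after`) for all pixels of that realm.
#'
#' @param n_pixels_per_realm named integer vector, realm -> pixel count.
#'   Names default to the 12 realms of [meow_realms()] when unnamed and of
#'   length 12; arbitrary realm names are allowed.
#' @param config baseline [synth_config()] for every pixel.
#' @param per_realm_overrides named list: realm -> list of config fields to
#'   override for that realm's pixels.
#' @param events optional data frame of [injected_event()] rows applied after
#'   generation.
#' @param latitudes optional named vector realm -> latitude for realms not in
#'   [meow_realms()] (default 45 north for unknown realms).
#' @return an `sst_grid`: list with `pixels` (pixel table: pixel_id,
#'   latitude, longitude, realm, hemisphere), `series` (named list of
#'   `sst_series`), and `provenance` (config, overrides, event truth list).
#' @export
generate_grid <- function(n_pixels_per_realm, config = synth_config(),
                          per_realm_overrides = NULL, events = NULL,
                          latitudes = NULL) {
  if (is.null(names(n_pixels_per_realm))) {
    if (length(n_pixels_per_realm) == 12L) {
      names(n_pixels_per_realm) <- meow_realms()$realm
    } else stop("n_pixels_per_realm must be named")
  }
  if (any(n_pixels_per_realm < 1)) stop("pixel counts must be >= 1")
  validate_synth_config(config)
  anchors <- meow_realms()
  pixels <- list(); series <- list()
  for (realm in names(n_pixels_per_realm)) {
    k <- anchors$latitude[match(realm, anchors$realm)]
    lat <- if (!is.null(latitudes) && realm %in% names(latitudes)) {
      latitudes[[realm]]
    } else if (!is.na(k)) k else 45
    lon0 <- anchors$longitude[match(realm, anchors$realm)]
    if (is.na(lon0)) lon0 <- 0
    cfg <- config
    if (!is.null(per_realm_overrides) && realm %in% names(per_realm_overrides)) {
      ov <- per_realm_overrides[[realm]]
      cfg[names(ov)] <- ov
      class(cfg) <- "synth_config"
      validate_synth_config(cfg)
    }
    for (i in seq_len(n_pixels_per_realm[[realm]])) {
      pid <- sprintf("%s_%02d", realm_slug(realm), i)
      s <- generate_series(cfg, pixel_id = pid,
                           seed = pixel_seed(config$rng_seed, pid))
      if (!is.null(events)) s <- inject_events(s, events)
      series[[pid]] <- s
      pixels[[pid]] <- data.frame(
        pixel_id = pid, latitude = lat, longitude = lon0 + 0.25 * (i - 1),
        realm = realm,
        hemisphere = if (lat >= 0) "north" else "south")
    }
  }
  grid <- list(pixels = do.call(rbind, c(pixels, make.row.names = FALSE)),
               series = series,
               provenance = list(config = config,
                                 per_realm_overrides = per_realm_overrides,
                                 events = events))
  class(grid) <- "sst_grid"
  grid
}

#' @export
print.sst_grid <- function(x, ...) {
  cat(sprintf("<sst_grid> %d pixels in %d realms, %s to %s\n",
              nrow(x$pixels), length(unique(x$pixels$realm)),
              format(min(x$series[[1]]$date)), format(max(x$series[[1]]$date))))
  invisible(x)
}

#' @export
print.sst_series <- function(x, ...) {
  cat(sprintf("<sst_series> pixel %s: %d days, %s to %s\n",
              pixel_id_of(x), nrow(x), format(min(x$date)),
              format(max(x$date))))
  invisible(x)
}
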
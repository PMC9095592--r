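# Plain-text interchange: long-format daily SST CSV
# (pixel_id, date ISO-8601, sst_celsius), realm table CSV
# (pixel_id, realm, hemisphere), and a JSON truth sidecar recording the
# generator configuration and injected events.

#' Write / read a grid's SST series as long-format CSV
#'
#' Columns: `pixel_id`, `date` (ISO-8601), `sst_celsius`.
#'
#' @param grid an `sst_grid`.
#' @param path output CSV path.
#' @return `write_sst_csv` returns `path` invisibly; `read_sst_csv` returns a
#'   named list of `sst_series`.
#' @export
write_sst_csv <- function(grid, path) {
  rows <- lapply(grid$series, function(s) {
    data.frame(pixel_id = pixel_id_of(s), date = format(s$date),
               sst_celsius = s$sst)
  })
  write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sst_csv
#' @export
read_sst_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "date", "sst_celsius")
  if (!all(need %in% names(df))) {
    stop("SST CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$pixel_id), function(d) {
    d <- d[order(d$date), ]
    sst_series(d$pixel_id[1], as.Date(d$date), d$sst_celsius)
  })
  out[order(names(out))]
}

#' Write / read the pixel -> realm assignment table
#'
#' Columns: `pixel_id`, `realm`, `hemisphere` (`north`/`south`); latitude and
#' longitude are carried when available.
#'
#' @param pixels pixel table (as in `sst_grid$pixels`).
#' @param path CSV path.
#' @export
write_realm_csv <- function(pixels, path) {
  write.csv(pixels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_realm_csv
#' @export
read_realm_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "realm", "hemisphere")
  if (!all(need %in% names(df))) {
    stop("realm CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$hemisphere %in% c("north", "south"))) {
    stop("hemisphere must be 'north' or 'south'")
  }
  df
}

#' Write / read the synthetic-grid truth sidecar (JSON)
#'
#' Records the generator configuration, realm overrides and the injected
#' event list, so a written grid can be compared against its ground truth.
#'
#' @param grid an `sst_grid`.
#' @param path JSON path.
#' @export
write_truth_json <- function(grid, path) {
  prov <- grid$provenance
  payload <- list(
    config = lapply(prov$config, function(v) {
      if (inherits(v, "Date")) format(v) else v
    }),
    per_realm_overrides = prov$per_realm_overrides,
    events = if (!is.null(prov$events)) {
      ev <- prov$events
      ev$onset_date <- format(ev$onset_date)
      ev
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$events) && NROW(x$events) > 0) {
    x$events <- as.data.frame(x$events)
    x$events$onset_date <- as.Date(x$events$onset_date)
  }
  cfg <- x$config
  cfg$start_date <- as.Date(cfg$start_date)
  cfg$end_date <- as.Date(cfg$end_date)
  if (is.null(cfg$change_year) || is.na(cfg$change_year)) {
    cfg["change_year"] <- list(NA_integer_)
  }
  class(cfg) <- "synth_config"
  x$config <- cfg
  x
}

#' Write a detected-event table as CSV
#'
#' Columns: pixel_id, start_date, end_date, duration, intensity_mean,
#' intensity_max, intensity_cumulative.
#'
#' @param events event data frame ([detect_events()] output, possibly
#'   row-bound across pixels).
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  ev <- events
  ev$start_date <- format(ev$start_date)
  ev$end_date <- format(ev$end_date)
  write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
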
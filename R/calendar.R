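# Calendar helpers: proleptic Gregorian with real leap days.
# Day-of-year uses a fixed 366-slot indexing in which 1 Mar is always slot 61,
# so the same calendar day lands in the same slot in leap and non-leap years.

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Day-of-year slot (366-slot indexing)
#'
#' Maps dates to a 1..366 day-of-year slot in which 29 February occupies
#' slot 60 and 1 March is always slot 61, in leap and non-leap years alike.
#' Climatologies are stored per slot so that the threshold for, say, 15 July
#' is the same slot every year.
#'
#' @param dates a `Date` vector.
#' @return integer vector of slots in 1..366.
#' @export
doy_slot <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  yd <- lt$yday + 1L
  leap <- is_leap_year(lt$year + 1900L)
  ifelse(!leap & yd >= 60L, yd + 1L, yd)
}

month_of <- function(dates) as.POSIXlt(dates)$mon + 1L
year_of <- function(dates) as.POSIXlt(dates)$year + 1900L

# Number of days between consecutive dates is 1 for a gap-free daily series.
find_gaps <- function(dates) {
  if (length(dates) < 2L) return(data.frame(gap_start = as.Date(character()),
                                            gap_end = as.Date(character()),
                                            n_days = integer()))
  d <- diff(as.integer(dates))
  i <- which(d > 1L)
  data.frame(gap_start = dates[i] + 1L,
             gap_end = dates[i + 1L] - 1L,
             n_days = d[i] - 1L)
}
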
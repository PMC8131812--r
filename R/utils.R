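# Internal date helpers. All timestamps in the package are timezone-naive
# local times represented as POSIXct in UTC, so arithmetic is DST-free.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Day-of-year on a fixed non-leap calendar, folding Feb 29 into Feb 28, so
# that a given calendar date maps to the same index every year.
doy_nonleap <- function(dates) {
  m <- data.table::month(dates)
  d <- data.table::mday(dates)
  d[m == 2L & d == 29L] <- 28L
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  cum[m] + d
}

# Build a Date from year + non-leap day-of-year (1..365).
date_from_doy <- function(year, doy) {
  as.Date(sprintf("%d-01-01", year)) + (doy - 1L)
}

# Label a date with the spring/summer breeding season it belongs to
# (Aug-Feb, labelled by the season's starting calendar year); NA for the
# Mar-Jul nonbreeding months.
season_start_year <- function(dates) {
  m <- data.table::month(dates)
  y <- data.table::year(dates)
  out <- rep(NA_integer_, length(dates))
  out[m >= 8L] <- y[m >= 8L]
  out[m <= 2L] <- y[m <= 2L] - 1L
  out
}

# POSIXct (UTC) from Date plus seconds-of-day.
posix_from_day <- function(dates, secs) {
  as.POSIXct(as.numeric(as.POSIXct(dates, tz = "UTC")) + secs,
             origin = "1970-01-01", tz = "UTC")
}

# Calendar date of a POSIXct without timezone lookups (UTC storage).
date_of <- function(ts) {
  as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
       call. = FALSE)
}
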
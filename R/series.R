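#' Daily colony-attendance series
#'
#' Counts, per calendar date, how many penguins entered the colony. The
#' default counts *distinct* marked individuals (a bird legitimately
#' crossing twice more than 40 min apart still counts once); raw incoming
#' crossing counts are available via `count = "crossings"`. Dates with no
#' crossings between the first and last observed date are present with
#' count 0, so the series is contiguous.
#'
#' @param records Cleaned crossing `data.table` (incoming stream).
#' @param count `"individuals"` (distinct ids per date, default) or
#'   `"crossings"`.
#' @return A `data.table` with columns `date` and `n` (one row per date,
#'   contiguous, zero-filled); empty input gives an empty series.
#' @export
daily_attendance <- function(records, count = c("individuals", "crossings")) {
  count <- match.arg(count)
  if (nrow(records) == 0L)
    return(data.table(date = as.Date(character()), n = integer()))
  dt <- data.table(date = date_of(records$timestamp),
                   transponder_id = records$transponder_id)
  agg <- if (count == "individuals") {
    dt[, .(n = uniqueN(transponder_id)), by = date]
  } else {
    dt[, .(n = .N), by = date]
  }
  full <- data.table(date = seq(min(agg$date), max(agg$date), by = "day"))
  out <- agg[full, on = "date"]
  out[is.na(n), n := 0L]
  data.table::setorder(out, date)
  out[]
}

#' Daily nest-occupancy series
#'
#' Counts distinct nests recorded as occupied on each check date. Dates are
#' not zero-filled: occupancy is only known on check dates.
#'
#' @param nest_checks Nest-check `data.table` (`date`, `nest_id`, `status`).
#' @return A `data.table` with columns `date` and `n_nests_occupied`.
#' @export
daily_occupancy <- function(nest_checks) {
  if (nrow(nest_checks) == 0L)
    return(data.table(date = as.Date(character()), n_nests_occupied = integer()))
  out <- nest_checks[status == "occupied",
                     .(n_nests_occupied = uniqueN(nest_id)), by = date]
  data.table::setorder(out, date)
  out[]
}

#' Mean annual attendance pattern
#'
#' Collapses a multi-year daily series onto day-of-year: for each day
#' (Feb 29 folded into Feb 28) the mean and SD of the counts across years.
#' With a single year of data the SD is reported as missing.
#'
#' @param series Daily series from [daily_attendance()] (columns `date`,
#'   `n`).
#' @return A `data.table` with columns `doy`, `mean_n`, `sd_n`, `n_years`.
#' @export
annual_mean_series <- function(series) {
  if (nrow(series) == 0L)
    return(data.table(doy = integer(), mean_n = numeric(), sd_n = numeric(),
                      n_years = integer()))
  dt <- data.table(doy = doy_nonleap(series$date),
                   year = data.table::year(series$date), n = series$n)
  # Feb 29 folds onto Feb 28: average within year first so each year
  # contributes one value per doy
  dt <- dt[, .(n = mean(n)), by = .(year, doy)]
  out <- dt[, .(mean_n = mean(n),
                sd_n = if (.N > 1L) sd(n) else NA_real_,
                n_years = .N), by = doy]
  data.table::setorder(out, doy)
  out[]
}
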
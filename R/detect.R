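#' Detector parameters for the autumn-window threshold rule
#'
#' The autumn breeding attempt (ABA) is detected per year from the daily
#' attendance series: it *starts* on the first day of a run of at least
#' `min_run_days` successive days on which attendance is at least
#' `start_multiplier` times the March minimum (the post-molt baseline), and
#' *ends* on the first subsequent day on which attendance has declined by at
#' least `end_decline_fraction` from the maximum recorded since the start,
#' provided no further qualifying run begins within the next `quiet_days`
#' days.
#'
#' @param start_multiplier Threshold multiplier on the March minimum
#'   (default 2; "at least twice" is inclusive).
#' @param min_run_days Length of the qualifying run in days (default 5,
#'   inclusive).
#' @param end_decline_fraction Decline fraction ending the window (default
#'   0.5, i.e. attendance at or below half the running maximum).
#' @param quiet_days Days that must pass without a new qualifying run for
#'   the window to end (default 14).
#' @param search_window_doy Length-2 integer day-of-year range searched for
#'   the start (default Apr 1 -- Jul 31).
#' @return A `detector_params` list.
#' @export
detector_params <- function(start_multiplier = 2,
                            min_run_days = 5L,
                            end_decline_fraction = 0.5,
                            quiet_days = 14L,
                            search_window_doy = c(91L, 212L)) {
  stopifnot(start_multiplier > 1, min_run_days >= 1,
            end_decline_fraction > 0, end_decline_fraction < 1,
            quiet_days >= 0, length(search_window_doy) == 2L)
  structure(list(start_multiplier = start_multiplier,
                 min_run_days = as.integer(min_run_days),
                 end_decline_fraction = end_decline_fraction,
                 quiet_days = as.integer(quiet_days),
                 search_window_doy = as.integer(search_window_doy)),
            class = "detector_params")
}

#' March minimum attendance
#'
#' The lowest daily count over March 1--31 of the given year: the post-molt
#' baseline that anchors the start threshold.
#'
#' @param series Daily attendance series (`date`, `n`).
#' @param year Calendar year.
#' @return Integer minimum count.
#' @export
march_minimum <- function(series, year) {
  mar <- series[date >= as.Date(sprintf("%d-03-01", year)) &
                  date <= as.Date(sprintf("%d-03-31", year))]
  if (nrow(mar) == 0L)
    stop(sprintf("no March %d coverage in attendance series: cannot anchor threshold", year),
         call. = FALSE)
  if (nrow(mar) < 31L)
    warning(sprintf("March %d only partially covered (%d days)", year, nrow(mar)))
  min(mar$n)
}

# Logical vector: does a qualifying run (>= min_run_days successive counts
# >= threshold) begin at each index? Incomplete tail windows do not qualify.
run_starts <- function(n, threshold, min_run_days) {
  ok <- as.integer(n >= threshold)
  rs <- data.table::frollsum(ok, min_run_days, align = "left") == min_run_days
  rs[is.na(rs)] <- FALSE
  rs
}

#' Detect the start of the autumn attendance window
#'
#' First date in the search window beginning `min_run_days` successive days
#' of attendance at or above `threshold`.
#'
#' @param series Daily attendance series for (at least) one year.
#' @param year Calendar year searched.
#' @param threshold Start threshold (see [aba_threshold()]).
#' @param params [detector_params()].
#' @return A `Date`, or `NULL` if no qualifying run exists (a valid
#'   outcome: not every year need show an autumn attempt).
#' @export
detect_start <- function(series, year, threshold, params = detector_params()) {
  rs <- run_starts(series$n, threshold, params$min_run_days)
  doy <- doy_nonleap(series$date)
  in_win <- data.table::year(series$date) == year &
    doy >= params$search_window_doy[1] & doy <= params$search_window_doy[2]
  idx <- which(rs & in_win)
  if (!length(idx)) return(NULL)
  series$date[idx[1L]]
}

#' Detect the end of the autumn attendance window
#'
#' First date after `start` on which attendance is at or below
#' `end_decline_fraction` times the running maximum since `start`, with no
#' qualifying run (the start criterion re-applied) beginning within the
#' following `quiet_days` days. The returned date is exclusive: the window
#' is `[start, end)`.
#'
#' @param series Daily attendance series.
#' @param start Window start date (from [detect_start()]).
#' @param threshold Start threshold (re-used for the "no further peak"
#'   check).
#' @param params [detector_params()].
#' @return A list with `end` (Date, exclusive) and `open_ended` (TRUE when
#'   the series ran out before the criterion was met, in which case `end`
#'   is the day after the last observation).
#' @export
detect_end <- function(series, start, threshold, params = detector_params()) {
  i0 <- match(start, series$date)
  if (is.na(i0)) stop("start date not present in series", call. = FALSE)
  nvec <- series$n
  nr <- length(nvec)
  rs <- run_starts(nvec, threshold, params$min_run_days)
  runmax <- cummax(nvec[i0:nr])
  for (e in seq(i0 + 1L, length.out = max(0L, nr - i0))) {
    rm_ <- runmax[e - i0]  # max over [start, e)
    if (nvec[e] <= params$end_decline_fraction * rm_) {
      quiet <- seq(e, min(e + params$quiet_days - 1L, nr))
      if (!any(rs[quiet])) {
        return(list(end = series$date[e], open_ended = FALSE))
      }
    }
  }
  list(end = series$date[nr] + 1L, open_ended = TRUE)
}

#' Segment an autumn window into peaks and troughs
#'
#' Within the envelope `[start, end)`, maximal runs of days at or above the
#' threshold become peaks (`first_peak`, `second_peak`, `peak_3`, ... in
#' order) and the sub-threshold runs between two peaks become troughs.
#' Peaks and troughs tile the envelope without overlap (a leading or
#' trailing sub-threshold run -- possible only for open-ended windows -- is
#' labelled `trough` as well).
#'
#' @param series Daily attendance series.
#' @param start,end Envelope bounds (end exclusive).
#' @param threshold Start threshold.
#' @return A `data.table` of windows: `kind`, `start`, `end`,
#'   `duration_days`, `peak_max`.
#' @export
segment_peaks <- function(series, start, end, threshold) {
  seg <- series[date >= start & date < end]
  if (nrow(seg) == 0L)
    return(data.table(kind = character(), start = as.Date(character()),
                      end = as.Date(character()), duration_days = integer(),
                      peak_max = numeric()))
  r <- rle(seg$n >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peak_i <- 0L
  kind <- character(length(r$lengths))
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) {
      peak_i <- peak_i + 1L
      kind[j] <- if (peak_i == 1L) "first_peak"
                 else if (peak_i == 2L) "second_peak"
                 else sprintf("peak_%d", peak_i)
    } else {
      kind[j] <- "trough"
    }
  }
  data.table(kind = kind,
             start = seg$date[starts],
             end = seg$date[ends] + 1L,
             duration_days = r$lengths,
             peak_max = vapply(seq_along(starts), function(j)
               as.numeric(max(seg$n[starts[j]:ends[j]])), numeric(1)))
}

#' Start threshold for a year
#'
#' `start_multiplier` times the March minimum, floored at 1 so that a
#' zero-attendance March (colony absent) cannot make every day qualify.
#'
#' @param series Daily attendance series.
#' @param year Calendar year.
#' @param params [detector_params()].
#' @return Numeric threshold.
#' @export
aba_threshold <- function(series, year, params = detector_params()) {
  max(params$start_multiplier * march_minimum(series, year), 1)
}

#' Detect and segment the autumn window for one year
#'
#' Convenience wrapper: computes the threshold from the March minimum, runs
#' [detect_start()], [detect_end()] and [segment_peaks()], and returns all
#' windows (envelope plus segments) for the year.
#'
#' @param series Daily attendance series covering March and the search
#'   window of `year`.
#' @param year Calendar year.
#' @param params [detector_params()].
#' @return A `data.table` of windows (`year`, `kind`, `start`, `end`,
#'   `duration_days`, `peak_max`, `threshold`, `open_ended`), or `NULL`
#'   when no window is detected.
#' @export
detect_aba <- function(series, year, params = detector_params()) {
  thr <- aba_threshold(series, year, params)
  s <- detect_start(series, year, thr, params)
  if (is.null(s)) return(NULL)
  e <- detect_end(series, s, thr, params)
  segs <- segment_peaks(series, s, e$end, thr)
  env <- data.table(kind = "aba_envelope", start = s, end = e$end,
                    duration_days = as.integer(e$end - s),
                    peak_max = max(segs$peak_max))
  out <- rbindlist(list(env, segs))
  out[, `:=`(year = year, threshold = thr, open_ended = e$open_ended)]
  data.table::setcolorder(out, c("year", "kind", "start", "end",
                                 "duration_days", "peak_max", "threshold",
                                 "open_ended"))
  out[]
}

#' Detect autumn windows for every year of a series
#'
#' Runs [detect_aba()] for each calendar year with March coverage; years
#' with no qualifying window or no March data are skipped with a message.
#'
#' @param series Daily attendance series.
#' @param params [detector_params()].
#' @param years Years to scan (default: all years present in the series).
#' @return A `data.table` of windows across years.
#' @export
detect_aba_all <- function(series, params = detector_params(), years = NULL) {
  years <- years %||% sort(unique(data.table::year(series$date)))
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    w <- tryCatch(detect_aba(series, years[i], params), error = function(e) {
      message(sprintf("year %d skipped: %s", years[i], conditionMessage(e)))
      NULL
    })
    if (is.null(w)) {
      message(sprintf("year %d: no autumn window detected", years[i]))
    }
    out[[i]] <- w
  }
  rbindlist(out[!vapply(out, is.null, logical(1))])
}

#' Summarize detected windows across years
#'
#' Per window kind: number of years, mean and SD (n-1 denominator; missing
#' for a single year) of durations, mean start day-of-year, and the range of
#' start dates.
#'
#' @param windows Window `data.table` from [detect_aba_all()].
#' @return A `data.table` with one row per kind.
#' @export
summarize_windows <- function(windows) {
  if (nrow(windows) == 0L)
    return(data.table(kind = character(), n_years = integer(),
                      mean_duration = numeric(), sd_duration = numeric(),
                      mean_start_doy = numeric(),
                      earliest_start = as.Date(character()),
                      latest_start = as.Date(character())))
  out <- windows[, .(
    n_years = uniqueN(year),
    mean_duration = mean(duration_days),
    sd_duration = if (.N > 1L) sd(duration_days) else NA_real_,
    mean_start_doy = mean(doy_nonleap(start)),
    earliest_start = min(start),
    latest_start = max(start)
  ), by = kind]
  data.table::setorder(out, kind)
  out[]
}
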
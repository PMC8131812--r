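# Shared fixtures: compact builders for crossing records and attendance
# series, and a small simulation config used across test files.

make_records <- function(id, time, mass = 1100, direction = "in") {
  data.table::data.table(
    transponder_id = id,
    timestamp = as.POSIXct(time, tz = "UTC"),
    mass_g = as.numeric(mass),
    direction = direction
  )
}

make_register <- function(ids, sex = "F", year_marked = 2000L,
                          marked_as = "fledgling") {
  data.table::data.table(transponder_id = ids, sex = sex,
                         year_marked = as.integer(year_marked),
                         marked_as = marked_as)
}

# Daily series for one calendar year from a default level plus overrides:
# set_counts(list(c("2003-04-27", "2003-05-13", 25), ...)) style.
make_series <- function(year, default = 10L, spans = list()) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- rep(as.integer(default), length(dates))
  for (sp in spans) {
    i <- dates >= as.Date(sp[[1]]) & dates <= as.Date(sp[[2]])
    n[i] <- as.integer(sp[[3]])
  }
  data.table::data.table(date = dates, n = n)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_individuals = 60, years = 2003:2004, seed = 7), list(...))
  do.call(sim_config, args)
}

# Independent brute-force oracle for the anchored-greedy deduplication:
# per individual, walk records chronologically keeping a record only when
# >= window minutes after the last kept one.
dedup_oracle <- function(records, window_min = 40) {
  dt <- data.table::copy(records)
  data.table::setorder(dt, transponder_id, timestamp)
  keep <- logical(nrow(dt))
  for (id in unique(dt$transponder_id)) {
    idx <- which(dt$transponder_id == id)
    last <- -Inf
    for (i in idx) {
      ti <- as.numeric(dt$timestamp[i])
      if (ti - last >= window_min * 60) {
        keep[i] <- TRUE
        last <- ti
      }
    }
  }
  out <- dt[keep]
  data.table::setorder(out, timestamp, transponder_id)
  out
}
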
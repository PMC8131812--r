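#' Read gateway crossing records from CSV
#'
#' Expects columns `transponder_id`, `timestamp` (ISO-8601 local time),
#' `mass_g`, `direction` (`in`/`out`). Rows that fail to parse (bad
#' timestamp, non-numeric mass, unknown direction) are never silently
#' dropped: they are returned in a `rejects` table with a reason per row.
#'
#' @param path CSV file path.
#' @return A list with `records` (a `data.table`: `transponder_id`,
#'   `timestamp` POSIXct, `mass_g` numeric with `NA` for missing,
#'   `direction`) and `rejects` (offending raw rows plus a `reason` column).
#' @export
read_crossings <- function(path) {
  if (!file.exists(path)) stop("crossings file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, colClasses = "character")
  need <- c("transponder_id", "timestamp", "mass_g", "direction")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("crossings file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
                   tz = "UTC")
  alt <- is.na(ts)
  if (any(alt))
    ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%d %H:%M:%OS",
                                   tz = "UTC"), tz = "UTC")
  mass <- suppressWarnings(as.numeric(raw$mass_g))
  bad_mass <- !is.na(raw$mass_g) & raw$mass_g != "" & is.na(mass)
  bad <- is.na(ts) | bad_mass | !(raw$direction %in% c("in", "out"))
  reason <- character(nrow(raw))
  reason[!(raw$direction %in% c("in", "out"))] <- "bad direction"
  reason[bad_mass] <- "unparseable mass"
  reason[is.na(ts)] <- "unparseable timestamp"
  rejects <- raw[bad][, reason := reason[bad]]
  records <- data.table(transponder_id = raw$transponder_id[!bad],
                        timestamp = ts[!bad],
                        mass_g = mass[!bad],
                        direction = raw$direction[!bad])
  list(records = records, rejects = rejects)
}

#' Read an individual register from CSV
#'
#' Expects columns `transponder_id`, `sex` (`F`/`M`/`unknown`),
#' `year_marked`, `marked_as` (`fledgling`/`adult`). Duplicate transponder
#' ids are an error.
#'
#' @param path CSV file path.
#' @return A `data.table` register.
#' @export
read_register <- function(path) {
  if (!file.exists(path)) stop("register file not found: ", path, call. = FALSE)
  reg <- data.table::fread(path, colClasses = list(
    character = c("transponder_id", "sex", "marked_as"),
    integer = "year_marked"))
  if (anyDuplicated(reg$transponder_id))
    stop("register contains duplicate transponder ids", call. = FALSE)
  reg
}

#' Read nest-check records from CSV
#'
#' Expects columns `date`, `nest_id`, `occupant_ids` (semicolon-joined) and
#' `status`.
#'
#' @param path CSV file path.
#' @return A `data.table` with `date` parsed to `Date`.
#' @export
read_nest_checks <- function(path) {
  if (!file.exists(path)) stop("nest-check file not found: ", path, call. = FALSE)
  nc <- data.table::fread(path, colClasses = "character")
  nc[, date := as.Date(date)]
  nc
}

#' Keep only crossings of registered individuals
#'
#' @param records Crossing `data.table`.
#' @param register Individual register (needs `transponder_id`).
#' @return Records whose `transponder_id` appears in the register, original
#'   order preserved. An empty register triggers a warning and returns an
#'   empty table.
#' @export
filter_marked <- function(records, register) {
  if (nrow(register) == 0L) {
    warning("empty register: all crossings removed")
    return(records[0L])
  }
  records[transponder_id %chin% register$transponder_id]
}

#' Keep only incoming crossings
#'
#' Many birds enter the colony over the monitored track but leave by other
#' routes, so only incoming crossings form the analysis stream.
#'
#' @param records Crossing `data.table`.
#' @return Records with `direction == "in"`.
#' @export
filter_incoming <- function(records) {
  records[direction == "in"]
}

#' Remove out-of-range body masses
#'
#' Retains masses in `[low_g, high_g]` inclusive: the bounds read "under"
#' and "over", so exactly-at-bound masses stay. Missing masses are retained
#' by default (the filter guards against implausible reads, it is not a
#' completeness requirement).
#'
#' @param records Crossing `data.table`.
#' @param low_g,high_g Plausible body-mass bounds in grams.
#' @param drop_missing Drop records with missing mass instead of keeping
#'   them.
#' @return Filtered records.
#' @export
filter_mass <- function(records, low_g = 700, high_g = 1700,
                        drop_missing = FALSE) {
  ok <- records$mass_g >= low_g & records$mass_g <= high_g
  ok[is.na(ok)] <- !drop_missing
  records[ok]
}

#' Remove within-window repeat crossings of the same individual
#'
#' Gateway reads of one individual less than `window_min` minutes apart are
#' pseudo-replicates (a bird lingering on the platform). Per individual, a
#' greedy chronological scan keeps a crossing only if it is at least
#' `window_min` minutes after that individual's last *kept* crossing; the
#' first crossing is always kept. Records of different individuals never
#' interact. The scan is deterministic and order-independent: input is
#' sorted by (individual, time) internally and returned in chronological
#' order.
#'
#' @param records Crossing `data.table`.
#' @param window_min Minimum separation in minutes (default 40).
#' @return Deduplicated records sorted by (`timestamp`, `transponder_id`).
#' @export
dedup_crossings <- function(records, window_min = 40) {
  if (nrow(records) <= 1L) return(data.table::copy(records))
  dt <- data.table::copy(records)
  data.table::setorder(dt, transponder_id, timestamp)
  tsec <- as.numeric(dt$timestamp)
  wsec <- window_min * 60
  id <- dt$transponder_id
  nr <- nrow(dt)
  new_id <- c(TRUE, id[-1L] != id[-nr])
  gap <- c(Inf, tsec[-1L] - tsec[-nr])
  # a crossing >= window after its immediate predecessor is always kept:
  # the last kept crossing is no later than the predecessor
  anchor <- new_id | gap >= wsec
  keep <- rep(TRUE, nr)
  lastkept <- tsec
  for (i in which(!anchor)) {
    if (tsec[i] - lastkept[i - 1L] >= wsec) {
      lastkept[i] <- tsec[i]
    } else {
      keep[i] <- FALSE
      lastkept[i] <- lastkept[i - 1L]
    }
  }
  out <- dt[keep]
  data.table::setorder(out, timestamp, transponder_id)
  out
}

#' Clean a crossing log for analysis
#'
#' Applies the standard filter chain to raw gateway records: registered
#' individuals only, incoming crossings only, plausible body masses, then
#' 40-min deduplication -- so that deduplication operates on the
#' analysis-relevant incoming stream. The order is overridable and each
#' stage's removals are tallied in an audit report.
#'
#' @param records Crossing `data.table` (e.g. `read_crossings(path)$records`).
#' @param register Individual register.
#' @param dedup_min Deduplication window in minutes.
#' @param mass_low_g,mass_high_g Body-mass bounds in grams.
#' @param drop_missing_mass Drop missing-mass records at the mass stage.
#' @param stage_order Character vector permuting
#'   `c("marked", "incoming", "mass", "dedup")`.
#' @return A list with `records` (the cleaned stream, chronological) and
#'   `report`, a `cleaning_report`: `n_input`, `n_removed_unmarked`,
#'   `n_removed_direction`, `n_removed_mass`, `n_removed_dedup`,
#'   `n_output` (and the parameters used). `n_output` always equals
#'   `n_input` minus the removals.
#' @export
#' @examples
#' sim <- simulate_colony(sim_config(n_individuals = 30, years = 2003, seed = 3))
#' cl <- clean_crossings(sim$crossings, sim$individuals)
#' cl$report$n_removed_dedup == sim$truth$audit$n_dup
clean_crossings <- function(records, register, dedup_min = 40,
                            mass_low_g = 700, mass_high_g = 1700,
                            drop_missing_mass = FALSE,
                            stage_order = c("marked", "incoming", "mass", "dedup")) {
  if (!setequal(stage_order, c("marked", "incoming", "mass", "dedup")))
    stop("stage_order must be a permutation of marked, incoming, mass, dedup",
         call. = FALSE)
  removed <- c(marked = 0L, incoming = 0L, mass = 0L, dedup = 0L)
  cur <- records
  for (st in stage_order) {
    before <- nrow(cur)
    cur <- switch(st,
      marked = filter_marked(cur, register),
      incoming = filter_incoming(cur),
      mass = filter_mass(cur, mass_low_g, mass_high_g, drop_missing_mass),
      dedup = dedup_crossings(cur, dedup_min))
    removed[[st]] <- before - nrow(cur)
  }
  if (!"dedup" %in% stage_order[length(stage_order)]) {
    # ensure chronological output even if dedup was not last
    data.table::setorder(cur, timestamp, transponder_id)
  }
  report <- structure(list(
    n_input = nrow(records),
    n_removed_unmarked = removed[["marked"]],
    n_removed_direction = removed[["incoming"]],
    n_removed_mass = removed[["mass"]],
    n_removed_dedup = removed[["dedup"]],
    n_output = nrow(cur),
    params = list(dedup_min = dedup_min, mass_low_g = mass_low_g,
                  mass_high_g = mass_high_g,
                  drop_missing_mass = drop_missing_mass,
                  stage_order = stage_order)
  ), class = "cleaning_report")
  list(records = cur, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input    %8d\n", x$n_input))
  cat(sprintf("  unmarked %8d removed\n", x$n_removed_unmarked))
  cat(sprintf("  outgoing %8d removed\n", x$n_removed_direction))
  cat(sprintf("  mass     %8d removed\n", x$n_removed_mass))
  cat(sprintf("  dedup    %8d removed\n", x$n_removed_dedup))
  cat(sprintf("  output   %8d\n", x$n_output))
  invisible(x)
}
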
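#' Generate a marked-individual register
#'
#' Draws the simulated population: transponder ids, sexes, starting ages
#' (from `config$age_distribution`) and marking history. Fledgling-marked
#' birds have `year_marked` equal to their birth year; adult-marked birds
#' (a configurable fraction, only possible for ages >= 3) are assigned
#' `year_marked` so that the standard age rule -- years since marking plus a
#' 3-year maturation allowance -- reproduces their true age.
#'
#' Uses the current RNG state; seed via [simulate_colony()] or `set.seed()`
#' for reproducibility.
#'
#' @param config A [sim_config()] object.
#' @return A `data.table` with columns `transponder_id`, `sex` (`"F"`/`"M"`),
#'   `year_marked`, `marked_as` (`"fledgling"`/`"adult"`) and `age_start`
#'   (true age in the first simulated year; internal convenience, not part
#'   of the on-disk register schema).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  empty <- data.table(transponder_id = character(), sex = character(),
                      year_marked = integer(), marked_as = character(),
                      age_start = integer())
  if (n == 0L) return(empty)
  y0 <- min(config$years)
  ages <- sample(as.integer(names(config$age_distribution)), n,
                 replace = TRUE, prob = config$age_distribution)
  sex <- ifelse(runif(n) < config$sex_ratio, "F", "M")
  adult <- runif(n) < config$adult_marked_fraction & ages >= 3L
  data.table(
    transponder_id = sprintf("T%05d", seq_len(n)),
    sex = sex,
    year_marked = as.integer(ifelse(adult, y0 - (ages - 3L), y0 - ages)),
    marked_as = ifelse(adult, "adult", "fledgling"),
    age_start = ages
  )
}

# Calibrate the logistic age model of ABA attendance: find (intercept,
# slope) such that the population-mean attendance probability equals
# base_prob and the expected attendee-minus-nonattendee mean-age gap equals
# age_effect. The gap depends only on centred ages, so one calibration
# serves every simulated year (the whole cohort ages together).
calibrate_attendance_model <- function(ages, base_prob, age_effect) {
  if (base_prob <= 0 || base_prob >= 1) {
    if (age_effect > 0)
      stop("aba_age_effect unattainable when aba_base_prob is 0 or 1",
           call. = FALSE)
    return(list(intercept = stats::qlogis(min(max(base_prob, 1e-12), 1 - 1e-12)),
                slope = 0))
  }
  z <- ages - mean(ages)
  if (age_effect == 0 || all(z == 0)) {
    if (age_effect > 0)
      stop("aba_age_effect unattainable: no age variation in population",
           call. = FALSE)
    return(list(intercept = stats::qlogis(base_prob), slope = 0))
  }
  solve_intercept <- function(b) {
    uniroot(function(a) mean(plogis(a + b * z)) - base_prob,
            c(-40, 40), tol = 1e-10)$root
  }
  gap_of <- function(b) {
    p <- plogis(solve_intercept(b) + b * z)
    sum(p * z) / sum(p) - sum((1 - p) * z) / sum(1 - p)
  }
  b_hi <- 12
  if (gap_of(b_hi) < age_effect)
    stop(sprintf(paste0("aba_age_effect = %.2f yr is unattainable for this ",
                        "age distribution and aba_base_prob = %.2f"),
                 age_effect, base_prob), call. = FALSE)
  b <- uniroot(function(b) gap_of(b) - age_effect, c(0, b_hi), tol = 1e-8)$root
  list(intercept = solve_intercept(b), slope = b)
}

# Realized ABA window for one year: whole-block start jitter plus
# per-segment duration jitter (integer days, floors keep segments >= 3 d).
draw_aba_windows <- function(config, year) {
  s_jit <- round(rnorm(1, 0, config$window_jitter_sd_days))
  jd <- function(mu) {
    if (config$duration_jitter_sd_days == 0) return(as.integer(round(mu)))
    max(3L, as.integer(round(rnorm(1, mu, config$duration_jitter_sd_days))))
  }
  d1 <- jd(config$aba_first_peak[2])
  dt_ <- jd(config$aba_trough_duration)
  d2 <- jd(config$aba_second_peak[2])
  s <- date_from_doy(year, config$aba_first_peak[1]) + s_jit
  data.table(
    year = year,
    kind = c("aba_envelope", "first_peak", "trough", "second_peak"),
    start = c(s, s, s + d1, s + d1 + dt_),
    end = c(s + d1 + dt_ + d2, s + d1, s + d1 + dt_, s + d1 + dt_ + d2)
  )
}

rtrunc_mass <- function(k, mean_g, sd_g, lo = 700, hi = 1700) {
  plo <- stats::pnorm(lo, mean_g, sd_g)
  phi <- stats::pnorm(hi, mean_g, sd_g)
  stats::qnorm(plo + runif(k) * (phi - plo), mean_g, sd_g)
}

routlier_mass <- function(k) {
  # uniform over [400, 699.9] and [1700.1, 2200]: strictly outside the
  # retained range even after rounding masses to 0.1 g
  x <- runif(k, 0, 799.8)
  ifelse(x < 299.9, 400 + x, 1700.1 + (x - 299.9))
}

#' Simulate gateway crossing records with ground truth
#'
#' The core individual-based generator. Each individual, on each day, comes
#' ashore with a season-dependent probability: a post-molt March baseline,
#' a quiet at-sea winter (Apr--Jul, reached through a one-week early-April
#' taper), a spring/summer breeding season (Aug--Feb) in which breeders
#' visit frequently, and -- for birds attending that year's autumn breeding
#' attempt -- high visit rates during the two courtship peaks and a low rate
#' during the prelaying-exodus trough. ABA attendance is logistic in age,
#' calibrated so the expected attendee/non-attendee mean-age gap equals
#' `config$aba_age_effect`; every attendee is guaranteed at least one
#' incoming crossing inside each realized peak.
#'
#' Each visit yields one incoming crossing at a dusk arrival time
#' (18:00--22:00). On top of the true visits the generator injects, at the
#' configured rates, the three artefact classes the cleaning module removes:
#' extra reads less than 40 min after a visit, outgoing crossings, and
#' unregistered-bird reads. Out-of-range body masses are injected only on
#' primary incoming reads that carry no duplicate, so that each injected
#' artefact is removed by exactly one cleaning stage and the cleaning audit
#' is exactly determined (see the `audit` element of the returned truth).
#'
#' @param population Register from [generate_population()].
#' @param config A [sim_config()] object.
#' @return A list with elements `crossings` (a `data.table`:
#'   `transponder_id`, `timestamp` (POSIXct), `mass_g`, `direction`) sorted
#'   by time, and `truth`, itself a list: `windows` (realized ABA envelope
#'   and segments per year), `flags` (per year and individual: breeder and
#'   ABA-attendee status), and `audit` (exact injected counts of unmarked,
#'   outgoing, out-of-range-mass and within-40-min records among the
#'   analysis stream).
#' @export
generate_crossings <- function(population, config) {
  validate_sim_config(config)
  years <- sort(config$years)
  empty_truth <- list(
    windows = data.table(year = integer(), kind = character(),
                         start = as.Date(character()), end = as.Date(character())),
    flags = data.table(year = integer(), transponder_id = character(),
                       breeder = logical(), aba_attendee = logical()),
    audit = list(n_visits = 0L, n_unmarked = 0L, n_out = 0L,
                 n_mass_outlier = 0L, n_dup = 0L)
  )
  if (nrow(population) == 0L) {
    return(list(crossings = data.table(transponder_id = character(),
                                       timestamp = as.POSIXct(character(), tz = "UTC"),
                                       mass_g = numeric(), direction = character()),
                truth = empty_truth))
  }

  n <- nrow(population)
  days <- seq(as.Date(sprintf("%d-01-01", min(years))),
              as.Date(sprintf("%d-02-28", max(years) + 1L)), by = "day")
  nd <- length(days)
  mon <- data.table::month(days)
  mday <- data.table::mday(days)
  seas_yr <- season_start_year(days)

  ## realized ABA windows and per-year flags
  windows <- rbindlist(lapply(years, function(y) draw_aba_windows(config, y)))
  cal <- calibrate_attendance_model(population$age_start, config$aba_base_prob,
                                    config$aba_age_effect)
  z <- population$age_start - mean(population$age_start)
  p_attend <- plogis(cal$intercept + cal$slope * z)
  flags <- rbindlist(lapply(years, function(y) data.table(
    year = y,
    transponder_id = population$transponder_id,
    breeder = runif(n) < config$breeder_prob,
    aba_attendee = runif(n) < p_attend
  )))

  ## daily visit probability matrix (individuals x days)
  base_day <- numeric(nd)
  base_day[mon == 3L] <- config$baseline_daily_visit_prob
  base_day[mon >= 5L & mon <= 7L] <- config$winter_visit_prob
  base_day[mon >= 8L | mon <= 2L] <- config$baseline_daily_visit_prob
  apr <- mon == 4L
  ramp <- pmax(0, 1 - mday[apr] / 8)  # taper over Apr 1-7, then winter level
  base_day[apr] <- config$winter_visit_prob +
    (config$baseline_daily_visit_prob - config$winter_visit_prob) * ramp
  P <- matrix(rep(base_day, each = n), nrow = n)

  for (y in years) {
    br <- flags[year == y, breeder]
    cols <- which(!is.na(seas_yr) & seas_yr == y)
    if (length(cols)) P[br, cols] <- config$breeding_season_visit_prob
    att <- flags[year == y, aba_attendee]
    w <- windows[year == y]
    for (k in c("first_peak", "second_peak")) {
      cols <- which(days >= w[kind == k, start] & days < w[kind == k, end])
      P[att, cols] <- config$aba_peak_visit_prob
    }
    cols <- which(days >= w[kind == "trough", start] & days < w[kind == "trough", end])
    P[att, cols] <- config$aba_trough_visit_prob
  }

  hit <- which(matrix(runif(n * nd), nrow = n) < P, arr.ind = TRUE)
  visits <- data.table(ind = hit[, 1L], day = hit[, 2L])

  ## guarantee every attendee one visit inside each realized peak
  forced <- rbindlist(lapply(years, function(y) {
    att <- which(flags[year == y, aba_attendee])
    if (!length(att)) return(NULL)
    w <- windows[year == y]
    rbindlist(lapply(c("first_peak", "second_peak"), function(k) {
      cols <- which(days >= w[kind == k, start] & days < w[kind == k, end])
      data.table(ind = att,
                 day = cols[sample.int(length(cols), length(att), replace = TRUE)])
    }))
  }))
  visits <- unique(rbindlist(list(visits, forced)))
  data.table::setorder(visits, ind, day)
  nv <- nrow(visits)

  ## primary incoming reads at dusk arrival times
  day0 <- as.numeric(as.POSIXct(days[1], tz = "UTC"))
  tsec <- day0 + (visits$day - 1L) * 86400 + 64800 + runif(nv) * 14400
  outlier <- runif(nv) < config$outlier_mass_rate
  ndup <- rpois(nv, config$dup_crossing_rate)
  ndup[outlier] <- 0L  # keep artefact classes disjoint (exact audit)
  mass <- numeric(nv)
  mass[!outlier] <- rtrunc_mass(sum(!outlier), config$mass_mean_g, config$mass_sd_g)
  mass[outlier] <- routlier_mass(sum(outlier))
  rec_in <- data.table(id = population$transponder_id[visits$ind],
                       tsec = tsec, mass_g = mass, direction = "in")

  ## within-40-min duplicate reads (always in-range mass, non-outlier parent)
  dup_parent <- rep.int(seq_len(nv), ndup)
  k <- length(dup_parent)
  rec_dup <- if (k) data.table(
    id = population$transponder_id[visits$ind[dup_parent]],
    tsec = tsec[dup_parent] + runif(k, 30, 2370),  # 0.5 to 39.5 min later
    mass_g = rtrunc_mass(k, config$mass_mean_g, config$mass_sd_g),
    direction = "in") else NULL

  ## outgoing crossings (departures 6-14 h after arrival)
  is_out <- runif(nv) < config$out_crossing_rate
  k <- sum(is_out)
  rec_out <- if (k) data.table(
    id = population$transponder_id[visits$ind[is_out]],
    tsec = tsec[is_out] + runif(k, 6, 14) * 3600,
    mass_g = rtrunc_mass(k, config$mass_mean_g, config$mass_sd_g),
    direction = "out") else NULL

  ## unregistered-bird reads
  k <- rpois(1, config$unmarked_rate * nv)
  rec_unk <- if (k) data.table(
    id = sprintf("UNK%04d", sample.int(50L, k, replace = TRUE)),
    tsec = day0 + (sample.int(nd, k, replace = TRUE) - 1L) * 86400 +
      64800 + runif(k) * 14400,
    mass_g = rtrunc_mass(k, config$mass_mean_g, config$mass_sd_g),
    direction = "in") else NULL

  crossings <- rbindlist(list(rec_in, rec_dup, rec_out, rec_unk))
  data.table::setorder(crossings, tsec, id)
  crossings <- crossings[, .(
    transponder_id = id,
    timestamp = as.POSIXct(tsec, origin = "1970-01-01", tz = "UTC"),
    mass_g = round(mass_g, 1),
    direction = direction
  )]

  truth <- list(
    windows = windows,
    flags = flags,
    audit = list(n_visits = nv,
                 n_unmarked = if (is.null(rec_unk)) 0L else nrow(rec_unk),
                 n_out = if (is.null(rec_out)) 0L else nrow(rec_out),
                 n_mass_outlier = sum(outlier),
                 n_dup = if (is.null(rec_dup)) 0L else nrow(rec_dup))
  )
  list(crossings = crossings, truth = truth)
}

#' Simulate nest-check records
#'
#' Emulates a long-term nest-monitoring program: nests are checked three
#' times a week (Mon/Wed/Fri) during the September--February breeding
#' season and once a week (Mondays) otherwise. Spring/summer breeders are
#' paired into nests and recorded as occupants on every check date of their
#' season; ABA attendees are likewise paired and recorded on the weekly
#' check dates falling inside the realized autumn window, producing the
#' autumn bump in nest occupancy.
#'
#' @param population Register from [generate_population()].
#' @param truth Truth object from [generate_crossings()].
#' @param config A [sim_config()] object.
#' @return A `data.table` with columns `date`, `nest_id`, `occupant_ids`
#'   (semicolon-joined transponder ids) and `status` (`"occupied"`).
#' @export
generate_nest_checks <- function(population, truth, config) {
  empty <- data.table(date = as.Date(character()), nest_id = character(),
                      occupant_ids = character(), status = character())
  if (nrow(truth$flags) == 0L) return(empty)
  years <- sort(unique(truth$flags$year))
  days <- seq(as.Date(sprintf("%d-01-01", min(years))),
              as.Date(sprintf("%d-02-28", max(years) + 1L)), by = "day")
  wday <- (as.integer(days) + 4L) %% 7L  # 0 = Sunday
  mon <- data.table::month(days)
  in_season <- mon >= 9L | mon <= 2L
  check <- (in_season & wday %in% c(1L, 3L, 5L)) | (!in_season & wday == 1L)
  check_dates <- days[check]

  pair_up <- function(ids, prefix) {
    if (!length(ids)) return(NULL)
    ids <- sample(ids)
    nn <- ceiling(length(ids) / 2)
    data.table(nest_id = sprintf("%s%03d", prefix, rep(seq_len(nn), each = 2)[seq_along(ids)]),
               transponder_id = ids)[, .(occupant_ids = paste(transponder_id, collapse = ";")),
                                     by = nest_id]
  }

  out <- vector("list", 2L * length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    fl <- truth$flags[year == y]
    nests <- pair_up(fl[breeder == TRUE, transponder_id], sprintf("Y%d-N", y))
    if (!is.null(nests)) {
      dts <- check_dates[check_dates >= as.Date(sprintf("%d-09-01", y)) &
                           check_dates <= as.Date(sprintf("%d-02-28", y + 1L))]
      out[[2L * i - 1L]] <- nests[CJ(nest_id = nest_id, date = dts), on = "nest_id"]
    }
    aba_nests <- pair_up(fl[aba_attendee == TRUE, transponder_id], sprintf("Y%d-A", y))
    if (!is.null(aba_nests)) {
      w <- truth$windows[year == y & kind == "aba_envelope"]
      dts <- check_dates[check_dates >= w$start & check_dates < w$end]
      if (length(dts))
        out[[2L * i]] <- aba_nests[CJ(nest_id = nest_id, date = dts), on = "nest_id"]
    }
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  res[, status := "occupied"]
  data.table::setorder(res, date, nest_id)
  res[, .(date, nest_id, occupant_ids, status)]
}

#' Run the full colony simulation
#'
#' Seeds the RNG (restoring its previous state on exit), draws the
#' population, crossing records and nest checks, and optionally writes the
#' standard CSV outputs plus machine-readable ground truth.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, writes `crossings.csv`,
#'   `individuals.csv`, `nest_checks.csv`, `truth_windows.csv`,
#'   `truth_flags.csv` and `truth_audit.json`. Identical config + seed
#'   yields byte-identical files.
#' @return (Invisibly when writing) a list with elements `crossings`,
#'   `individuals`, `nest_checks` and `truth`.
#' @export
#' @examples
#' sim <- simulate_colony(sim_config(n_individuals = 40, years = 2003:2004,
#'                                   seed = 42))
#' nrow(sim$crossings)
simulate_colony <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
  }
  population <- generate_population(config)
  gc_ <- generate_crossings(population, config)
  nest_checks <- generate_nest_checks(population, gc_$truth, config)
  sim <- list(crossings = gc_$crossings,
              individuals = population[, .(transponder_id, sex, year_marked, marked_as)],
              nest_checks = nest_checks,
              truth = gc_$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cr <- data.table::copy(sim$crossings)
    cr[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
    data.table::fwrite(cr, file.path(out_dir, "crossings.csv"))
    data.table::fwrite(sim$individuals, file.path(out_dir, "individuals.csv"))
    data.table::fwrite(sim$nest_checks, file.path(out_dir, "nest_checks.csv"))
    data.table::fwrite(sim$truth$windows, file.path(out_dir, "truth_windows.csv"))
    data.table::fwrite(sim$truth$flags, file.path(out_dir, "truth_flags.csv"))
    jsonlite::write_json(sim$truth$audit, file.path(out_dir, "truth_audit.json"),
                         auto_unbox = TRUE)
    return(invisible(sim))
  }
  sim
}
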
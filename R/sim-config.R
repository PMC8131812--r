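#' Simulation configuration for the colony-attendance generator
#'
#' Builds and validates the parameter set controlling the individual-based
#' simulator ([simulate_colony()] and friends). Defaults describe an
#' 11-year study of a large little-penguin colony monitored by an automated
#' gateway: a marked population of a few hundred birds, a spring/summer
#' (Aug--Feb) breeding season, a post-molt March period of moderate colony
#' attendance, a quiet at-sea winter (Apr--Jul), and an autumn breeding
#' attempt (ABA) made of two courtship peaks separated by a prelaying-exodus
#' trough, attended preferentially by older birds.
#'
#' @param n_individuals Number of marked individuals in the register.
#' @param years Calendar years simulated (one ABA window per year; the
#'   spring/summer season starting in the last year runs into the following
#'   February).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output files.
#' @param age_distribution Named numeric vector of probabilities over ages
#'   (years) at the start of the simulation; names are the ages. Default is
#'   a survivorship-like geometric taper over ages 2--15.
#' @param sex_ratio Fraction of females in `[0, 1]`.
#' @param adult_marked_fraction Fraction of individuals marked as adults
#'   (age then carries a 3-year maturation allowance) rather than at
#'   fledging.
#' @param breeder_prob Probability an individual breeds in a given
#'   spring/summer season (drawn independently per year).
#' @param baseline_daily_visit_prob Daily probability of coming ashore during
#'   the post-molt March period and for non-breeders during Aug--Feb.
#' @param winter_visit_prob Daily probability of coming ashore during the
#'   at-sea winter months (Apr--Jul) outside any ABA behaviour.
#' @param breeding_season_visit_prob Daily probability a breeder visits the
#'   colony during its Aug--Feb breeding season.
#' @param aba_first_peak Length-2 numeric `c(start_doy, duration)`: mean
#'   start day-of-year and duration (days) of the first autumn courtship
#'   peak.
#' @param aba_trough_duration Mean duration (days) of the prelaying-exodus
#'   trough between the two peaks.
#' @param aba_second_peak Length-2 numeric `c(start_doy, duration)` for the
#'   second peak. The start is informative only when jitter is zero; the
#'   realized second peak always follows the realized trough.
#' @param window_jitter_sd_days SD (days) of the integer year-to-year jitter
#'   applied to the whole ABA block start.
#' @param duration_jitter_sd_days SD (days) of the independent integer
#'   jitter applied to each segment duration (floored at 3 days).
#' @param aba_base_prob Population-mean probability that an individual
#'   attends the ABA in a given year.
#' @param aba_age_effect Target mean-age gap (years) between ABA attendees
#'   and non-attendees; attendance is logistic in age with the slope
#'   calibrated numerically each year to hit this gap in expectation.
#' @param aba_peak_visit_prob Daily visit probability for an ABA attendee on
#'   peak days.
#' @param aba_trough_visit_prob Daily visit probability for an ABA attendee
#'   on trough days.
#' @param dup_crossing_rate Expected number of extra gateway reads within
#'   40 min of a true visit (exercises the deduplication filter).
#' @param out_crossing_rate Probability a visit also produces an outgoing
#'   crossing (exercises the direction filter).
#' @param unmarked_rate Expected unregistered-bird crossings per true visit
#'   (exercises the register filter).
#' @param mass_mean_g,mass_sd_g Body-mass distribution (g) of valid reads;
#'   valid masses are truncated to `[700, 1700]` g.
#' @param outlier_mass_rate Probability a primary incoming read carries an
#'   out-of-range mass, drawn uniformly from `[400, 700)` or `(1700, 2200]`
#'   g (exercises the mass filter on both bounds).
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_colony()], [generate_population()],
#'   [generate_crossings()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, years = 2003:2005, seed = 1)
#' cfg$aba_base_prob
sim_config <- function(n_individuals = 332L,
                       years = 2003:2013,
                       seed = 1L,
                       age_distribution = NULL,
                       sex_ratio = 0.5,
                       adult_marked_fraction = 0.1,
                       breeder_prob = 0.4,
                       baseline_daily_visit_prob = 0.10,
                       winter_visit_prob = 0.005,
                       breeding_season_visit_prob = 0.25,
                       aba_first_peak = c(start_doy = 117, duration = 17),
                       aba_trough_duration = 10,
                       aba_second_peak = c(start_doy = 144, duration = 12),
                       window_jitter_sd_days = 5,
                       duration_jitter_sd_days = 2,
                       aba_base_prob = 0.76,
                       aba_age_effect = 2.5,
                       aba_peak_visit_prob = 0.5,
                       aba_trough_visit_prob = 0.02,
                       dup_crossing_rate = 0.10,
                       out_crossing_rate = 0.30,
                       unmarked_rate = 0.02,
                       mass_mean_g = 1100,
                       mass_sd_g = 150,
                       outlier_mass_rate = 0.01) {
  if (is.null(age_distribution)) {
    ages <- 2:15
    w <- 0.8^(ages - 2)
    age_distribution <- stats::setNames(w / sum(w), ages)
  }
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    years = as.integer(years),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    age_distribution = age_distribution,
    sex_ratio = sex_ratio,
    adult_marked_fraction = adult_marked_fraction,
    breeder_prob = breeder_prob,
    baseline_daily_visit_prob = baseline_daily_visit_prob,
    winter_visit_prob = winter_visit_prob,
    breeding_season_visit_prob = breeding_season_visit_prob,
    aba_first_peak = unname(aba_first_peak),
    aba_trough_duration = aba_trough_duration,
    aba_second_peak = unname(aba_second_peak),
    window_jitter_sd_days = window_jitter_sd_days,
    duration_jitter_sd_days = duration_jitter_sd_days,
    aba_base_prob = aba_base_prob,
    aba_age_effect = aba_age_effect,
    aba_peak_visit_prob = aba_peak_visit_prob,
    aba_trough_visit_prob = aba_trough_visit_prob,
    dup_crossing_rate = dup_crossing_rate,
    out_crossing_rate = out_crossing_rate,
    unmarked_rate = unmarked_rate,
    mass_mean_g = mass_mean_g,
    mass_sd_g = mass_sd_g,
    outlier_mass_rate = outlier_mass_rate
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks field types, probability ranges and duration constraints; errors
#' name the offending field.
#'
#' @param cfg A `sim_config` object (or bare list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  prob_fields <- c("sex_ratio", "adult_marked_fraction", "breeder_prob",
                   "baseline_daily_visit_prob", "winter_visit_prob",
                   "breeding_season_visit_prob", "aba_base_prob",
                   "aba_peak_visit_prob", "aba_trough_visit_prob",
                   "unmarked_rate", "outlier_mass_rate")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!num1(v) || v < 0 || v > 1) stop_config(f, "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$n_individuals) || length(cfg$n_individuals) != 1L ||
      is.na(cfg$n_individuals) || cfg$n_individuals < 0)
    stop_config("n_individuals", "must be a nonnegative count")
  if (length(cfg$years) < 1L || anyNA(cfg$years))
    stop_config("years", "must be one or more calendar years")
  p <- cfg$age_distribution
  if (!is.numeric(p) || is.null(names(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8)
    stop_config("age_distribution", "must be named probabilities summing to 1")
  if (any(as.integer(names(p)) < 0)) stop_config("age_distribution", "has negative ages")
  for (f in c("aba_first_peak", "aba_second_peak")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2L || v[2] < 1)
      stop_config(f, "must be c(start_doy, duration) with duration >= 1 day")
  }
  if (!num1(cfg$aba_trough_duration) || cfg$aba_trough_duration < 1)
    stop_config("aba_trough_duration", "must be >= 1 day")
  for (f in c("window_jitter_sd_days", "duration_jitter_sd_days",
              "dup_crossing_rate", "out_crossing_rate"))
    if (!num1(cfg[[f]]) || cfg[[f]] < 0) stop_config(f, "must be >= 0")
  if (!num1(cfg$mass_sd_g) || cfg$mass_sd_g <= 0)
    stop_config("mass_sd_g", "must be > 0")
  if (!num1(cfg$mass_mean_g) || cfg$mass_mean_g <= 0)
    stop_config("mass_mean_g", "must be > 0")
  if (!num1(cfg$aba_age_effect) || cfg$aba_age_effect < 0)
    stop_config("aba_age_effect", "must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals, years %d-%d, seed %s\n",
              x$n_individuals, min(x$years), max(x$years),
              if (is.null(x$seed)) "<none>" else x$seed))
  cat(sprintf("  ABA: peak1 doy %g (%g d), trough %g d, peak2 %g d; base prob %.2f, age effect %.1f yr\n",
              x$aba_first_peak[1], x$aba_first_peak[2], x$aba_trough_duration,
              x$aba_second_peak[2], x$aba_base_prob, x$aba_age_effect))
  invisible(x)
}
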
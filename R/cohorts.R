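#' Assign ages to registered individuals for a given year
#'
#' Fledgling-marked birds have known hatch year, so age is years since
#' marking. Adult-marked birds get a 3-year maturation allowance added to
#' their years since marking (the time for a fledgling to mature and return
#' to the colony as a breeder).
#'
#' @param register Individual register (`transponder_id`, `year_marked`,
#'   `marked_as`).
#' @param year Calendar year for which ages are computed.
#' @return A `data.table`: `transponder_id`, `year`, `age`.
#' @export
#' @examples
#' reg <- data.table::data.table(
#'   transponder_id = c("a", "b"), sex = c("F", "M"),
#'   year_marked = c(2005L, 2005L), marked_as = c("fledgling", "adult"))
#' assign_age(reg, 2010)  # ages 5 and 8
assign_age <- function(register, year) {
  if (any(year < register$year_marked))
    stop(sprintf("age undefined: year %d precedes year_marked for %d individual(s)",
                 year, sum(year < register$year_marked)), call. = FALSE)
  data.table(transponder_id = register$transponder_id,
             year = as.integer(year),
             age = as.integer(year - register$year_marked +
                                ifelse(register$marked_as == "adult", 3L, 0L)))
}

#' Spring/summer breeders per season from nest-check records
#'
#' An individual "bred during spring/summer" of season-year `y` if it
#' appears as a nest occupant on a check dated inside the Aug--Feb season
#' starting in calendar year `y`. Checks in the Mar--Jul nonbreeding months
#' (including autumn-window occupancy) never define breeders.
#'
#' @param nest_checks Nest-check `data.table` (`date`, `nest_id`,
#'   `occupant_ids` semicolon-joined, `status`).
#' @return A `data.table`: `year` (season start year), `transponder_id`.
#' @export
breeders_from_nest_checks <- function(nest_checks) {
  if (nrow(nest_checks) == 0L)
    return(data.table(year = integer(), transponder_id = character()))
  occ <- nest_checks[status == "occupied"]
  occ[, year := season_start_year(date)]
  occ <- occ[!is.na(year)]
  if (nrow(occ) == 0L)
    return(data.table(year = integer(), transponder_id = character()))
  out <- occ[, .(transponder_id = unlist(strsplit(occupant_ids, ";", fixed = TRUE))),
             by = year]
  unique(out[transponder_id != ""])[order(year, transponder_id)]
}

#' Classify breeders by autumn attendance
#'
#' For each year with a detected autumn envelope, splits that year's
#' spring/summer breeders into those with at least one cleaned incoming
#' crossing dated inside the envelope (`ss_and_aba`) and those without
#' (`ss_only`). The two sets partition the breeders; non-breeders attending
#' the autumn window belong to neither. Years without a detected window are
#' excluded with a message.
#'
#' @param breeders Output of [breeders_from_nest_checks()].
#' @param clean_records Cleaned crossing stream.
#' @param windows Window table from [detect_aba_all()] (only
#'   `aba_envelope` rows are used).
#' @return A `data.table`: `year`, `transponder_id`, `cohort`
#'   (`"ss_only"`/`"ss_and_aba"`).
#' @export
classify_cohorts <- function(breeders, clean_records, windows) {
  env <- windows[kind == "aba_envelope"]
  cross_dates <- data.table(transponder_id = clean_records$transponder_id,
                            date = date_of(clean_records$timestamp))
  out <- vector("list", 0L)
  for (y in sort(unique(breeders$year))) {
    w <- env[year == y]
    if (nrow(w) == 0L) {
      message(sprintf("year %d: no autumn window; breeders excluded from cohort analysis", y))
      next
    }
    ids <- breeders[year == y, transponder_id]
    attendees <- unique(cross_dates[date >= w$start & date < w$end, transponder_id])
    out[[length(out) + 1L]] <- data.table(
      year = y, transponder_id = ids,
      cohort = ifelse(ids %chin% attendees, "ss_and_aba", "ss_only"))
  }
  if (!length(out))
    return(data.table(year = integer(), transponder_id = character(),
                      cohort = character()))
  rbindlist(out)
}

#' Yearly cohort summary
#'
#' One summary row per year: breeder count, the proportion of breeders
#' (total, and within each sex) that also attended the autumn window, and
#' the mean age of each cohort. Empty strata give missing proportions;
#' unknown-sex individuals enter the totals but neither sex stratum.
#'
#' @param cohorts Output of [classify_cohorts()].
#' @param register Individual register (for sex and age).
#' @return A `data.table` with columns `year`, `n_breeders`,
#'   `prop_aba_total`, `prop_aba_female`, `prop_aba_male`,
#'   `mean_age_ss_only`, `mean_age_ss_and_aba`.
#' @export
cohort_table <- function(cohorts, register) {
  if (nrow(cohorts) == 0L)
    return(data.table(year = integer(), n_breeders = integer(),
                      prop_aba_total = numeric(), prop_aba_female = numeric(),
                      prop_aba_male = numeric(), mean_age_ss_only = numeric(),
                      mean_age_ss_and_aba = numeric()))
  prop <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  out <- vector("list", 0L)
  for (y in sort(unique(cohorts$year))) {
    co <- cohorts[year == y]
    ages <- assign_age(register, y)
    dt <- merge(co, register[, .(transponder_id, sex)], by = "transponder_id")
    dt <- merge(dt, ages[, .(transponder_id, age)], by = "transponder_id")
    aba <- dt$cohort == "ss_and_aba"
    out[[length(out) + 1L]] <- data.table(
      year = y,
      n_breeders = nrow(dt),
      prop_aba_total = prop(aba),
      prop_aba_female = prop(aba[dt$sex == "F"]),
      prop_aba_male = prop(aba[dt$sex == "M"]),
      mean_age_ss_only = prop(dt$age[!aba]),
      mean_age_ss_and_aba = prop(dt$age[aba])
    )
  }
  rbindlist(out)
}

#' Paired t-test on yearly values
#'
#' The study's comparison statistic: differences `d = y - x` are taken
#' pairwise (one pair per year), and `t = mean(d) / (sd(d) / sqrt(n))` with
#' an n-1 denominator in the SD is referred to a Student t distribution
#' with `n - 1` degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length (>= 2), paired by position.
#' @return A `paired_t` object: `n_pairs`, `mean_diff`, `sd_diff`,
#'   `t_statistic`, `df`, `p_two_sided`.
#' @export
#' @examples
#' paired_t(c(6.4, 3.16, 4.1), c(7.5, 7.6, 7.4))
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired_t: x and y must have equal length", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("paired_t: need at least 2 complete pairs", call. = FALSE)
  d <- y - x
  sdd <- sd(d)
  if (sdd == 0) stop("paired_t: zero-variance differences", call. = FALSE)
  tstat <- mean(d) / (sdd / sqrt(n))
  structure(list(
    n_pairs = n,
    mean_diff = mean(d),
    sd_diff = sdd,
    t_statistic = tstat,
    df = n - 1L,
    p_two_sided = 2 * pt(-abs(tstat), df = n - 1L)
  ), class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.3f, df = %d, p = %.4g (mean diff %.3f +/- SD %.3f, n = %d)\n",
              x$t_statistic, x$df, x$p_two_sided, x$mean_diff, x$sd_diff,
              x$n_pairs))
  invisible(x)
}

#' Mean participation proportion across years
#'
#' Unweighted mean of the yearly autumn-participation proportions, with the
#' across-year SD and SE.
#'
#' @param props Numeric vector of yearly proportions (NAs dropped).
#' @return A list: `mean`, `sd`, `se`, `n_years`.
#' @export
mean_proportion <- function(props) {
  props <- props[!is.na(props)]
  if (!length(props)) stop("mean_proportion: no proportions supplied", call. = FALSE)
  n <- length(props)
  list(mean = mean(props),
       sd = if (n > 1L) sd(props) else NA_real_,
       se = if (n > 1L) sd(props) / sqrt(n) else NA_real_,
       n_years = n)
}
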
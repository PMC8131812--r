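#' Analyse a set of colony-monitoring inputs in memory
#'
#' The analysis half of the pipeline without any file IO: cleans the
#' crossing log, builds the daily attendance series, detects and segments
#' the autumn windows, classifies breeders by autumn attendance, and runs
#' the cross-year comparisons. Convenient for simulation studies where
#' [run_pipeline()]'s artifact-writing is not wanted.
#'
#' @param crossings Raw crossing `data.table`.
#' @param register Individual register.
#' @param nest_checks Nest-check `data.table`.
#' @param detector [detector_params()].
#' @param cleaning Optional list of extra [clean_crossings()] arguments.
#' @return A list: `clean` (records + report), `series`, `windows`,
#'   `window_summary`, `cohort_summary`, and `tests` (from
#'   [headline_stats()]; `NULL` when fewer than two analysable years).
#' @export
#' @examples
#' sim <- simulate_colony(sim_config(n_individuals = 60, years = 2003:2005,
#'                                   seed = 9))
#' res <- analyze_colony(sim$crossings, sim$individuals, sim$nest_checks)
#' res$cohort_summary
analyze_colony <- function(crossings, register, nest_checks,
                           detector = detector_params(), cleaning = list()) {
  cl <- do.call(clean_crossings,
                c(list(records = crossings, register = register), cleaning))
  series <- daily_attendance(cl$records)
  windows <- detect_aba_all(series, detector)
  breeders <- breeders_from_nest_checks(nest_checks)
  cohorts <- classify_cohorts(breeders, cl$records, windows)
  csum <- cohort_table(cohorts, register)
  tests <- if (nrow(csum) >= 2L) headline_stats(csum) else NULL
  list(clean = cl, series = series, windows = windows,
       window_summary = summarize_windows(windows),
       cohort_summary = csum, tests = tests)
}
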
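test_that("March minimum is the monthly minimum and requires coverage", {
  s <- make_series(2003, default = 10)
  expect_equal(march_minimum(s, 2003), 10L)

  s2 <- make_series(2003, default = 10,
                    spans = list(list("2003-03-05", "2003-03-05", 8),
                                 list("2003-03-20", "2003-03-20", 15)))
  expect_equal(march_minimum(s2, 2003), 8L)

  expect_error(march_minimum(make_series(2003)[date >= as.Date("2003-06-01")], 2003),
               "March")
})

test_that("zero-attendance March floors the threshold at one", {
  s <- make_series(2003, default = 5,
                   spans = list(list("2003-03-01", "2003-03-31", 0)))
  expect_equal(aba_threshold(s, 2003), 1)
})

test_that("start is the first day of a five-day run at or above threshold", {
  # March min 10 -> threshold 20; two near-miss days then a sustained run
  s <- make_series(2003, default = 10,
                   spans = list(list("2003-04-25", "2003-04-25", 15),
                                list("2003-04-26", "2003-04-26", 19),
                                list("2003-04-27", "2003-05-13", 25)))
  thr <- aba_threshold(s, 2003)
  expect_equal(thr, 20)
  expect_equal(detect_start(s, 2003, thr), as.Date("2003-04-27"))

  # flat series below threshold: absence is a valid result
  expect_null(detect_start(make_series(2003, default = 10), 2003, 20))

  # boundary inclusivity: exactly-at-threshold run of exactly 5 days
  s5 <- make_series(2003, default = 10,
                    spans = list(list("2003-05-01", "2003-05-05", 20)))
  expect_equal(detect_start(s5, 2003, 20), as.Date("2003-05-01"))
  # one day shorter does not qualify
  s4 <- make_series(2003, default = 10,
                    spans = list(list("2003-05-01", "2003-05-04", 20)))
  expect_null(detect_start(s4, 2003, 20))
})

test_that("end is the first half-decline day with a quiet fortnight", {
  # peak at 25 then sustained drop to 8 (8 <= 12.5)
  s <- make_series(2003, default = 8,
                   spans = list(list("2003-03-01", "2003-03-31", 10),
                                list("2003-04-27", "2003-05-13", 25)))
  e <- detect_end(s, as.Date("2003-04-27"), 20)
  expect_equal(e$end, as.Date("2003-05-14"))
  expect_false(e$open_ended)
})

test_that("a decline followed by a new qualifying run within 14 days is not an end", {
  # multi-peak year: drop to 12 (<= 12.5) for 3 days, second run begins
  # within the quiet window, then a true sustained decline
  s <- make_series(2003, default = 8,
                   spans = list(list("2003-03-01", "2003-03-31", 10),
                                list("2003-04-27", "2003-05-13", 25),
                                list("2003-05-14", "2003-05-16", 12),
                                list("2003-05-17", "2003-05-28", 25)))
  e <- detect_end(s, as.Date("2003-04-27"), 20)
  expect_equal(e$end, as.Date("2003-05-29"))

  segs <- segment_peaks(s, as.Date("2003-04-27"), e$end, 20)
  expect_equal(segs$kind, c("first_peak", "trough", "second_peak"))
  expect_equal(segs$duration_days, c(17L, 3L, 12L))
})

test_that("a monotone decline ends on the day it crosses half the maximum", {
  s <- make_series(2003, default = 4,
                   spans = list(list("2003-03-01", "2003-03-31", 10),
                                list("2003-04-27", "2003-05-08", 40),
                                list("2003-05-09", "2003-05-09", 30),
                                list("2003-05-10", "2003-05-10", 24),
                                list("2003-05-11", "2003-05-11", 19),
                                list("2003-05-12", "2003-05-12", 15)))
  e <- detect_end(s, as.Date("2003-04-27"), 20)
  expect_equal(e$end, as.Date("2003-05-11"))  # 19 <= 20 = 0.5 * 40
})

test_that("segments are run-lengths that tile the envelope", {
  s <- make_series(2003, default = 5,
                   spans = list(list("2003-03-01", "2003-03-31", 10),
                                list("2003-04-20", "2003-05-06", 30),  # 17 d
                                list("2003-05-07", "2003-05-16", 6),   # 10 d
                                list("2003-05-17", "2003-05-28", 28))) # 12 d
  w <- detect_aba(s, 2003)
  env <- w[kind == "aba_envelope"]
  segs <- w[kind != "aba_envelope"]
  expect_equal(segs$kind, c("first_peak", "trough", "second_peak"))
  expect_equal(segs$duration_days, c(17L, 10L, 12L))
  expect_equal(segs$start[1], env$start)
  expect_equal(segs$end[nrow(segs)], env$end)
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])  # no gaps, no overlap
  expect_equal(sum(segs$duration_days), env$duration_days)

  # single run: one first_peak, no trough
  s1 <- make_series(2003, default = 5,
                    spans = list(list("2003-03-01", "2003-03-31", 10),
                                 list("2003-04-20", "2003-05-06", 30)))
  w1 <- detect_aba(s1, 2003)
  expect_equal(w1[kind != "aba_envelope", kind], "first_peak")
})

test_that("repeat-pattern years report all peaks in order", {
  spans <- list(list("2003-03-01", "2003-03-31", 10))
  starts <- as.Date(c("2003-04-15", "2003-05-01", "2003-05-17", "2003-06-02"))
  for (i in seq_along(starts)) {
    spans[[length(spans) + 1]] <- list(as.character(starts[i]),
                                       as.character(starts[i] + 9), 30)
  }
  s <- make_series(2003, default = 5, spans = spans)
  w <- detect_aba(s, 2003)
  peaks <- w[!kind %in% c("aba_envelope", "trough")]
  expect_equal(peaks$kind, c("first_peak", "second_peak", "peak_3", "peak_4"))
  expect_equal(nrow(w[kind == "trough"]), 3L)
  expect_true(all(w[kind == "trough", duration_days] == 6L))
})

test_that("detected dates are invariant to rescaling the whole series", {
  s <- make_series(2003, default = 5,
                   spans = list(list("2003-03-01", "2003-03-31", 10),
                                list("2003-04-20", "2003-05-06", 30),
                                list("2003-05-07", "2003-05-16", 6),
                                list("2003-05-17", "2003-05-28", 28)))
  w1 <- detect_aba(s, 2003)
  s10 <- data.table::copy(s)[, n := n * 10L]
  w10 <- detect_aba(s10, 2003)
  expect_equal(w10[, .(kind, start, end, duration_days)],
               w1[, .(kind, start, end, duration_days)])
})

test_that("raising the start multiplier never advances the start date", {
  set.seed(8)
  for (i in 1:10) {
    base <- sample(5:12, 1)
    s <- make_series(2003, default = base)
    # random blocks of elevated attendance in autumn
    for (j in 1:3) {
      d0 <- as.Date("2003-04-01") + sample(0:80, 1)
      s[date >= d0 & date <= d0 + sample(4:15, 1),
        n := base * sample(2:4, 1)]
    }
    prev <- as.Date("1900-01-01")
    for (mult in c(1.5, 2, 2.5, 3)) {
      st <- detect_start(s, 2003, max(mult * march_minimum(s, 2003), 1),
                         detector_params())
      if (is.null(st)) st <- as.Date("9999-12-31")
      expect_gte(as.numeric(st - prev), 0)
      prev <- st
    }
  }
})

test_that("a series ending mid-window is flagged open-ended", {
  s <- make_series(2003, default = 5,
                   spans = list(list("2003-03-01", "2003-03-31", 10),
                                list("2003-04-20", "2003-12-31", 30)))
  w <- detect_aba(s, 2003)
  expect_true(all(w$open_ended))
  expect_equal(w[kind == "aba_envelope", end], as.Date("2004-01-01"))
})

test_that("window summaries use the n-1 SD and report the start range", {
  w <- data.table::data.table(
    year = 2003:2005, kind = "first_peak",
    start = as.Date(c("2003-04-20", "2004-04-25", "2005-04-30")),
    end = as.Date(c("2003-05-07", "2004-05-11", "2005-05-17")),
    duration_days = c(17L, 16L, 18L), peak_max = 30, threshold = 20,
    open_ended = FALSE)
  sm <- summarize_windows(w)
  expect_equal(sm$mean_duration, 17)
  expect_equal(sm$sd_duration, 1)
  expect_equal(sm$earliest_start, as.Date("2003-04-20"))
  expect_equal(sm$latest_start, as.Date("2005-04-30"))
  expect_equal(sm$mean_start_doy, mean(c(110, 115, 120)))

  sm2 <- summarize_windows(w[1])
  expect_true(is.na(sm2$sd_duration))

  w$duration_days <- 17L
  expect_equal(summarize_windows(w)$sd_duration, 0)
})
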
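test_that("config validation names the offending field", {
  expect_error(sim_config(sex_ratio = 1.5), "sex_ratio")
  expect_error(sim_config(mass_sd_g = 0), "mass_sd_g")
  expect_error(sim_config(aba_trough_duration = 0), "aba_trough_duration")
  expect_error(sim_config(aba_first_peak = c(117, 0)), "aba_first_peak")
  expect_error(sim_config(outlier_mass_rate = -0.1), "outlier_mass_rate")
})

test_that("empty population gives empty outputs", {
  cfg <- sim_config(n_individuals = 0, years = 2003, seed = 1)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 0L)
  gen <- generate_crossings(pop, cfg)
  expect_equal(nrow(gen$crossings), 0L)
  expect_equal(nrow(gen$truth$flags), 0L)
  expect_equal(nrow(generate_nest_checks(pop, gen$truth, cfg)), 0L)
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- small_config()
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_colony(cfg, out_dir = d1)
  simulate_colony(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("sex ratio is recovered within three binomial SDs", {
  set.seed(7)
  pop <- generate_population(sim_config(n_individuals = 500, years = 2003,
                                        sex_ratio = 0.5, seed = NULL))
  frac_f <- mean(pop$sex == "F")
  expect_lt(abs(frac_f - 0.5), 3 * sqrt(0.25 / 500))
})

test_that("marking year is consistent with age for both marking routes", {
  set.seed(11)
  cfg <- sim_config(n_individuals = 400, years = 2005:2006,
                    adult_marked_fraction = 0.4, seed = NULL)
  pop <- generate_population(cfg)
  # the age rule applied to the register must recover the true starting age
  ages <- assign_age(pop, 2005)
  expect_equal(ages$age, pop$age_start)
  expect_true(all(pop$year_marked <= 2005))
  expect_true(any(pop$marked_as == "adult"))
})

test_that("every flagged autumn attendee has an incoming crossing inside the true window", {
  sim <- simulate_colony(small_config())
  env <- sim$truth$windows[kind == "aba_envelope"]
  cross <- sim$crossings[direction == "in"]
  cross[, date := as.Date(timestamp)]
  for (y in env$year) {
    ids <- sim$truth$flags[year == y & aba_attendee == TRUE, transponder_id]
    w <- env[year == y]
    seen <- unique(cross[date >= w$start & date < w$end, transponder_id])
    expect_true(all(ids %in% seen), info = sprintf("year %d", y))
  }
})

test_that("attendance model calibration hits base probability and age gap", {
  set.seed(3)
  ages <- sample(2:15, 300, replace = TRUE, prob = 0.8^(0:13))
  for (gap in c(0, 1, 2.5)) {
    cal <- calibrate_attendance_model(ages, 0.76, gap)
    p <- plogis(cal$intercept + cal$slope * (ages - mean(ages)))
    expect_equal(mean(p), 0.76, tolerance = 1e-6)
    got <- sum(p * ages) / sum(p) - sum((1 - p) * ages) / sum(1 - p)
    expect_equal(got, gap, tolerance = 1e-5)
  }
  expect_error(calibrate_attendance_model(rep(5, 100), 0.76, 2.5),
               "unattainable")
})

test_that("null age effect yields near-zero attendee age gap in truth flags", {
  gaps <- vapply(1:8, function(s) {
    sim <- simulate_colony(small_config(aba_age_effect = 0, seed = s,
                                        n_individuals = 200))
    fl <- merge(sim$truth$flags, sim$individuals, by = "transponder_id")
    fl[, age := year - year_marked + ifelse(marked_as == "adult", 3L, 0L)]
    fl[, mean(age[aba_attendee]) - mean(age[!aba_attendee])]
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.25)
})

test_that("nest-check dates follow the monitoring cadence", {
  sim <- simulate_colony(small_config())
  dates <- sort(unique(sim$nest_checks$date))
  mon <- data.table::month(dates)
  wd <- (as.integer(dates) + 4L) %% 7L  # 0 = Sunday
  in_season <- mon >= 9L | mon <= 2L
  expect_true(all(wd[in_season] %in% c(1L, 3L, 5L)))   # Mon/Wed/Fri
  expect_true(all(wd[!in_season] == 1L))               # weekly Mondays

  # independent calendar oracle: 3/week count over one season span
  span <- seq(as.Date("2003-09-01"), as.Date("2004-02-28"), by = "day")
  expected <- sum(((as.integer(span) + 4L) %% 7L) %in% c(1L, 3L, 5L))
  got <- sum(dates >= as.Date("2003-09-01") & dates <= as.Date("2004-02-28"))
  expect_equal(got, expected)
})

test_that("nest checks cover exactly the breeding pairs and their season", {
  sim <- simulate_colony(small_config())
  season <- sim$nest_checks[grepl("-N", nest_id)]
  occ <- unique(unlist(strsplit(season$occupant_ids, ";")))
  truth_breeders <- unique(sim$truth$flags[breeder == TRUE, transponder_id])
  expect_setequal(occ, truth_breeders)
  # rows only on dates within the labelled season
  yr <- as.integer(sub("^Y(\\d+)-.*$", "\\1", season$nest_id))
  expect_true(all(season$date >= as.Date(sprintf("%d-09-01", yr)) &
                    season$date <= as.Date(sprintf("%d-02-28", yr + 1L))))
})

test_that("no breeders and no attendees give no nest checks", {
  cfg <- small_config(breeder_prob = 0, aba_base_prob = 0, aba_age_effect = 0)
  sim <- simulate_colony(cfg)
  expect_equal(nrow(sim$nest_checks), 0L)
})

test_that("realized windows have positive durations and consecutive segments", {
  sim <- simulate_colony(small_config())
  w <- sim$truth$windows
  expect_true(all(w$end > w$start))
  for (y in unique(w$year)) {
    wy <- w[year == y]
    expect_equal(wy[kind == "first_peak", end], wy[kind == "trough", start])
    expect_equal(wy[kind == "trough", end], wy[kind == "second_peak", start])
    expect_equal(wy[kind == "aba_envelope", start], wy[kind == "first_peak", start])
    expect_equal(wy[kind == "aba_envelope", end], wy[kind == "second_peak", end])
  }
})
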
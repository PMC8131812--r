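# abascan

Attendance-record analysis for seabird colonies monitored by an automated
gateway (PIT-tag weighbridge): cleaning of raw crossing logs, daily
attendance/nest-occupancy series, threshold-based detection of the
**autumn breeding attempt (ABA)** window, and cross-year cohort
comparisons of the birds that take part.

## The scientific problem

Little penguins (*Eudyptula minor*) at large colonies breed in austral
spring/summer (Aug–Feb), but attendance records show a second, smaller
peak in autumn with courtship-like behaviour — effectively an extra
breeding attempt. Two questions drive the analysis:

1. **When is the autumn window?** Per year, the window *starts* on the
   first day of ≥ 5 successive days with daily attendance
   `n(t) ≥ 2 × min(March)` — twice the post-molt March minimum — and
   *ends* on the first day with `n(t) ≤ ½ × max` since the start, with no
   further qualifying run within the next 14 days. Within the envelope,
   runs at/above the threshold are courtship peaks, the runs between them
   the prelaying-exodus trough.
2. **Who takes part?** Among each year's spring/summer breeders (from nest
   checks), birds with ≥ 1 cleaned incoming crossing inside the window
   form the autumn cohort. Yearly cohort summaries (participation
   proportions, mean ages, with age = years since fledging-marking, or +3
   years for adult-marked birds) are compared across years with a paired
   t-test: `t = mean(d) / (sd(d)/√n)`, `df = n − 1`, one pair of yearly
   values per year.

Raw logs are cleaned first: registered individuals only, incoming
crossings only, body mass within [700, 1700] g, and removal of repeat
reads of the same bird < 40 min apart (anchored greedy scan).

A seeded individual-based simulator (`simulate_colony()`) generates
crossing logs, registers and nest checks with known ground truth —
injected windows, attendee flags and artefact counts — so every stage is
testable without any field data.

## Worked example

```r
library(abascan)

sim <- simulate_colony(sim_config(seed = 1))   # 332 birds, 2003-2013
res <- analyze_colony(sim$crossings, sim$individuals, sim$nest_checks)

res$clean$report
#> <cleaning_report>
#>   input      261891
#>   unmarked     3725 removed
#>   outgoing    55345 removed
#>   mass         1848 removed
#>   dedup       18275 removed
#>   output     182698

res$window_summary[, .(kind, n_years, mean_duration, sd_duration)]
#>            kind n_years mean_duration sd_duration
#> 1: aba_envelope      11      39.18182    2.786330
#> 2:   first_peak      11      16.90909    1.578261
#> 3:  second_peak      11      12.18182    1.887760
#> 4:       trough      11      10.09091    1.300350

res$tests$age
#> Paired t-test: t = 13.221, df = 10, p = 1.169e-07 (mean diff 2.268 +/- SD 0.569, n = 11)
```

Reading this: the simulated colony's autumn window lasts ~39 days split
into a ~17-day first peak, ~10-day trough and ~12-day second peak; the
autumn-attending cohort is on average 2.27 years older than the
spring/summer-only cohort across the 11 years (the generator injected a
2.5-year effect; the small shortfall is classification leakage from
background winter visits, quantified in the vignette).

The same comparisons on the published yearly summary of the Phillip
Island colony (2003–2013), bundled as `published_cohort_summary()`:

```r
hs <- headline_stats(published_cohort_summary())
hs$age
#> Paired t-test: t = 5.206, df = 10, p = 0.0003981 (mean diff 2.469 +/- SD 1.573, n = 11)
hs$sex
#> Paired t-test: t = 0.849, df = 10, p = 0.4159 (mean diff 0.015 +/- SD 0.060, n = 11)
hs$participation
#> mean 76.4%, SD 6.3%, SE 1.9% across 11 years
```

So on the published record the autumn cohort averages 2.5 years older
(t = 5.2, p < .001), the sexes participate equally (t = 0.85, p = .42),
and on average 76% of breeders also attend the autumn window.

`run_pipeline()` runs the same chain from CSV inputs (or a simulation
config) to CSV/JSON artifacts plus a hash manifest;
`inst/scripts/aba-scan.R` is a small command-line wrapper.

## Package layout

- `R/simulate.R`, `R/sim-config.R` — ground-truthed colony simulator
- `R/cleaning.R` — crossing-log filters and audit report
- `R/series.R` — daily attendance / occupancy / annual pattern
- `R/detect.R` — autumn-window detector and segmentation
- `R/cohorts.R`, `R/published.R` — ages, cohorts, paired comparisons
- `R/analyze.R`, `R/pipeline.R` — orchestration
- `vignettes/autumn-breeding-detection.Rmd` — models, assumptions,
  parameter choices, limitations
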
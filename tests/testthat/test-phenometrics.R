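test_that("a linear ramp crosses 50% amplitude exactly halfway", {
  d <- seq(as.Date("2016-01-01"), as.Date("2018-12-31"), by = 1)
  t <- day_num(d)
  d100 <- day_num(as.Date("2017-04-10"))      # DOY 100 of 2017
  d200 <- d100 + 100                          # DOY 200
  v <- rep(0.2, length(t))
  v[t > d100 & t <= d200] <- 0.2 + 0.5 * (t[t > d100 & t <= d200] - d100) / 100
  v[t > d200] <- pmax(0.2, 0.7 - 0.5 * (t[t > d200] - d200) / 100)
  daily <- daily_series(d, v)
  cs <- detect_cycles(daily, 2017)
  expect_identical(cs$num_cycles, 1L)
  tm <- timing_metrics(cs$cycles[[1]], daily, 2017)
  # ramp from 0.2 (DOY 100) to 0.7 (DOY 200): 50% crossing at DOY 150
  expect_identical(unname(tm["50PCGI"]), 150L)
  expect_identical(unname(tm["Peak"]), 200L)
  # symmetric triangle: mid-greenup and mid-greendown equidistant from peak
  expect_identical(tm[["Peak"]] - tm[["50PCGI"]],
                   tm[["50PCGD"]] - tm[["Peak"]])
  # ordering invariant
  expect_true(all(diff(tm[c("OGI", "50PCGI", "OGMx", "Peak", "OGD",
                            "50PCGD", "OGMn")]) >= 0))
})

test_that("a cycle whose onset precedes January 1 reports a negative OGI", {
  cy <- data.frame(sos = day_num(as.Date("2016-12-01")),
                   eos = day_num(as.Date("2017-03-15")),
                   amplitude = 0.5, up_rate = 6, down_rate = 6)
  daily <- truth_daily(make_truth("double_logistic", baseline = 0.2,
                                  cycles = cy),
                       "2016-01-01", "2018-12-31")
  cs <- detect_cycles(daily, 2017)
  expect_identical(cs$num_cycles, 1L)
  tm <- timing_metrics(cs$cycles[[1]], daily, 2017)
  expect_lt(tm[["OGI"]], 1)
  expect_gte(tm[["OGI"]], -181)
})

test_that("greenness metrics are the peak, amplitude and daily sum", {
  tr <- truth_single_season(2016:2018, baseline = 0.2, amplitude = 0.35)
  daily <- truth_daily(tr, "2016-01-01", "2018-12-31")
  cs <- detect_cycles(daily, 2017)
  cyc <- cs$cycles[[1]]
  tm <- timing_metrics(cyc, daily, 2017)
  gm <- greenness_metrics(cyc, daily, tm, 2017)
  expect_equal(unname(gm["EVImax"]), cyc$peak_value)
  expect_equal(unname(gm["EVIamp"]), cyc$peak_value - cyc$greenup_min)
  # independent summation oracle over the OGI..OGMn day span
  dn <- day_num(daily$dates)
  d0 <- day_num(jan1(2017)) + tm[["OGI"]] - 1L
  d1 <- day_num(jan1(2017)) + tm[["OGMn"]] - 1L
  expect_equal(unname(gm["EVIarea"]),
               sum(daily$evi2_fit[dn >= d0 & dn <= d1]))
  # floored daily values bound the integral from below
  expect_gte(gm[["EVIarea"]], (d1 - d0 + 1) * daily$background)
})

test_that("annual metrics are reported even with zero cycles", {
  daily <- truth_daily(make_truth("flat", baseline = 0.25),
                       "2016-01-01", "2018-12-31")
  rec <- pixel_phenometrics(daily, 2017)
  expect_identical(unname(rec["NumCycles"]), 0)
  expect_true(all(is.na(rec[c("OGI", "50PCGI", "OGMx", "Peak", "OGD",
                              "50PCGD", "OGMn")])))
  expect_equal(unname(rec["EVImax"]), 0.25)
  expect_equal(unname(rec["EVIamp"]), 0)
  expect_equal(unname(rec["EVIarea"]), 365 * 0.25)
  expect_identical(unname(rec["QA"]), 4)
  expect_identical(unname(rec["numObs"]), 365)
})

test_that("numObs counts distinct clear days in the calendar year", {
  daily <- truth_daily(truth_single_season(2016:2018),
                       "2016-01-01", "2018-12-31")
  clear <- seq(as.Date("2017-01-03"), by = 3, length.out = 120)
  am <- annual_metrics(daily, 2017, clear_dates = clear)
  expect_identical(unname(am["numObs"]), 120)
  # never exceeds the days of a year
  am_all <- annual_metrics(daily, 2017,
                           clear_dates = seq(as.Date("2016-12-01"),
                                             as.Date("2018-02-01"), by = 1))
  expect_lte(am_all[["numObs"]], 366)
})

test_that("QA classes follow the correlation / gap truth table", {
  tr <- truth_single_season(2016:2018)
  daily <- truth_daily(tr, "2016-01-01", "2018-12-31")
  cs <- detect_cycles(daily, 2017)
  cyc <- cs$cycles[[1]]
  span <- seq(cyc$start_day - 40, cyc$end_day + 40, by = 10)
  fit_at <- daily$evi2_fit[match(day_num(span), day_num(daily$dates))]
  # high correlation, short gaps -> 1
  expect_identical(qa_flag(cyc, daily, span, fit_at), 1L)
  # one violation (gap >= 30 d in greenup) -> 2
  gap_dates <- span[!(span > cyc$start_day + 5 & span < cyc$start_day + 45)]
  gap_vals <- daily$evi2_fit[match(day_num(gap_dates), day_num(daily$dates))]
  expect_identical(qa_flag(cyc, daily, gap_dates, gap_vals), 2L)
  # one violation (low correlation) -> 2
  lowr <- perturb_to_r(fit_at, 0.3, seed = 2)
  expect_identical(qa_flag(cyc, daily, span, lowr), 2L)
  # both violations -> 3
  lowr_gap <- perturb_to_r(gap_vals, 0.3, seed = 3)
  expect_identical(qa_flag(cyc, daily, gap_dates, lowr_gap), 3L)
  # no cycle -> 4
  expect_identical(qa_flag(NULL, daily), 4L)
  # fewer than 3 obs in a phase -> 4
  expect_identical(qa_flag(cyc, daily, span[1:4], fit_at[1:4]), 4L)
  # constant observations give an undefined correlation, counted as a
  # violation
  const <- rep(0.4, length(span))
  expect_lte(qa_flag(cyc, daily, span, const), 3L)
  expect_gte(qa_flag(cyc, daily, span, const), 2L)
})

test_that("timing ordering holds across a battery of random series", {
  cfg <- default_config()
  for (seed in 1:25) {
    tr <- random_truth(seed)
    daily <- truth_daily(tr, "2016-01-01", "2018-12-31")
    rec <- pixel_phenometrics(daily, 2017, cfg)
    for (suf in c("", "_2")) {
      tm <- rec[paste0(c("OGI", "50PCGI", "OGMx", "Peak", "OGD", "50PCGD",
                         "OGMn"), suf)]
      if (any(is.na(tm))) next
      expect_true(all(diff(tm) >= 0), label = paste("seed", seed, suf))
    }
    expect_true(rec[["QA"]] %in% 1:4)
    if (!is.na(rec[["EVIamp"]]) && !is.na(rec[["EVImax"]]))
      expect_lte(rec[["EVIamp"]], rec[["EVImax"]] + 1e-12)
  }
})

test_that("noiseless dense input recovers all seven timing metrics within a day", {
  tr <- truth_single_season(2016:2018)
  m <- truth_cycle_metrics(tr, 2)
  dates <- seq(as.Date("2016-07-01"), as.Date("2019-01-31"), by = 1)
  s <- simulate_series(tr, dates, noise_sd = 0, gap_prob = 0, spike_prob = 0,
                       snow_prob = 0, seed = 1)
  daily <- condition_series(s, min(dates), max(dates))
  rec <- pixel_phenometrics(daily, 2017)
  truth_doy <- c(m$crossings[c("up_15", "up_50", "up_90")], m$peak_day,
                 m$crossings[c("down_90", "down_50", "down_15")]) -
    day_num(jan1(2017)) + 1
  got <- rec[c("OGI", "50PCGI", "OGMx", "Peak", "OGD", "50PCGD", "OGMn")]
  expect_true(all(abs(got - truth_doy) <= 1))
  expect_identical(unname(rec["QA"]), 1)
})
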
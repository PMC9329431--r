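test_that("local peak finding handles unimodal, flat and bimodal series", {
  d <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = 1)
  t <- seq_along(d)
  one <- daily_series(d, 0.4 + 0.3 * sin(pi * (t - 1) / (length(t) - 1)))
  expect_identical(length(find_local_peaks(one)), 1L)
  flat <- daily_series(d, rep(0.3, length(d)))
  expect_identical(length(find_local_peaks(flat)), 0L)
  tr <- make_truth("double_logistic", baseline = 0.15,
                   cycles = data.frame(sos = day_num(jan1(2017)) + c(60, 240),
                                       eos = day_num(jan1(2017)) + c(140, 320),
                                       amplitude = c(0.5, 0.4),
                                       up_rate = 6, down_rate = 6))
  two <- truth_daily(tr, "2017-01-01", "2017-12-31")
  pk <- find_local_peaks(two)
  expect_identical(length(pk), 2L)
  m1 <- truth_cycle_metrics(tr, 1); m2 <- truth_cycle_metrics(tr, 2)
  expect_lte(abs(day_num(two$dates[pk[1]]) - m1$peak_day), 1)
  expect_lte(abs(day_num(two$dates[pk[2]]) - m2$peak_day), 1)
})

test_that("plateau ties break to the earliest day", {
  d <- seq(as.Date("2017-01-01"), by = 1, length.out = 101)
  v <- c(seq(0.2, 0.6, length.out = 40), rep(0.6, 21),
         seq(0.6, 0.2, length.out = 40))
  pk <- find_local_peaks(daily_series(d, v))
  expect_identical(length(pk), 1L)
  expect_identical(pk, 40L)
})

test_that("cycle amplitude criteria follow the 0.1 and 35% rules", {
  mk <- function(amp_main, amp_second = NULL) {
    cy <- data.frame(sos = day_num(jan1(2017)) + 100,
                     eos = day_num(jan1(2017)) + 220,
                     amplitude = amp_main, up_rate = 6, down_rate = 6)
    if (!is.null(amp_second))
      cy <- rbind(cy, data.frame(sos = day_num(jan1(2017)) + 280,
                                 eos = day_num(jan1(2017)) + 330,
                                 amplitude = amp_second,
                                 up_rate = 5, down_rate = 5))
    truth_daily(make_truth("double_logistic", baseline = 0.2, cycles = cy),
                "2016-01-01", "2018-12-31")
  }
  # 0.05 bump on a flat baseline: below the absolute floor
  expect_identical(detect_cycles(mk(0.05), 2017)$num_cycles, 0L)
  # 0.12 bump with 24-month range 0.12: both criteria met
  expect_identical(detect_cycles(mk(0.12), 2017)$num_cycles, 1L)
  # secondary 0.12 bump against a 0.6 main: 0.12 < 0.35 * 0.6
  cs <- detect_cycles(mk(0.6, 0.12), 2017)
  expect_identical(cs$num_cycles, 1L)
  # secondary 0.3 bump clears 0.35 * 0.6 = 0.21
  cs2 <- detect_cycles(mk(0.6, 0.30), 2017)
  expect_identical(cs2$num_cycles, 2L)
})

test_that("cycle start is capped at 185 days before the peak", {
  d <- seq(as.Date("2016-01-01"), as.Date("2018-12-31"), by = 1)
  t <- day_num(d); pk_day <- day_num(as.Date("2017-10-01"))
  v <- ifelse(t <= pk_day, 0.2 + 0.6 * pmax(0, 1 - (pk_day - t) / 300),
              0.2 + 0.6 * pmax(0, 1 - (t - pk_day) / 120))
  cs <- detect_cycles(daily_series(d, v), 2017)
  expect_identical(cs$num_cycles, 1L)
  cyc <- cs$cycles[[1]]
  expect_identical(day_num(cyc$peak_day) - day_num(cyc$start_day), 185L)
})

test_that("accepted peaks are at least 30 days apart", {
  tr <- truth_multi_cycle(2016:2018, n_cycles = 6, amplitude = 0.45)
  daily <- truth_daily(tr, "2016-01-01", "2018-12-31")
  cs <- detect_cycles(daily, 2017)
  pk <- vapply(cs$cycles, function(cy) day_num(cy$peak_day), 0L)
  expect_true(all(diff(sort(pk)) >= 30))
  # invariants on every accepted cycle
  for (cy in cs$cycles) {
    expect_true(day_num(cy$start_day) < day_num(cy$peak_day))
    expect_true(day_num(cy$peak_day) < day_num(cy$end_day))
    expect_lte(day_num(cy$peak_day) - day_num(cy$start_day), 185)
    expect_gte(cy$amplitude, 0.1)
  }
})

test_that("flat and multi-bump series produce the documented cycle counts", {
  flatd <- truth_daily(make_truth("flat", baseline = 0.18),
                       "2016-01-01", "2018-12-31")
  cs <- detect_cycles(flatd, 2017)
  expect_identical(cs$num_cycles, 0L)
  expect_identical(length(cs$reported), 0L)
  alf <- truth_daily(truth_multi_cycle(2016:2018, n_cycles = 6),
                     "2016-01-01", "2018-12-31")
  cs6 <- detect_cycles(alf, 2017)
  expect_lte(cs6$num_cycles, 6L)
  expect_gte(cs6$num_cycles, 2L)
  expect_identical(length(cs6$reported), 2L)
  amps <- vapply(cs6$cycles, function(cy) cy$amplitude, 0)
  expect_equal(cs6$reported[[1]]$amplitude, max(amps))
  expect_gte(cs6$reported[[1]]$amplitude, cs6$reported[[2]]$amplitude)
  one <- truth_daily(truth_single_season(2016:2018),
                     "2016-01-01", "2018-12-31")
  expect_identical(detect_cycles(one, 2017)$num_cycles, 1L)
})

test_that("insufficient coverage of the target year signals NULL", {
  short <- truth_daily(truth_single_season(2017),
                       "2017-01-01", "2017-12-31")
  expect_null(detect_cycles(short, 2017))
})

test_that("detection is deterministic", {
  daily <- truth_daily(truth_multi_cycle(2016:2018, n_cycles = 3),
                       "2016-01-01", "2018-12-31")
  a <- detect_cycles(daily, 2017)
  b <- detect_cycles(daily, 2017)
  expect_identical(a, b)
})

test_that("detection agrees with the brute-force enumerator", {
  cfg <- default_config()
  for (seed in 1:40) {
    tr <- random_truth(seed)
    dts <- seq(as.Date("2016-01-01"), as.Date("2018-12-31"), by = 1)
    v <- truth_evi2(tr, dts)
    set.seed(seed + 5000)
    v <- v + as.numeric(stats::filter(rnorm(length(v), sd = 0.004),
                                      rep(1 / 15, 15), circular = TRUE))
    daily <- daily_series(dts, v)
    got <- detect_cycles(daily, 2017, cfg)
    want <- brute_force_cycles(daily, 2017, cfg)
    expect_identical(got$num_cycles, length(want), label = paste("seed", seed))
    if (length(want)) {
      got_tab <- t(vapply(got$cycles, function(cy)
        c(day_num(cy$start_day), day_num(cy$peak_day), day_num(cy$end_day)),
        numeric(3)))
      want_tab <- t(vapply(want, function(cy)
        c(cy$start, cy$peak, cy$end), numeric(3)))
      expect_equal(got_tab, want_tab, label = paste("seed", seed))
    }
  }
})
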
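test_that("EVI2 matches hand-computed values", {
  expect_equal(compute_evi2(0.3, 0.3), 0)
  expect_equal(compute_evi2(0.4, 0.1), 2.5 * 0.3 / 1.64)  # 0.4573170...
  expect_lt(compute_evi2(0.05, 0.2), 0)
  m <- compute_evi2(matrix(0.4, 2, 2), matrix(0.1, 2, 2))
  expect_equal(m, matrix(2.5 * 0.3 / 1.64, 2, 2))
})

test_that("screening flags negatives, snow and isolated spikes", {
  d <- as.Date("2017-01-01") + seq(0, 120, by = 3)
  v <- rep(0.3, length(d))
  v[5] <- -0.03                       # negative
  v[20] <- 0.9                        # isolated island
  st <- rep("clear", length(d)); st[10] <- "snow"
  s <- screen_observations(pixel_series(d, v, st))
  expect_identical(s$status[5], "negative")
  expect_identical(s$status[10], "snow")
  expect_identical(s$status[20], "spike")
  expect_true(all(s$status[-c(5, 10, 20)] == "clear"))
})

test_that("clean monotone series pass screening unchanged", {
  d <- as.Date("2017-03-01") + seq(0, 90, by = 3)
  v <- seq(0.2, 0.8, length.out = length(d))
  s <- screen_observations(pixel_series(d, v))
  expect_true(all(s$status == "clear"))
  expect_identical(s$evi2, v)
})

test_that("screening is idempotent", {
  tr <- truth_single_season(2016:2018)
  dates <- seq(as.Date("2016-07-01"), as.Date("2018-12-31"), by = 2)
  s <- simulate_series(tr, dates, spike_prob = 0.05, snow_prob = 0.05,
                       seed = 21)
  once <- screen_observations(s)
  twice <- screen_observations(once)
  expect_identical(once, twice)
})

test_that("background is the 10th percentile of usable observations", {
  d <- as.Date("2017-01-01") + seq(0, 27, by = 3)
  v <- seq(0.1, 1.0, by = 0.1)                 # ten values
  s <- pixel_series(d, v)
  expect_equal(compute_background(s), unname(quantile(v, 0.1, type = 7)))
  # constant series: all percentiles equal the constant
  expect_equal(compute_background(pixel_series(d, rep(0.42, 10))), 0.42)
  # snow-flagged lows are excluded
  d2 <- as.Date("2017-01-01") + seq(0, 14 * 3, by = 3)
  v2 <- c(rep(0, 5), seq(0.15, 0.6, length.out = 10))
  st2 <- c(rep("snow", 5), rep("clear", 10))
  bg <- compute_background(pixel_series(d2, v2, st2))
  expect_gte(bg, 0.15)
  # insufficient data signals NA
  expect_true(is.na(compute_background(pixel_series(d[1:5], v[1:5]))))
})

test_that("background flooring replaces and re-admits observations", {
  d <- as.Date("2017-01-01") + seq(0, 18, by = 3)
  v <- c(0.15, 0.5, -0.02, 0.9, 0.25, 0.18, 0.3)
  st <- c("clear", "clear", "negative", "spike", "snow", "clear", "clear")
  f <- floor_to_background(pixel_series(d, v, st), 0.2)
  expect_equal(f$evi2, c(0.2, 0.5, 0.2, 0.2, 0.2, 0.2, 0.3))
  expect_identical(f$status,
                   c("below_background", "clear", "below_background",
                     "below_background", "below_background",
                     "below_background", "clear"))
  # all below background -> constant series
  allb <- floor_to_background(pixel_series(d, rep(0.1, 7)), 0.2)
  expect_equal(allb$evi2, rep(0.2, 7))
})

test_that("raising an observation never lowers the floored series", {
  d <- as.Date("2017-01-01") + seq(0, 60, by = 3)
  set.seed(4)
  v <- runif(length(d), 0.05, 0.6)
  base <- floor_to_background(pixel_series(d, v), 0.2)
  for (i in c(1, 7, 15)) {
    v2 <- v; v2[i] <- v2[i] + 0.3
    up <- floor_to_background(pixel_series(d, v2), 0.2)
    expect_true(all(up$evi2 >= base$evi2 - 1e-12))
  }
})

test_that("the spline interpolates noiseless daily input as penalty -> 0", {
  d <- seq(as.Date("2016-07-01"), as.Date("2017-12-31"), by = 1)
  t <- as.integer(d)
  v <- 0.4 + 0.3 * sin(2 * pi * t / 365)
  fit <- fit_daily_spline(pixel_series(d, v), lambda = 1e-12)
  expect_lt(max(abs(fit$evi2_fit - v)), 1e-6)
})

test_that("the spline gap-fills a 30-day hole continuously", {
  tr <- truth_single_season(2016:2018)
  d <- seq(as.Date("2016-07-01"), as.Date("2018-12-31"), by = 2)
  gap <- !(d >= as.Date("2017-06-10") & d <= as.Date("2017-07-10"))
  s <- pixel_series(d[gap], truth_evi2(tr, d[gap]))
  fit <- fit_daily_spline(s, as.Date("2016-07-01"), as.Date("2018-12-31"))
  expect_true(all(is.finite(fit$evi2_fit)))
  expect_identical(length(fit$evi2_fit),
                   length(seq(as.Date("2016-07-01"),
                              as.Date("2018-12-31"), by = 1)))
  # no jumps across the gap: daily increments stay small
  expect_lt(max(abs(diff(fit$evi2_fit))), 0.05)
})

test_that("noisy 3-day sampling recovers the mid-greenup day within 2 days", {
  tr <- truth_single_season(2016:2018)
  m <- truth_cycle_metrics(tr, 2)              # the 2017 bump
  d <- seq(as.Date("2016-07-01"), as.Date("2018-12-31"), by = 3)
  s <- simulate_series(tr, d, noise_sd = 0.02, gap_prob = 0, spike_prob = 0,
                       snow_prob = 0, seed = 31)
  fit <- fit_daily_spline(s, background = min(s$evi2))
  half <- m$min_up + 0.5 * (m$peak_value - m$min_up)
  crossing <- fit$dates[which(fit$evi2_fit >= half &
                                format(fit$dates, "%Y") == "2017")[1]]
  expect_lte(abs(as.numeric(crossing) - m$crossings["up_50"]), 2)
})

test_that("spline fitting is invariant to observation order", {
  tr <- truth_single_season(2016:2018)
  d <- seq(as.Date("2016-07-01"), as.Date("2018-12-31"), by = 3)
  s <- simulate_series(tr, d, seed = 17)
  # shuffle then rebuild in sorted order: pixel_series enforces ordering,
  # so supply duplicated/perturbed input through the fit directly
  fit1 <- fit_daily_spline(s)
  fit2 <- fit_daily_spline(pixel_series(s$dates, s$evi2, s$status))
  expect_equal(fit1$evi2_fit, fit2$evi2_fit)
})

test_that("insufficient observations or span yield the NULL signal", {
  d <- as.Date("2017-01-01") + seq(0, 27, by = 3)
  expect_null(fit_daily_spline(pixel_series(d[1:5], rep(0.3, 5))))
  v <- seq(0.2, 0.4, length.out = 10)
  expect_null(fit_daily_spline(pixel_series(d, v)))  # span < 1 year
})

test_that("trailing-year padding copies Feb-Jun observations forward", {
  d <- seq(as.Date("2020-02-01"), as.Date("2022-01-31"), by = 5)
  v <- 0.3 + 0.1 * sin(as.numeric(d) / 50)
  s <- pixel_series(d, v)
  p <- pad_trailing_year(s)
  src <- d >= as.Date("2021-02-01") & d <= as.Date("2021-06-30")
  expect_identical(attr(p, "n_padded"), sum(src))
  expect_identical(length(p$dates), length(d) + sum(src))
  # padded copies carry the source values one year later
  shifted <- d[src] + 365
  expect_true(all(shifted %in% p$dates))
  expect_equal(p$evi2[match(shifted, p$dates)], v[src])
  # a record already past June 30 is unchanged
  d2 <- seq(as.Date("2020-02-01"), as.Date("2022-07-15"), by = 5)
  s2 <- pixel_series(d2, rep(0.3, length(d2)))
  expect_identical(pad_trailing_year(s2), s2)
})
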
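# shared test fixtures: clean daily series straight from truth curves, and
# observation vectors with an exact sample correlation to a target

# local date helpers so test code does not reach into package internals
day_num <- function(d) as.integer(as.Date(d))
num_day <- function(n) as.Date(n, origin = "1970-01-01")
jan1 <- function(y) as.Date(sprintf("%d-01-01", y))
dec31 <- function(y) as.Date(sprintf("%d-12-31", y))

truth_daily <- function(truth, start, end) {
  dates <- seq(as.Date(start), as.Date(end), by = 1)
  daily_series(dates, truth_evi2(truth, dates))
}

# perturb fitted values f into observations whose sample Pearson
# correlation with f is exactly r (deterministic for a fixed seed)
perturb_to_r <- function(f, r, seed = 1L) {
  stopifnot(length(f) >= 3L, stats::sd(f) > 0)
  set.seed(seed)
  z <- stats::rnorm(length(f))
  u <- (f - mean(f)) / stats::sd(f)
  e <- stats::residuals(stats::lm(z ~ u))
  v <- (e - mean(e)) / stats::sd(e)
  obs <- r * u + sqrt(1 - r^2) * v
  mean(f) + obs * stats::sd(f)
}

# a random truth with 0-3 bumps in the target year, used by the
# oracle-equivalence suite
random_truth <- function(seed, target_year = 2017L) {
  set.seed(seed)
  k <- sample(0:3, 1)
  if (k == 0L) return(make_truth("flat", baseline = runif(1, 0.1, 0.3)))
  sos <- sort(day_num(jan1(target_year)) +
                sample(seq(30, 300, by = 5), k)) + runif(k, -2, 2)
  len <- runif(k, 35, 90)
  make_truth("multi_cycle", baseline = runif(1, 0.08, 0.2),
             cycles = data.frame(sos = as.integer(sos),
                                 eos = as.integer(sos + len),
                                 amplitude = runif(k, 0.05, 0.6),
                                 up_rate = runif(k, 3, 8),
                                 down_rate = runif(k, 3, 8)))
}
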
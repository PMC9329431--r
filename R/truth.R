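# Ground-truth seasonal trajectories for the synthetic generator.
#
# Each growth cycle is a double-logistic bump: a greenup sigmoid and a
# greendown sigmoid sharing a plateau,
#   v(t) = baseline + sum_c A_c * plogis((t - sos_c)/r_up) *
#                            plogis(-(t - eos_c)/r_dn) + ramp * (t - t0)
# This family is the standard land-surface-phenology test function: its
# threshold-crossing days are available independently of the pipeline by
# root-finding on the continuous curve, which makes exact parameter-recovery
# tests possible.

#' Construct a ground-truth phenology trajectory
#'
#' @param kind one of `"double_logistic"` (one or more seasonal bumps),
#'   `"multi_cycle"` (alias with several short bumps), `"flat"` (constant
#'   baseline), `"ramp"` (linear trend, no cycle).
#' @param baseline dormant-season EVI2 floor (dimensionless).
#' @param cycles data.frame with one row per bump: `sos`, `eos` (Dates or
#'   day numbers: greenup / greendown sigmoid midpoints), `amplitude`,
#'   `up_rate`, `down_rate` (days; sigmoid scale parameters).
#' @param ramp_slope EVI2 change per day for `kind = "ramp"`.
#' @param ramp_origin date at which the ramp equals `baseline`.
#' @return object of class `truth_pheno`.
#' @export
make_truth <- function(kind = c("double_logistic", "multi_cycle", "flat", "ramp"),
                       baseline = 0.15, cycles = NULL,
                       ramp_slope = 0, ramp_origin = as.Date("2016-07-01")) {
  kind <- match.arg(kind)
  if (kind %in% c("double_logistic", "multi_cycle")) {
    stopifnot(is.data.frame(cycles), nrow(cycles) >= 1L)
    cycles$sos <- day_num(cycles$sos)
    cycles$eos <- day_num(cycles$eos)
    stopifnot(all(cycles$eos > cycles$sos), all(cycles$amplitude > 0),
              all(cycles$up_rate > 0), all(cycles$down_rate > 0))
  } else {
    cycles <- data.frame(sos = integer(0), eos = integer(0),
                         amplitude = numeric(0), up_rate = numeric(0),
                         down_rate = numeric(0))
  }
  structure(list(kind = kind, baseline = baseline, cycles = cycles,
                 ramp_slope = ramp_slope, ramp_origin = day_num(ramp_origin)),
            class = "truth_pheno")
}

#' Evaluate a truth trajectory
#'
#' @param truth a `truth_pheno`.
#' @param dates Dates (or day numbers) at which to evaluate.
#' @return numeric EVI2 values.
#' @export
truth_evi2 <- function(truth, dates) {
  t <- day_num(dates)
  v <- rep(truth$baseline, length(t))
  cy <- truth$cycles
  if (nrow(cy) > 0L) {
    for (i in seq_len(nrow(cy))) {
      v <- v + cy$amplitude[i] *
        stats::plogis((t - cy$sos[i]) / cy$up_rate[i]) *
        stats::plogis(-(t - cy$eos[i]) / cy$down_rate[i])
    }
  }
  if (truth$ramp_slope != 0)
    v <- v + truth$ramp_slope * (t - truth$ramp_origin)
  v
}

# convenience: one bump per listed year at fixed phenology
#' Single-season truth with one bump per year
#'
#' @param years integer years, one bump each.
#' @param baseline dormant floor.
#' @param amplitude seasonal amplitude.
#' @param sos_doy,eos_doy day-of-year of the greenup and greendown sigmoid
#'   midpoints.
#' @param up_rate,down_rate sigmoid scales in days.
#' @return a `truth_pheno`.
#' @export
truth_single_season <- function(years, baseline = 0.15, amplitude = 0.5,
                                sos_doy = 130, eos_doy = 270,
                                up_rate = 7, down_rate = 10) {
  cycles <- data.frame(
    sos = day_num(jan1(years)) + sos_doy - 1,
    eos = day_num(jan1(years)) + eos_doy - 1,
    amplitude = amplitude, up_rate = up_rate, down_rate = down_rate)
  make_truth("double_logistic", baseline = baseline, cycles = cycles)
}

#' Multi-bump (e.g. alfalfa-like) truth with several short cycles per year
#'
#' @param years integer years.
#' @param n_cycles bumps per year.
#' @param baseline,amplitude as in [truth_single_season()].
#' @param first_doy day-of-year of the first bump's greenup midpoint.
#' @param period days between successive bump midpoints.
#' @param cycle_len days between a bump's greenup and greendown midpoints.
#' @param rate sigmoid scale in days for both flanks.
#' @return a `truth_pheno`.
#' @export
truth_multi_cycle <- function(years, n_cycles = 6, baseline = 0.15,
                              amplitude = 0.4, first_doy = 60, period = 45,
                              cycle_len = 25, rate = 4) {
  starts <- unlist(lapply(years, function(y)
    day_num(jan1(y)) + first_doy - 1 + period * (seq_len(n_cycles) - 1L)))
  cycles <- data.frame(sos = starts, eos = starts + cycle_len,
                       amplitude = amplitude, up_rate = rate, down_rate = rate)
  make_truth("multi_cycle", baseline = baseline, cycles = cycles)
}

# search interval around one bump, padded well into the tails
.truth_bump_interval <- function(truth, i) {
  cy <- truth$cycles
  lo <- cy$sos[i] - 12 * cy$up_rate[i]
  hi <- cy$eos[i] + 12 * cy$down_rate[i]
  if (nrow(cy) > 1L) {
    # stay between neighbouring bumps
    if (i > 1L) lo <- max(lo, (cy$eos[i - 1L] + cy$sos[i]) / 2)
    if (i < nrow(cy)) hi <- min(hi, (cy$eos[i] + cy$sos[i + 1L]) / 2)
  }
  c(lo, hi)
}

#' Analytic phenometric truth for one bump of a trajectory
#'
#' Computes, by continuous optimisation and root-finding on the generating
#' curve itself (never on a daily grid or a spline), the peak day and the
#' 15/50/90% amplitude crossings on the greenup side and 90/50/15% crossings
#' on the greendown side. This is the independent oracle for
#' parameter-recovery tests.
#'
#' @param truth a `truth_pheno` with at least one cycle.
#' @param cycle index of the bump.
#' @return list with `peak_day`, `peak_value`, `min_up`, `min_down`,
#'   `amplitude`, and `crossings`, a named numeric vector of fractional day
#'   numbers (`up_15`, `up_50`, `up_90`, `down_90`, `down_50`, `down_15`).
#' @export
truth_cycle_metrics <- function(truth, cycle = 1L) {
  stopifnot(nrow(truth$cycles) >= cycle)
  iv <- .truth_bump_interval(truth, cycle)
  f <- function(t) truth_evi2(truth, t)
  op <- stats::optimize(f, iv, maximum = TRUE, tol = 1e-8)
  peak_day <- op$maximum; peak_value <- op$objective
  min_up <- stats::optimize(f, c(iv[1], peak_day), tol = 1e-8)
  min_dn <- stats::optimize(f, c(peak_day, iv[2]), tol = 1e-8)
  amp_up <- peak_value - min_up$objective
  amp_dn <- peak_value - min_dn$objective
  cross_up <- function(frac) {
    thr <- min_up$objective + frac * amp_up
    stats::uniroot(function(t) f(t) - thr, c(min_up$minimum, peak_day),
                   tol = 1e-8)$root
  }
  cross_dn <- function(frac) {
    thr <- min_dn$objective + frac * amp_dn
    stats::uniroot(function(t) f(t) - thr, c(peak_day, min_dn$minimum),
                   tol = 1e-8)$root
  }
  list(peak_day = peak_day, peak_value = peak_value,
       min_up = min_up$objective, min_down = min_dn$objective,
       amplitude = amp_up,
       crossings = c(up_15 = cross_up(0.15), up_50 = cross_up(0.50),
                     up_90 = cross_up(0.90), down_90 = cross_dn(0.90),
                     down_50 = cross_dn(0.50), down_15 = cross_dn(0.15)))
}

#' Save a per-pixel truth phenology table as netCDF
#'
#' One record per pixel and bump, for later comparison against the decoded
#' product. Layout: fixed dims `record` x `field`.
#'
#' @param truth_map list of `truth_pheno`, one per pixel (row-major).
#' @param site a `site_window`.
#' @param path output netCDF path.
#' @return `path`, invisibly.
#' @export
write_truth_netcdf <- function(truth_map, site, path) {
  rows <- list()
  for (p in seq_along(truth_map)) {
    tr <- truth_map[[p]]
    if (nrow(tr$cycles) == 0L) next
    for (ci in seq_len(nrow(tr$cycles))) {
      m <- truth_cycle_metrics(tr, ci)
      rows[[length(rows) + 1L]] <-
        c(p, ci, m$peak_day, m$peak_value, m$amplitude, tr$baseline,
          m$crossings)
    }
  }
  fields <- c("pixel", "cycle", "peak_day", "peak_value", "amplitude",
              "baseline", "up_15", "up_50", "up_90", "down_90", "down_50",
              "down_15")
  dat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), ncol = length(fields))
  nc3_write(path,
            dims = c(record = nrow(dat), field = length(fields)),
            vars = list(list(name = "truth", dims = c("record", "field"),
                             type = NC_DOUBLE, data = dat,
                             atts = list(fields = paste(fields, collapse = ",")))),
            global_atts = list(site_code = site$site_code,
                               title = "synthetic ground-truth phenology"))
  invisible(path)
}
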
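# Phenometrics: seven timing metrics, three greenness metrics, the annual
# metrics for zero-cycle pixels, and per-cycle QA flags.

TIMING_NAMES <- c("OGI", "50PCGI", "OGMx", "Peak", "OGD", "50PCGD", "OGMn")

#' Seven timing metrics of a growth cycle
#'
#' Greenup crossings are the first days, between cycle start and peak, on
#' which the daily series reaches 15%, 50% and 90% of the cycle amplitude
#' above the greenup-side minimum (OGI, 50PCGI, OGMx). Peak is the peak
#' day. Greendown crossings are the first days, between peak and cycle
#' end, on which the series drops to 90%, 50% and 15% of the descending
#' amplitude above the greendown-side minimum (OGD, 50PCGD, OGMn). All are
#' day-of-year integers relative to the target year (Jan 1 = 1; days in
#' the preceding year are negative or zero).
#'
#' @param cycle a `growth_cycle`.
#' @param daily the `daily_series` it was detected on.
#' @param target_year integer year the metrics are referenced to.
#' @return named integer vector `OGI`, `50PCGI`, `OGMx`, `Peak`, `OGD`,
#'   `50PCGD`, `OGMn`.
#' @export
timing_metrics <- function(cycle, daily, target_year) {
  d <- day_num(daily$dates)
  v <- daily$evi2_fit
  i0 <- match(day_num(cycle$start_day), d)
  ip <- match(day_num(cycle$peak_day), d)
  i1 <- match(day_num(cycle$end_day), d)
  up <- i0:ip; down <- ip:i1
  amp_up <- cycle$peak_value - cycle$greenup_min
  amp_dn <- cycle$peak_value - cycle$greendown_min
  first_at_or_above <- function(frac) {
    thr <- cycle$greenup_min + frac * amp_up
    up[which(v[up] >= thr)[1]]
  }
  first_at_or_below <- function(frac) {
    thr <- cycle$greendown_min + frac * amp_dn
    down[which(v[down] <= thr)[1]]
  }
  idx <- c(first_at_or_above(0.15), first_at_or_above(0.50),
           first_at_or_above(0.90), ip,
           first_at_or_below(0.90), first_at_or_below(0.50),
           first_at_or_below(0.15))
  stats::setNames(doy_rel(daily$dates[idx], target_year), TIMING_NAMES)
}

#' Greenness metrics of a growth cycle
#'
#' `EVImax` is the peak value, `EVIamp` the greenup-side amplitude (the
#' quantity the acceptance criteria act on), and `EVIarea` the sum of the
#' daily fitted EVI2 from the greenup-onset day (OGI) through the dormancy
#' day (OGMn), inclusive.
#'
#' @param cycle a `growth_cycle`.
#' @param daily its `daily_series`.
#' @param timing output of [timing_metrics()].
#' @param target_year integer year.
#' @return named numeric vector `EVImax`, `EVIamp`, `EVIarea`.
#' @export
greenness_metrics <- function(cycle, daily, timing, target_year) {
  d0 <- day_num(jan1(target_year)) + timing[["OGI"]] - 1L
  d1 <- day_num(jan1(target_year)) + timing[["OGMn"]] - 1L
  d <- day_num(daily$dates)
  span <- d >= d0 & d <= d1
  c(EVImax = cycle$peak_value,
    EVIamp = cycle$amplitude,
    EVIarea = sum(daily$evi2_fit[span]))
}

#' Annual metrics for a pixel (reported even with zero cycles)
#'
#' `numObs` counts the calendar days of the target year with at least one
#' clear observation. For pixels without a detected cycle the greenness
#' triple is computed from the daily fit over the calendar year: its
#' maximum, its range, and its sum.
#'
#' @param daily a `daily_series` (may be `NULL`).
#' @param target_year integer year.
#' @param clear_dates Dates with clear observations (defaults to the
#'   fitted observations flagged clear).
#' @return named numeric vector `EVImax`, `EVIamp`, `EVIarea`, `numObs`.
#' @export
annual_metrics <- function(daily, target_year,
                           clear_dates = daily$obs_dates[daily$obs_status == "clear"]) {
  n_obs <- length(unique(clear_dates[year_of(clear_dates) == target_year]))
  if (is.null(daily))
    return(c(EVImax = NA_real_, EVIamp = NA_real_, EVIarea = NA_real_,
             numObs = n_obs))
  in_year <- year_of(daily$dates) == target_year
  v <- daily$evi2_fit[in_year]
  c(EVImax = max(v), EVIamp = max(v) - min(v), EVIarea = sum(v),
    numObs = n_obs)
}

#' Quality-assurance flag for a detected cycle
#'
#' Per phase (greenup: start to peak; greendown: peak to end) the Pearson
#' correlation between clear observations and the fitted values at the
#' observation dates, and the maximum gap in days between consecutive
#' clear observations, are computed. QA 1 (high): r > `r_min` and gap <
#' `gap_max` in every phase. QA 2 (moderate): exactly one of {r below
#' threshold anywhere, gap at or above threshold anywhere}. QA 3 (low):
#' both. QA 4: no cycle detected, or fewer than 3 clear observations in a
#' phase. Undefined correlations (constant segments) count as a
#' correlation violation.
#'
#' @param cycle a `growth_cycle`, or `NULL` (no cycle detected).
#' @param daily its `daily_series`.
#' @param obs_dates,obs_values clear observations; default: the fitted
#'   observations flagged clear.
#' @param r_min correlation threshold (default 0.75).
#' @param gap_max gap threshold in days (default 30).
#' @return integer QA class in 1:4.
#' @export
qa_flag <- function(cycle, daily,
                    obs_dates = daily$obs_dates[daily$obs_status == "clear"],
                    obs_values = daily$obs_values[daily$obs_status == "clear"],
                    r_min = 0.75, gap_max = 30) {
  if (is.null(cycle) || is.null(daily)) return(4L)
  d_obs <- day_num(obs_dates)
  fit_at <- daily$evi2_fit[match(d_obs, day_num(daily$dates))]
  phases <- list(c(day_num(cycle$start_day), day_num(cycle$peak_day)),
                 c(day_num(cycle$peak_day), day_num(cycle$end_day)))
  viol_r <- FALSE; viol_g <- FALSE
  for (ph in phases) {
    sel <- which(d_obs >= ph[1] & d_obs <= ph[2] & !is.na(fit_at))
    if (length(sel) < 3L) return(4L)
    o <- obs_values[sel]; f <- fit_at[sel]
    r <- if (stats::sd(o) == 0 || stats::sd(f) == 0) NA_real_ else
      stats::cor(o, f)
    if (is.na(r) || r <= r_min) viol_r <- TRUE
    if (max(diff(sort(d_obs[sel]))) >= gap_max) viol_g <- TRUE
  }
  if (!viol_r && !viol_g) 1L else if (viol_r && viol_g) 3L else 2L
}

#' All phenometrics of one pixel for one target year
#'
#' Runs cycle detection, the timing/greenness metrics and QA for the two
#' largest-amplitude cycles, and the annual metrics.
#'
#' @param daily a `daily_series` (or `NULL` for insufficient data).
#' @param target_year integer year.
#' @param params parameter list (see [default_config()]).
#' @param clear_dates optional Dates of clear observations (for `numObs`
#'   and QA); defaults to the fitted observations flagged clear.
#' @return named numeric vector over all 24 product quantities
#'   (`NumCycles`, the 7 + 3 metrics for cycles 1 and 2, `QA`, `QA_2`,
#'   `numObs`), with `NA` where a layer is fill-coded.
#' @export
pixel_phenometrics <- function(daily, target_year, params = default_config(),
                               clear_dates = NULL) {
  layer_names <- product_layer_names()
  out <- stats::setNames(rep(NA_real_, length(layer_names)), layer_names)
  if (is.null(clear_dates) && !is.null(daily))
    clear_dates <- daily$obs_dates[daily$obs_status == "clear"]
  cs <- detect_cycles(daily, target_year, params)
  if (is.null(cs)) {                       # insufficient data
    out["QA"] <- 4; out["QA_2"] <- 4
    out["numObs"] <- if (is.null(clear_dates)) 0 else
      length(unique(clear_dates[year_of(clear_dates) == target_year]))
    return(out)
  }
  ann <- annual_metrics(daily, target_year, clear_dates)
  out["NumCycles"] <- cs$num_cycles
  out["numObs"] <- ann[["numObs"]]
  if (cs$num_cycles == 0L) {
    out["EVImax"] <- ann[["EVImax"]]
    out["EVIamp"] <- ann[["EVIamp"]]
    out["EVIarea"] <- ann[["EVIarea"]]
    out["QA"] <- 4; out["QA_2"] <- 4
    return(out)
  }
  for (k in seq_along(cs$reported)) {
    cyc <- cs$reported[[k]]
    suf <- if (k == 1L) "" else "_2"
    tm <- timing_metrics(cyc, daily, target_year)
    gm <- greenness_metrics(cyc, daily, tm, target_year)
    out[paste0(TIMING_NAMES, suf)] <- tm
    out[paste0(c("EVImax", "EVIamp", "EVIarea"), suf)] <- gm
    out[paste0("QA", if (k == 1L) "" else "_2")] <-
      qa_flag(cyc, daily, r_min = params$qa_r, gap_max = params$qa_gap)
  }
  if (length(cs$reported) < 2L) out["QA_2"] <- 4
  out
}
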
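# Series conditioning: index computation, outlier and snow screening,
# background estimation and flooring, and penalized cubic smoothing-spline
# gap-filling to a continuous daily series.

#' Two-band Enhanced Vegetation Index
#'
#' EVI2 = 2.5 (NIR - Red) / (NIR + 2.4 Red + 1). Vectorizes over rasters;
#' the denominator is positive for physical reflectance.
#'
#' @param nir,red reflectances (scalars, vectors or matrices).
#' @return index values with the shape of the inputs.
#' @examples
#' compute_evi2(0.4, 0.1)  # 2.5 * 0.3 / 1.64
#' @export
compute_evi2 <- function(nir, red) {
  2.5 * (nir - red) / (nir + 2.4 * red + 1)
}

#' Screen an observation series for negatives, snow and spikes
#'
#' A pure classification pass: statuses are recomputed from the raw values
#' and the snow-mask channel, so screening is idempotent. Negative EVI2
#' values are flagged `"negative"`. Snow flags from the mask channel are
#' kept. A remaining observation is a `"spike"` when its deviation from the
#' median of the surrounding temporal window exceeds
#' `max(spike_abs, spike_rel * local range)` and both immediate neighbours
#' lie on the same side of it, i.e. the excursion is a single-date island
#' rather than part of a rapid but real transition.
#'
#' @param series a `pixel_series`.
#' @param spike_window half-width of the temporal window in days (default
#'   15).
#' @param spike_abs absolute deviation floor (default 0.1 EVI2).
#' @param spike_rel relative deviation threshold as a fraction of the local
#'   range (default 0.3).
#' @return the series with statuses among `"clear"`, `"snow"`,
#'   `"negative"`, `"spike"`.
#' @export
screen_observations <- function(series, spike_window = 15, spike_abs = 0.1,
                                spike_rel = 0.3) {
  d <- day_num(series$dates)
  v <- series$evi2
  snow <- series$status == "snow"
  status <- ifelse(snow, "snow", "clear")
  status[!snow & v < 0] <- "negative"
  cand <- which(status == "clear")
  usable <- status == "clear"           # snow-free, non-negative support
  for (i in cand) {
    win <- which(usable & abs(d - d[i]) <= spike_window)
    win <- setdiff(win, i)
    if (length(win) < 3L) next
    med <- stats::median(v[win])
    rng <- diff(range(v[win]))
    thresh <- max(spike_abs, spike_rel * rng)
    if (abs(v[i] - med) <= thresh) next
    nb <- c(max(cand[cand < i], -Inf), min(cand[cand > i], Inf))
    if (!is.finite(nb[1]) || !is.finite(nb[2])) next
    same_side <- sign(v[i] - v[nb[1]]) == sign(v[i] - v[nb[2]]) &&
      sign(v[i] - v[nb[1]]) != 0
    if (same_side) status[i] <- "spike"
  }
  series$status <- status
  series
}

#' Background (dormant-season) EVI2 of a pixel
#'
#' The 10th percentile (linear interpolation between order statistics) of
#' the snow-free, non-spike, non-negative observations. With fewer than
#' `min_obs` such observations the pixel carries too little information and
#' `NA` is returned as an insufficient-data signal (consumed downstream as
#' QA class 4).
#'
#' @param series a screened `pixel_series`.
#' @param prob percentile as a probability (default 0.10).
#' @param min_obs minimum usable observations (default 10).
#' @return scalar background EVI2, or `NA_real_`.
#' @export
compute_background <- function(series, prob = 0.10, min_obs = 10L) {
  v <- series$evi2[series$status == "clear"]
  if (length(v) < min_obs) return(NA_real_)
  unname(stats::quantile(v, prob, type = 7))
}

#' Replace sub-background and contaminated observations with the background
#'
#' Observations below the background are raised to it, and snow, spike and
#' negative dates are re-admitted at the background value, so winters with
#' persistent snow still anchor the dormant baseline instead of leaving the
#' spline unsupported for months.
#'
#' @param series a screened `pixel_series`.
#' @param background scalar background EVI2 (see [compute_background()]).
#' @return the series with replaced observations flagged
#'   `"below_background"`.
#' @export
floor_to_background <- function(series, background) {
  if (is.na(background)) return(series)
  contaminated <- series$status %in% c("snow", "spike", "negative")
  low <- !contaminated & series$evi2 < background
  series$evi2[contaminated | low] <- background
  series$status[contaminated | low] <- "below_background"
  series
}

#' Pad the trailing target year with the previous year's late-winter and
#' spring observations
#'
#' When the record stops early in the final calendar year (e.g. at the end
#' of January), phenometrics for the preceding target year lack post-season
#' support. Observations dated February 1 through June 30 of the last full
#' year are copied onto the corresponding dates of the final year before
#' fitting. Records already extending past June 30 of the final year are
#' returned unchanged.
#'
#' @param series a `pixel_series`.
#' @return the padded series; padded observations keep their status.
#' @export
pad_trailing_year <- function(series) {
  last <- max(series$dates)
  y_end <- year_of(last)
  if (last >= as.Date(sprintf("%d-06-30", y_end))) return(series)
  src_year <- y_end - 1L
  from <- as.Date(sprintf("%d-02-01", src_year))
  to <- as.Date(sprintf("%d-06-30", src_year))
  idx <- which(series$dates >= from & series$dates <= to)
  if (length(idx) == 0L) return(series)
  shift <- day_num(jan1(y_end)) - day_num(jan1(src_year))
  new_dates <- num_day(day_num(series$dates[idx]) + shift)
  keep <- new_dates > last
  if (!any(keep)) return(series)
  all_dates <- c(series$dates, new_dates[keep])
  ord <- order(all_dates)
  out <- pixel_series(all_dates[ord],
                      c(series$evi2, series$evi2[idx][keep])[ord],
                      c(series$status, series$status[idx][keep])[ord])
  attr(out, "n_padded") <- sum(keep)
  out
}

#' Gap-fill and smooth a pixel series to daily resolution
#'
#' Fits a penalized cubic smoothing spline (generalized cross-validation
#' chooses the penalty unless `lambda` or `spar` is fixed; `spar_low`
#' bounds the search from below so the fit does not chase noise) through
#' the usable observations (status `"clear"` or `"below_background"`) and
#' evaluates it on every calendar day of the record. The daily fit is then
#' floored at the background.
#'
#' @param series a floored `pixel_series`.
#' @param record_start,record_end record span (Dates); defaults to the
#'   observation range.
#' @param background scalar background (used to floor the daily fit);
#'   `NA` skips flooring.
#' @param min_obs minimum usable observations (default 10).
#' @param min_span_days minimum observation span (default 365).
#' @param lambda optional fixed smoothing penalty passed to
#'   [stats::smooth.spline()].
#' @param spar optional fixed smoothing parameter (overrides GCV).
#' @param spar_low lower bound for the GCV search over `spar`.
#' @return object of class `daily_series`: `dates` (every day), `evi2_fit`,
#'   `background`, `obs_dates`, `obs_values`, `obs_status`, `residuals`; or
#'   `NULL` as the insufficient-data signal.
#' @export
fit_daily_spline <- function(series, record_start = NULL, record_end = NULL,
                             background = NA_real_, min_obs = 10L,
                             min_span_days = 365, lambda = NULL, spar = NULL,
                             spar_low = -0.5) {
  use <- series$status %in% c("clear", "below_background")
  d <- day_num(series$dates[use])
  v <- series$evi2[use]
  st <- series$status[use]
  if (length(d) < max(min_obs, 4L)) return(NULL)
  if (diff(range(d)) < min_span_days) return(NULL)
  # collapse duplicate days (smooth.spline handles ties, but keep it exact)
  if (anyDuplicated(d)) {
    v <- as.numeric(tapply(v, d, mean))
    st <- as.character(tapply(st, d, function(s)
      if (any(s == "clear")) "clear" else s[1]))
    d <- sort(unique(d))
  }
  args <- list(x = d, y = v, cv = FALSE, keep.data = FALSE)
  if (!is.null(lambda)) args$lambda <- lambda
  else if (!is.null(spar)) args$spar <- spar
  else args$control.spar <- list(low = spar_low)
  sp <- do.call(stats::smooth.spline, args)
  start <- day_num(record_start %||% min(series$dates))
  end <- day_num(record_end %||% max(series$dates))
  days <- seq.int(start, end)
  fit <- stats::predict(sp, days)$y
  if (!is.na(background)) fit <- pmax(fit, background)
  resid <- v - stats::predict(sp, d)$y
  structure(list(dates = num_day(days), evi2_fit = fit,
                 background = background,
                 obs_dates = num_day(d), obs_values = v,
                 obs_status = st, residuals = resid),
            class = "daily_series")
}

#' Construct a daily series directly from daily values
#'
#' Mainly for feeding analytically known trajectories straight into cycle
#' detection without an intermediate spline fit.
#'
#' @param dates consecutive calendar days.
#' @param values finite EVI2 values, one per day.
#' @param background optional scalar background (default: series minimum).
#' @return a `daily_series`.
#' @export
daily_series <- function(dates, values, background = min(values)) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values), all(is.finite(values)),
            all(diff(day_num(dates)) == 1L))
  structure(list(dates = dates, evi2_fit = as.numeric(values),
                 background = background,
                 obs_dates = dates, obs_values = as.numeric(values),
                 obs_status = rep("clear", length(dates)),
                 residuals = numeric(length(dates))),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s .. %s (%d days), background %.4g\n",
              min(x$dates), max(x$dates), length(x$dates), x$background))
  invisible(x)
}

#' Condition one pixel series end to end
#'
#' Screen, establish the background, floor, pad the trailing year, and fit
#' the daily spline.
#'
#' @param series a raw `pixel_series`.
#' @param record_start,record_end record span for the daily grid.
#' @param params parameter list (see [default_config()]); relevant entries:
#'   `spike_window`, `spike_abs`, `spike_rel`, `background_prob`,
#'   `min_obs`, `min_span_days`, `spar`, `lambda`, `spar_low`,
#'   `pad_trailing`.
#' @return a `daily_series`, or `NULL` on insufficient data.
#' @export
condition_series <- function(series, record_start = NULL, record_end = NULL,
                             params = default_config()) {
  s <- screen_observations(series, params$spike_window, params$spike_abs,
                           params$spike_rel)
  bg <- compute_background(s, params$background_prob, params$min_obs)
  if (is.na(bg)) return(NULL)
  s <- floor_to_background(s, bg)
  if (isTRUE(params$pad_trailing)) {
    s <- pad_trailing_year(s)
    # the daily grid follows the padded support past the nominal record end
    if (!is.null(record_end)) record_end <- max(as.Date(record_end), max(s$dates))
  }
  fit_daily_spline(s, record_start, record_end, background = bg,
                   min_obs = params$min_obs,
                   min_span_days = params$min_span_days,
                   lambda = params$lambda, spar = params$spar,
                   spar_low = params$spar_low)
}
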
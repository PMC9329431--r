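# Growth-cycle detection on daily EVI2 series.
#
# Candidate peaks are local maxima of the daily series; each is validated
# against two amplitude criteria — the rise from the greenup-side local
# minimum must be at least `min_amplitude` (0.1) AND at least
# `rel_amplitude` (35%) of the total EVI2 range over the 24-month window
# centred on the peak's year — and two timing constraints: the cycle start
# lies within `max_rise` (185) days before the peak and at least
# `min_peak_sep` (30) days after the previous accepted peak, with the
# mirrored constraints bounding the cycle end. Peaks are assessed
# recursively in descending peak value so dominant seasons constrain
# subordinate ones.

#' Find local peaks of a daily series
#'
#' A day is a peak when its value is the maximum of its +/- `window`-day
#' neighbourhood and the neighbourhood is not flat; ties (plateaus) break
#' to the earliest day. The first and last days of the record are never
#' peaks.
#'
#' @param daily a `daily_series`.
#' @param window neighbourhood half-width in days (default 15).
#' @return integer indices into `daily$dates` (possibly empty).
#' @export
find_local_peaks <- function(daily, window = 15L) {
  v <- daily$evi2_fit
  n <- length(v)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  for (i in 2:(n - 1L)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    win <- v[lo:hi]
    if (v[i] < max(win) || max(win) == min(win)) next
    # tie-break to the earliest day achieving the window maximum
    if (i > lo && any(v[lo:(i - 1L)] == v[i])) next
    peaks <- c(peaks, i)
  }
  peaks
}

#' Validate one candidate peak as a growth cycle
#'
#' @param daily a `daily_series`.
#' @param peak_idx index of the candidate peak.
#' @param prev_peak_day,next_peak_day day numbers of the neighbouring
#'   accepted peaks (or `NULL`).
#' @param params parameter list; uses `min_amplitude`, `rel_amplitude`,
#'   `max_rise`, `min_peak_sep`.
#' @return a `growth_cycle` (list with `start_day`, `peak_day`, `end_day`
#'   as Dates, `greenup_min`, `greendown_min`, `peak_value`, `amplitude`),
#'   or `NULL` when the candidate is rejected.
#' @export
validate_cycle <- function(daily, peak_idx, prev_peak_day = NULL,
                           next_peak_day = NULL, params = default_config()) {
  d <- day_num(daily$dates)
  v <- daily$evi2_fit
  n <- length(v)
  pd <- d[peak_idx]
  lo_day <- max(d[1], pd - params$max_rise,
                if (!is.null(prev_peak_day)) prev_peak_day + params$min_peak_sep else -Inf)
  hi_day <- min(d[n], pd + params$max_rise,
                if (!is.null(next_peak_day)) next_peak_day - params$min_peak_sep else Inf)
  lo <- match(lo_day, d); hi <- match(hi_day, d)
  if (is.na(lo) || is.na(hi) || lo >= peak_idx || hi <= peak_idx) return(NULL)
  up_seg <- lo:peak_idx
  start_idx <- up_seg[which.min(v[up_seg])]
  greenup_min <- v[start_idx]
  down_seg <- peak_idx:hi
  end_idx <- down_seg[which.min(v[down_seg])]
  greendown_min <- v[end_idx]
  if (start_idx >= peak_idx || end_idx <= peak_idx) return(NULL)
  amplitude <- v[peak_idx] - greenup_min
  amplitude_dn <- v[peak_idx] - greendown_min
  # 24-month context: the peak's calendar year +/- 6 months
  yr <- year_of(daily$dates[peak_idx])
  ctx <- d >= day_num(jan1(yr)) - 183L & d <= day_num(dec31(yr)) + 182L
  ctx_range <- diff(range(v[ctx]))
  eps <- 1e-9
  # the min/max difference criteria apply on both flanks: the same
  # procedure runs in reverse at the cycle end, which rejects spurious
  # secondary peaks riding on a season plateau
  if (min(amplitude, amplitude_dn) < params$min_amplitude - eps) return(NULL)
  if (min(amplitude, amplitude_dn) < params$rel_amplitude * ctx_range - eps)
    return(NULL)
  structure(list(start_day = daily$dates[start_idx],
                 peak_day = daily$dates[peak_idx],
                 end_day = daily$dates[end_idx],
                 greenup_min = greenup_min, greendown_min = greendown_min,
                 peak_value = v[peak_idx], amplitude = amplitude),
            class = "growth_cycle")
}

#' Detect growth cycles and assign them to a target year
#'
#' Every local peak is assessed exactly once, in descending peak value;
#' accepted peaks constrain the start/end search windows of peaks assessed
#' later. Cycles are assigned to the target year by their peak date. The
#' daily series must cover the target year with at least
#' `params$min_margin_days` days of margin on each side, otherwise the
#' insufficient-data signal (`NULL`) is returned.
#'
#' @param daily a `daily_series`.
#' @param target_year integer calendar year.
#' @param params parameter list (see [default_config()]).
#' @return object of class `cycle_set`: `target_year`, `cycles` (accepted,
#'   ordered by start day), `num_cycles`, `reported` (up to 2, by
#'   descending amplitude); or `NULL` when coverage is insufficient.
#' @export
detect_cycles <- function(daily, target_year, params = default_config()) {
  if (is.null(daily)) return(NULL)
  d <- day_num(daily$dates)
  need_lo <- day_num(jan1(target_year)) - params$min_margin_days
  need_hi <- day_num(dec31(target_year)) + params$min_margin_days
  if (d[1] > need_lo || d[length(d)] < need_hi) return(NULL)
  peaks <- find_local_peaks(daily, params$peak_window)
  ord <- peaks[order(-daily$evi2_fit[peaks], peaks)]
  accepted <- list()
  accepted_days <- numeric(0)
  for (p in ord) {
    pd <- d[p]
    if (any(abs(accepted_days - pd) < params$min_peak_sep)) next
    prev <- if (any(accepted_days < pd)) max(accepted_days[accepted_days < pd]) else NULL
    nxt <- if (any(accepted_days > pd)) min(accepted_days[accepted_days > pd]) else NULL
    cyc <- validate_cycle(daily, p, prev, nxt, params)
    if (is.null(cyc)) next
    accepted[[length(accepted) + 1L]] <- cyc
    accepted_days <- c(accepted_days, pd)
  }
  in_year <- vapply(accepted, function(cy) year_of(cy$peak_day) == target_year, TRUE)
  cycles <- accepted[in_year]
  if (length(cycles) > 1L) {
    cycles <- cycles[order(vapply(cycles, function(cy) day_num(cy$start_day), 0))]
  }
  amps <- vapply(cycles, function(cy) cy$amplitude, 0)
  reported <- cycles[order(-amps)][seq_len(min(2L, length(cycles)))]
  structure(list(target_year = target_year, cycles = cycles,
                 num_cycles = length(cycles), reported = reported),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> year %d: %d cycle(s), %d reported\n",
              x$target_year, x$num_cycles, length(x$reported)))
  invisible(x)
}
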
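# Independent brute-force cycle enumerator. Applies the same acceptance
# criteria as the detector but is written as plain exhaustive scans over
# the daily vector, sharing no code with the package implementation.

brute_force_cycles <- function(daily, target_year, params = default_config()) {
  v <- daily$evi2_fit
  d <- day_num(daily$dates)
  n <- length(v)
  w <- params$peak_window
  # candidate peaks by direct neighbourhood scan
  cand <- c()
  for (i in 2:(n - 1)) {
    lo <- max(1, i - w); hi <- min(n, i + w)
    if (v[i] != max(v[lo:hi])) next
    if (max(v[lo:hi]) == min(v[lo:hi])) next
    dup <- FALSE
    for (j in lo:(i - 1)) if (v[j] == v[i]) { dup <- TRUE; break }
    if (!dup) cand <- c(cand, i)
  }
  cand <- cand[order(-v[cand], cand)]
  acc <- list(); acc_days <- c()
  for (p in cand) {
    pd <- d[p]
    if (length(acc_days) && min(abs(acc_days - pd)) < params$min_peak_sep) next
    prevs <- acc_days[acc_days < pd]; nxts <- acc_days[acc_days > pd]
    lo_day <- max(d[1], pd - params$max_rise,
                  if (length(prevs)) max(prevs) + params$min_peak_sep else d[1])
    hi_day <- min(d[n], pd + params$max_rise,
                  if (length(nxts)) min(nxts) - params$min_peak_sep else d[n])
    lo <- which(d == lo_day); hi <- which(d == hi_day)
    if (!length(lo) || !length(hi) || lo >= p || hi <= p) next
    # exhaustive minima search on each flank
    s_idx <- lo; for (k in lo:p) if (v[k] < v[s_idx]) s_idx <- k
    e_idx <- p; for (k in p:hi) if (v[k] < v[e_idx]) e_idx <- k
    if (s_idx >= p || e_idx <= p) next
    amp_up <- v[p] - v[s_idx]; amp_dn <- v[p] - v[e_idx]
    yr <- as.integer(format(daily$dates[p], "%Y"))
    in_ctx <- d >= day_num(jan1(yr)) - 183 & d <= day_num(dec31(yr)) + 182
    rng <- max(v[in_ctx]) - min(v[in_ctx])
    if (min(amp_up, amp_dn) < params$min_amplitude - 1e-9) next
    if (min(amp_up, amp_dn) < params$rel_amplitude * rng - 1e-9) next
    acc[[length(acc) + 1]] <- list(start = d[s_idx], peak = pd, end = d[e_idx],
                                   amplitude = amp_up)
    acc_days <- c(acc_days, pd)
  }
  keep <- vapply(acc, function(cy)
    as.integer(format(num_day(cy$peak), "%Y")) == target_year, TRUE)
  out <- acc[keep]
  out[order(vapply(out, function(cy) cy$start, 0))]
}
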
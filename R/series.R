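#' Per-pixel vegetation-index observation series
#'
#' @param dates strictly increasing Dates.
#' @param evi2 numeric EVI2 values, same length.
#' @param status per-observation flag, one of `"clear"`, `"snow"`,
#'   `"spike"`, `"negative"`, `"below_background"`.
#' @return object of class `pixel_series`.
#' @export
pixel_series <- function(dates, evi2,
                         status = rep("clear", length(dates))) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(evi2), length(status) == length(evi2))
  if (length(dates) == 0L) stop("empty series: no observation dates")
  if (is.unsorted(dates, strictly = TRUE))
    stop("observation dates must be strictly increasing")
  ok <- c("clear", "snow", "spike", "negative", "below_background")
  if (!all(status %in% ok))
    stop("unknown status value(s): ", paste(setdiff(status, ok), collapse = ", "))
  structure(list(dates = dates, evi2 = as.numeric(evi2),
                 status = as.character(status)),
            class = "pixel_series")
}

#' @export
print.pixel_series <- function(x, ...) {
  cat(sprintf("<pixel_series> %d obs, %s .. %s; status: %s\n",
              length(x$dates), min(x$dates), max(x$dates),
              paste(sprintf("%s=%d", names(table(x$status)),
                            as.integer(table(x$status))), collapse = " ")))
  invisible(x)
}

#' Simulate an irregular EVI2 observation series from a truth trajectory
#'
#' Emulates the statistical structure of masked, mosaicked satellite
#' observations: Gaussian radiometric noise, random acquisition gaps,
#' occasional strongly negative spikes (cloud-shadow / aerosol artefacts),
#' and snow-contaminated excursions that are flagged in the status channel
#' (the analogue of a scene-level snow mask) rather than silently dropped.
#'
#' The injected contamination is recorded in the `"truth_log"` attribute
#' (`spike_dates`, `snow_dates`, `dropped_dates`) so recovery tests can
#' compare screening output with the generator's own bookkeeping.
#'
#' @param truth a `truth_pheno`.
#' @param dates candidate acquisition Dates (ascending).
#' @param noise_sd Gaussian noise standard deviation (EVI2 units).
#' @param gap_prob probability an acquisition date is dropped.
#' @param spike_prob probability a retained observation is replaced by a
#'   negative spike.
#' @param snow_prob probability a retained observation is snow-contaminated.
#' @param seed integer; fixes the random stream.
#' @return a `pixel_series` with attribute `"truth_log"`.
#' @export
simulate_series <- function(truth, dates, noise_sd = 0.02, gap_prob = 0.15,
                            spike_prob = 0.02, snow_prob = 0.03, seed = 1L) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty series: no observation dates")
  stopifnot(!is.unsorted(dates),
            gap_prob >= 0, gap_prob <= 1, spike_prob >= 0, spike_prob <= 1,
            snow_prob >= 0, snow_prob <= 1, noise_sd >= 0)
  set.seed(seed)
  keep <- stats::runif(length(dates)) >= gap_prob
  d <- dates[keep]
  if (length(d) == 0L) stop("all dates dropped; lower gap_prob")
  v <- truth_evi2(truth, d) + stats::rnorm(length(d), sd = noise_sd)
  status <- rep("clear", length(d))
  u <- stats::runif(length(d))
  spike <- u < spike_prob
  snow <- !spike & u < spike_prob + snow_prob
  # negative spikes: strongly depressed values the de-spiker must catch
  v[spike] <- -stats::runif(sum(spike), 0.06, 0.30)
  # snow pushes the apparent index up or down; the mask channel knows
  v[snow] <- v[snow] + sample(c(-1, 1), sum(snow), replace = TRUE) *
    stats::runif(sum(snow), 0.15, 0.45)
  status[snow] <- "snow"
  out <- pixel_series(d, v, status)
  attr(out, "truth_log") <- list(spike_dates = d[spike], snow_dates = d[snow],
                                 dropped_dates = dates[!keep])
  out
}
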
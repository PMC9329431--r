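# End-to-end orchestration: configuration, the site/year product loop, and
# deterministic toy fixtures.

#' Default pipeline configuration
#'
#' Every numeric rule of the production algorithm with its standard value:
#' scene filters (`max_cloud` 0.5, standard quality, ground control),
#' screening (`spike_window` 15 d, `spike_abs` 0.1, `spike_rel` 0.3),
#' background (`background_prob` 0.1, `min_obs` 10), cycle criteria
#' (`min_amplitude` 0.1, `rel_amplitude` 0.35, `max_rise` 185 d,
#' `min_peak_sep` 30 d, `peak_window` 15 d), QA thresholds (`qa_r` 0.75,
#' `qa_gap` 30 d), record span (July 1 2016 - Jan 31 2022), target years
#' 2017-2021, and `n_tiles` 200.
#'
#' @param ... named overrides (logged in the run log).
#' @return named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    record_start = as.Date("2016-07-01"),
    record_end = as.Date("2022-01-31"),
    target_years = 2017:2021,
    max_cloud = 0.5,
    require_standard = TRUE,
    require_ground_control = TRUE,
    spike_window = 15, spike_abs = 0.1, spike_rel = 0.3,
    background_prob = 0.10, min_obs = 10L, min_span_days = 365,
    lambda = NULL, spar = NULL, spar_low = -0.5,
    pad_trailing = TRUE,
    peak_window = 15L, min_amplitude = 0.1, rel_amplitude = 0.35,
    max_rise = 185, min_peak_sep = 30, min_margin_days = 180L,
    qa_r = 0.75, qa_gap = 30,
    n_tiles = 200L,
    seed = 1L)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  attr(cfg, "overridden") <- names(overrides)
  cfg
}

# stable short hash of the serialized config, stamped into provenance
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251)) %% .Machine$integer.max)
}

#' Run the full pipeline for one site over a scene catalogue
#'
#' Filters the catalogue, applies pixel masks, builds same-day mean
#' composites, tiles the window, conditions every pixel series, detects
#' growth cycles, computes phenometrics for each target year, and writes
#' one encoded product file per year. Tiles are processed independently
#' (pure per-tile work), so results do not depend on tile count or order.
#'
#' @param site a `site_window`.
#' @param scenes list of `scene` over the site grid.
#' @param config configuration list from [default_config()].
#' @param out_dir output directory for product files (`NULL` keeps cubes
#'   in memory only).
#' @return list with `cubes` (per target year), `paths`, `log`.
#' @export
run_pipeline <- function(site, scenes, config = default_config(),
                         out_dir = NULL) {
  log <- character(0)
  ov <- attr(config, "overridden")
  if (length(ov))
    log <- c(log, paste("config overrides:", paste(ov, collapse = ", ")))
  n0 <- length(scenes)
  scenes <- filter_scene_catalog(scenes, config$max_cloud,
                                 config$require_standard,
                                 config$require_ground_control)
  log <- c(log, sprintf("scene filter: retained %d of %d scenes",
                        length(scenes), n0))
  scenes <- lapply(scenes, apply_pixel_masks)
  composites <- build_composites(scenes, site)
  log <- c(log, attr(composites, "log"))
  tiles <- crop_and_tile(composites, site, config$n_tiles)
  years <- config$target_years
  layer_names <- product_layer_names()
  per_year <- lapply(years, function(y)
    lapply(layer_names, function(nm) matrix(NA_real_, site$nrow, site$ncol)))
  names(per_year) <- as.character(years)
  for (y in seq_along(years)) names(per_year[[y]]) <- layer_names
  n_insufficient <- 0L
  for (tile in tiles) {
    for (i in seq_along(tile$rows)) {
      for (j in seq_along(tile$cols)) {
        series <- tile_pixel_series(tile, i, j)
        daily <- if (is.null(series)) NULL else
          condition_series(series, config$record_start, config$record_end,
                           config)
        if (is.null(daily)) n_insufficient <- n_insufficient + 1L
        clear_dates <- tile$dates[tile$clear[, i, j]]
        for (y in years) {
          rec <- pixel_phenometrics(daily, y, config, clear_dates)
          for (nm in layer_names)
            per_year[[as.character(y)]][[nm]][tile$rows[i], tile$cols[j]] <-
              rec[[nm]]
        }
      }
    }
  }
  if (n_insufficient > 0L)
    log <- c(log, sprintf("%d pixel(s) had insufficient data", n_insufficient))
  prov <- config_hash(config)
  cubes <- lapply(years, function(y)
    encode_layers(per_year[[as.character(y)]], site, y))
  names(cubes) <- as.character(years)
  for (cb in cubes) log <- c(log, cb$log)
  paths <- character(0)
  if (!is.null(out_dir)) {
    paths <- vapply(cubes, function(cb)
      write_product(cb, out_dir, crs = site$crs, provenance = prov), "")
  }
  list(cubes = cubes, paths = paths, log = log)
}

#' Deterministic toy fixtures for tests and documentation
#'
#' @param name one of `"single_season"`, `"double_season"`,
#'   `"alfalfa_like"`, `"desert_like"`, `"snow_winter"`.
#' @param years integer years the truth spans.
#' @param seed integer seed for any randomized component.
#' @return list with `truth` (a `truth_pheno`), `site` (a coarse
#'   `site_window`), and `dates` (candidate acquisition dates).
#' @export
make_fixture <- function(name, years = 2017:2018, seed = 1L) {
  choices <- c("single_season", "double_season", "alfalfa_like",
               "desert_like", "snow_winter")
  if (!name %in% choices)
    stop("unknown fixture '", name, "'; options: ",
         paste(choices, collapse = ", "))
  all_years <- c(min(years) - 1L, years, max(years) + 1L)
  truth <- switch(name,
    single_season = truth_single_season(all_years),
    double_season = {
      starts <- unlist(lapply(all_years, function(y)
        day_num(jan1(y)) + c(80, 230)))
      make_truth("double_logistic", baseline = 0.15,
                 cycles = data.frame(sos = starts, eos = starts + 60,
                                     amplitude = rep(c(0.5, 0.35),
                                                     length(all_years)),
                                     up_rate = 6, down_rate = 8))
    },
    alfalfa_like = truth_multi_cycle(all_years, n_cycles = 6),
    desert_like = make_truth("flat", baseline = 0.18),
    snow_winter = truth_single_season(all_years, baseline = 0.12,
                                      amplitude = 0.45))
  site <- make_site(paste0("US-", toupper(substr(name, 1, 3))),
                    center = c(-100, 40), pixel_size = 1000,
                    box_side = 10000, site_name = gsub("_", " ", name))
  dates <- seq(as.Date(sprintf("%d-07-01", min(years) - 1L)),
               as.Date(sprintf("%d-01-31", max(years) + 1L)), by = 1)
  list(truth = truth, site = site, dates = dates, seed = seed,
       snow_prob = if (name == "snow_winter") 0.15 else 0.03)
}
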
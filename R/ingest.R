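# Ingest: catalogue filtering, per-pixel masking, same-day mosaicking,
# cropping/tiling, and per-tile observation stacks.

#' Filter a scene catalogue on provider quality metadata
#'
#' Retains scenes whose quality category is `"standard"` (when required),
#' whose cloud cover is at or below `max_cloud` (boundary inclusive), and
#' whose geolocation is tied to ground control (when required). Order is
#' preserved; an empty result is legal.
#'
#' @param scenes list of `scene`.
#' @param max_cloud maximum cloud-cover fraction retained (default 0.5).
#' @param require_standard drop scenes whose quality category is not
#'   `"standard"`.
#' @param require_ground_control drop scenes without ground control.
#' @return filtered list of `scene`.
#' @export
filter_scene_catalog <- function(scenes, max_cloud = 0.5,
                                 require_standard = TRUE,
                                 require_ground_control = TRUE) {
  keep <- vapply(scenes, function(s) {
    (!require_standard || identical(s$quality_category, "standard")) &&
      s$cloud_cover <= max_cloud &&
      (!require_ground_control || isTRUE(s$ground_control))
  }, TRUE)
  scenes[keep]
}

#' Apply per-pixel quality masks to a scene
#'
#' A pixel is retained iff its unusable mask is 0 (not cloud, not a
#' non-image area) and its usable mask is nonzero (not snow, shadow, haze
#' or cloud contaminated). All four bands at excluded pixels are set to NA.
#'
#' @param sc a `scene`.
#' @return the scene with excluded pixels missing-coded in every band.
#' @export
apply_pixel_masks <- function(sc) {
  d <- dim(sc$bands)[1:2]
  if (!identical(dim(sc$unusable_mask), d) || !identical(dim(sc$usable_mask), d))
    stop("mask/band shape mismatch")
  retained <- (sc$unusable_mask == 0L) & (sc$usable_mask != 0L)
  for (b in 1:4) {
    sl <- sc$bands[, , b]
    sl[!retained] <- NA_real_
    sc$bands[, , b] <- sl
  }
  sc$masked <- TRUE
  sc
}

#' Mosaic all scenes acquired on one date into a daily composite
#'
#' Per pixel and band, the composite value is the arithmetic mean of the
#' clear (unmasked) contributing values, so the result does not depend on
#' scene ordering. A pixel is clear when at least one scene contributes a
#' clear observation there.
#'
#' @param scenes_on_date list of masked `scene` objects sharing one date.
#' @param site a `site_window` (defines the composite grid).
#' @return object of class `daily_composite`: `date`, `bands` (rows x cols
#'   x 4), `clear` (logical matrix), `n_contributing` (integer matrix).
#' @export
mosaic_same_day <- function(scenes_on_date, site) {
  if (length(scenes_on_date) == 0L) stop("no scenes supplied for mosaicking")
  dts <- unique(vapply(scenes_on_date, function(s) format(s$date), ""))
  if (length(dts) != 1L)
    stop("scenes span multiple dates: ", paste(dts, collapse = ", "))
  nr <- site$nrow; nc <- site$ncol
  sums <- array(0, c(nr, nc, 4))
  n <- matrix(0L, nr, nc)
  for (s in scenes_on_date) {
    if (!identical(dim(s$bands)[1:2], c(nr, nc)))
      stop("scene grid does not match the site window")
    clear <- !is.na(s$bands[, , 4])
    n <- n + clear
    for (b in 1:4) {
      sl <- s$bands[, , b]
      sl[!clear] <- 0
      sums[, , b] <- sums[, , b] + sl
    }
  }
  bands <- array(NA_real_, c(nr, nc, 4))
  any_clear <- n > 0L
  for (b in 1:4) {
    sl <- sums[, , b] / ifelse(any_clear, n, NA_real_)
    bands[, , b] <- sl
  }
  structure(list(date = scenes_on_date[[1]]$date, bands = bands,
                 clear = any_clear, n_contributing = n),
            class = "daily_composite")
}

#' Build chronological daily composites from a masked scene catalogue
#'
#' Groups scenes by acquisition date, mosaics each group, and returns the
#' composites in chronological order. Scenes whose footprint misses the
#' window entirely are skipped with a log entry rather than an error.
#'
#' @param scenes list of `scene` (masks already applied).
#' @param site a `site_window`.
#' @return list of `daily_composite` with attribute `"log"` (character).
#' @export
build_composites <- function(scenes, site) {
  log <- character(0)
  on_grid <- vapply(scenes, function(s) {
    fp <- s$footprint
    fp$row1 >= 1L && fp$row0 <= site$nrow && fp$col1 >= 1L && fp$col0 <= site$ncol
  }, TRUE)
  if (any(!on_grid))
    log <- c(log, sprintf("skipped %d scene(s) with footprints outside the window",
                          sum(!on_grid)))
  scenes <- scenes[on_grid]
  dts <- as.Date(vapply(scenes, function(s) format(s$date), ""))
  ord <- order(dts)
  scenes <- scenes[ord]; dts <- dts[ord]
  out <- lapply(split(seq_along(scenes), dts), function(idx)
    mosaic_same_day(scenes[idx], site))
  out <- out[order(as.Date(names(out)))]
  log <- c(log, sprintf("composited %d scene(s) into %d daily composite(s)",
                        length(scenes), length(out)))
  structure(unname(out), log = log)
}

# pick a tile grid (rows x cols of tiles): among factor pairs of n_tiles
# that divide the pixel grid evenly, take the pair with aspect closest to
# the window's, preferring fewer tile rows on ties
.tile_grid <- function(nrow_px, ncol_px, n_tiles) {
  divs <- which(n_tiles %% seq_len(n_tiles) == 0L)
  feas <- divs[nrow_px %% divs == 0L & ncol_px %% (n_tiles / divs) == 0L]
  if (length(feas) == 0L)
    stop("configuration error: cannot split a ", nrow_px, " x ", ncol_px,
         " grid into ", n_tiles, " equal rectangular tiles")
  target <- sqrt(n_tiles * nrow_px / ncol_px)
  tr <- feas[order(abs(feas - target), feas)][1]
  c(rows = tr, cols = n_tiles / tr)
}

#' Crop composites to the site window and split them into tile stacks
#'
#' The window is partitioned into `n_tiles` equal rectangles (default 200,
#' i.e. 0.5 km2 each for a 10 x 10 km window) to bound per-job memory and
#' make tile-level processing embarrassingly parallel. Each tile stack
#' carries the chronological composites restricted to its pixel block.
#'
#' @param composites list of `daily_composite` over the full window.
#' @param site a `site_window`.
#' @param n_tiles number of tiles (must factor against the pixel grid).
#' @return list of `tile_stack`: `tile_id`, `rows`, `cols` (pixel index
#'   ranges), `dates`, `evi2` (array time x rows x cols), `clear`,
#'   `n_contributing`.
#' @export
crop_and_tile <- function(composites, site, n_tiles = 200L) {
  tg <- .tile_grid(site$nrow, site$ncol, n_tiles)
  th <- site$nrow / tg["rows"]; tw <- site$ncol / tg["cols"]
  dates <- as.Date(vapply(composites, function(cp) format(cp$date), ""))
  stopifnot(!is.unsorted(dates, strictly = TRUE))
  tiles <- vector("list", n_tiles)
  id <- 0L
  for (ti in seq_len(tg["rows"])) {
    for (tj in seq_len(tg["cols"])) {
      id <- id + 1L
      rows <- as.integer(((ti - 1) * th + 1):(ti * th))
      cols <- as.integer(((tj - 1) * tw + 1):(tj * tw))
      nt <- length(composites)
      evi2 <- array(NA_real_, c(nt, length(rows), length(cols)))
      clear <- array(FALSE, c(nt, length(rows), length(cols)))
      ncontrib <- array(0L, c(nt, length(rows), length(cols)))
      for (k in seq_len(nt)) {
        cp <- composites[[k]]
        evi2[k, , ] <- compute_evi2(cp$bands[rows, cols, 4],
                                    cp$bands[rows, cols, 3])
        clear[k, , ] <- cp$clear[rows, cols]
        ncontrib[k, , ] <- cp$n_contributing[rows, cols]
      }
      tiles[[id]] <- structure(
        list(tile_id = id, rows = rows, cols = cols, dates = dates,
             evi2 = evi2, clear = clear, n_contributing = ncontrib),
        class = "tile_stack")
    }
  }
  tiles
}

#' Extract the observation series of one pixel from a tile stack
#'
#' Only dates on which the composite pixel was clear become observations.
#'
#' @param tile a `tile_stack`.
#' @param i,j pixel indices within the tile.
#' @return a `pixel_series` (status all `"clear"`), or NULL when the pixel
#'   was never observed clear.
#' @export
tile_pixel_series <- function(tile, i, j) {
  ok <- tile$clear[, i, j] & is.finite(tile$evi2[, i, j])
  if (!any(ok)) return(NULL)
  pixel_series(tile$dates[ok], tile$evi2[ok, i, j])
}

#' Write a tile stack as netCDF (dimensions time, y, x)
#'
#' @param tile a `tile_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tile_stack <- function(tile, path) {
  nt <- length(tile$dates)
  nc3_write(path,
    dims = c(time = nt, y = length(tile$rows), x = length(tile$cols)),
    vars = list(
      list(name = "time", dims = "time", type = NC_INT,
           data = day_num(tile$dates),
           atts = list(units = "days since 1970-01-01")),
      list(name = "evi2", dims = c("time", "y", "x"), type = NC_DOUBLE,
           data = tile$evi2, atts = list(long_name = "two-band EVI")),
      list(name = "clear", dims = c("time", "y", "x"), type = NC_BYTE,
           data = array(as.integer(tile$clear), dim(tile$clear)),
           atts = list(long_name = "clear observation flag")),
      list(name = "n_contributing", dims = c("time", "y", "x"), type = NC_INT,
           data = tile$n_contributing,
           atts = list(long_name = "scenes contributing to composite"))),
    global_atts = list(tile_id = tile$tile_id,
                       row0 = tile$rows[1], col0 = tile$cols[1]))
  invisible(path)
}

#' Read a tile stack written by [write_tile_stack()]
#'
#' @param path netCDF path.
#' @return a `tile_stack`.
#' @export
read_tile_stack <- function(path) {
  nc <- nc3_read(path)
  dates <- num_day(nc$vars$time$data)
  ny <- nc$dims[["y"]]; nx <- nc$dims[["x"]]
  row0 <- nc$global_atts$row0; col0 <- nc$global_atts$col0
  structure(list(tile_id = nc$global_atts$tile_id,
                 rows = seq.int(row0, length.out = ny),
                 cols = seq.int(col0, length.out = nx),
                 dates = dates,
                 evi2 = nc$vars$evi2$data,
                 clear = array(nc$vars$clear$data == 1L,
                               dim(nc$vars$clear$data)),
                 n_contributing = nc$vars$n_contributing$data),
            class = "tile_stack")
}
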
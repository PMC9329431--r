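# Raster-to-raster and raster-to-point phenometric comparison: window
# averaging, paired r / RMSE / bias statistics, and reproducible point
# sampling.

# window row/col offsets for an n-pixel window; odd windows are centred,
# even windows take floor((n-1)/2) pixels before and the rest after
.window_offsets <- function(n) seq_len(n) - 1L - floor((n - 1L) / 2L)

#' Average a raster over square windows at given centres
#'
#' Missing (`NA`) cells are excluded from each mean; a window with no
#' finite cells yields `NA`.
#'
#' @param raster numeric matrix.
#' @param centers integer matrix (n x 2) of row/col centre pixels.
#' @param window_pixels window edge length in pixels (e.g. 3 or 30).
#' @return numeric vector of window means.
#' @export
window_average <- function(raster, centers, window_pixels = 3L) {
  off <- .window_offsets(window_pixels)
  apply(centers, 1L, function(rc) {
    rows <- rc[1] + off; cols <- rc[2] + off
    if (min(rows) < 1L || max(rows) > nrow(raster) ||
        min(cols) < 1L || max(cols) > ncol(raster))
      stop("window does not fit inside the raster at centre (",
           rc[1], ", ", rc[2], ")")
    vals <- raster[rows, cols]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  })
}

#' Paired comparison statistics for one metric
#'
#' Drops incomplete pairs, then reports the Pearson correlation, the
#' root-mean-square error, and the bias `mean(a - b)` (first minus
#' second). With fewer than 3 complete pairs, or a zero-variance vector,
#' the undefined statistics are `NA`.
#'
#' @param a,b paired numeric vectors (e.g. this product vs a reference).
#' @return object of class `comparison_report`: `n`, `r`, `rmse`, `bias`.
#' @export
compare_metrics <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L)
    return(structure(list(n = n, r = NA_real_, rmse = NA_real_,
                          bias = NA_real_), class = "comparison_report"))
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)
  structure(list(n = n, r = r, rmse = sqrt(mean((a - b)^2)),
                 bias = mean(a - b)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("n = %d, r = %.3f, RMSE = %.2f, bias = %.2f\n",
              x$n, x$r, x$rmse, x$bias))
  invisible(x)
}

#' Reproducibly sample comparison points on a pixel grid
#'
#' Uniform sampling without replacement over eligible pixels: masked
#' pixels and a margin of half the comparison window at every edge are
#' excluded so windows always fit.
#'
#' @param nrow_px,ncol_px grid size.
#' @param n number of points.
#' @param window_pixels comparison window edge length (margin source).
#' @param seed integer random seed.
#' @param exclusion_mask optional logical matrix; `TRUE` pixels are
#'   excluded.
#' @return integer matrix (n x 2) of row/col centres.
#' @export
sample_comparison_points <- function(nrow_px, ncol_px, n, window_pixels = 3L,
                                     seed = 1L, exclusion_mask = NULL) {
  off <- .window_offsets(window_pixels)
  r_ok <- seq.int(1L - min(off), nrow_px - max(off))
  c_ok <- seq.int(1L - min(off), ncol_px - max(off))
  eligible <- as.matrix(expand.grid(row = r_ok, col = c_ok))
  if (!is.null(exclusion_mask)) {
    keep <- !exclusion_mask[cbind(eligible[, 1], eligible[, 2])]
    eligible <- eligible[keep, , drop = FALSE]
  }
  if (n > nrow(eligible))
    stop("requested ", n, " points but only ", nrow(eligible), " eligible")
  set.seed(seed)
  idx <- sample.int(nrow(eligible), n)
  eligible[idx, , drop = FALSE]
}

#' Compare two product cubes layer by layer
#'
#' Window-averages each requested layer of both cubes at shared sampled
#' centres (scaled to each cube's grid if the grids differ by an integer
#' factor) and reports r / RMSE / bias per layer.
#'
#' @param cube_a,cube_b `product_cube`s on the same grid.
#' @param layers layer names to compare (default: the six DOY metrics of
#'   the first cycle other than Peak, plus Peak).
#' @param n_points sampled comparison points.
#' @param window_pixels window edge length.
#' @param seed integer seed for point sampling.
#' @return data.frame: layer, n, r, rmse, bias.
#' @export
compare_products <- function(cube_a, cube_b,
                             layers = c("OGI", "50PCGI", "OGMx", "Peak",
                                        "OGD", "50PCGD", "OGMn"),
                             n_points = 500L, window_pixels = 3L, seed = 1L) {
  d <- dim(cube_a$layers[[1]])
  stopifnot(identical(d, dim(cube_b$layers[[1]])))
  n_eligible <- (d[1] - window_pixels + 1L) * (d[2] - window_pixels + 1L)
  pts <- sample_comparison_points(d[1], d[2], min(n_points, n_eligible),
                                  window_pixels, seed)
  rows <- lapply(layers, function(nm) {
    va <- window_average(decode_layer(cube_a, nm), pts, window_pixels)
    vb <- window_average(decode_layer(cube_b, nm), pts, window_pixels)
    rep <- compare_metrics(va, vb)
    data.frame(layer = nm, n = rep$n, r = rep$r, rmse = rep$rmse,
               bias = rep$bias, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare a product cube against a point table
#'
#' Implements tower-camera-style comparison: for each point, the product
#' layer is averaged over a small window offset a fixed distance in a
#' fixed bearing from the point (cameras typically look north, so the
#' default window sits 30 m north).
#'
#' @param cube a `product_cube`.
#' @param points data.frame with columns `row`, `col` (pixel position of
#'   the instrument) and one column per compared layer holding the
#'   reference DOY value.
#' @param site a `site_window` (for the pixel size).
#' @param layers layer names to compare.
#' @param window_pixels window edge length (default 5).
#' @param offset_m offset distance in metres (default 30).
#' @param bearing one of `"north"`, `"south"`, `"east"`, `"west"`.
#' @return data.frame: layer, n, r, rmse, bias.
#' @export
compare_to_points <- function(cube, points, site,
                              layers = c("50PCGI", "50PCGD"),
                              window_pixels = 5L, offset_m = 30,
                              bearing = "north") {
  px <- max(1L, as.integer(round(offset_m / site$pixel_size)))
  shift <- switch(bearing, north = c(-px, 0L), south = c(px, 0L),
                  east = c(0L, px), west = c(0L, -px),
                  stop("unknown bearing: ", bearing))
  centers <- cbind(points$row + shift[1], points$col + shift[2])
  rows <- lapply(layers, function(nm) {
    va <- window_average(decode_layer(cube, nm), centers, window_pixels)
    rep <- compare_metrics(va, points[[nm]])
    data.frame(layer = nm, n = rep$n, r = rep$r, rmse = rep$rmse,
               bias = rep$bias, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
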
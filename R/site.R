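#' Define a square analysis window centred on a tower
#'
#' A site window is a square box (default 10 km on a side) centred on a flux
#' tower, gridded at a fixed pixel size. The pixel grid must tile the box
#' exactly, so the box side must be a positive multiple of the pixel size;
#' at the native 3 m pixel the default side is 9999 m, the largest multiple
#' of 3 not exceeding the nominal 10 km.
#'
#' @param site_code short site identifier, e.g. `"US-Xy1"`.
#' @param center numeric `c(lon, lat)` in degrees.
#' @param pixel_size pixel edge length in metres (default 3).
#' @param box_side box edge length in metres; must be a multiple of
#'   `pixel_size`. Default: 9999 when `pixel_size` is 3, otherwise 10000.
#' @param site_name long site name (used in product directory names).
#' @param crs coordinate reference system identifier stored as metadata.
#' @return an object of class `site_window` with fields `site_code`,
#'   `site_name`, `center`, `pixel_size`, `box_side`, `nrow`, `ncol`, `crs`.
#' @examples
#' s <- make_site("US-Toy", c(-100, 40), pixel_size = 50)
#' s$nrow # 200
#' @export
make_site <- function(site_code, center = c(0, 0), pixel_size = 3,
                      box_side = if (pixel_size == 3) 9999 else 10000,
                      site_name = site_code, crs = "local-metric") {
  stopifnot(pixel_size > 0, box_side > 0)
  n <- box_side / pixel_size
  if (abs(n - round(n)) > 1e-9)
    stop("configuration error: box_side (", box_side,
         " m) is not a multiple of pixel_size (", pixel_size, " m)")
  n <- as.integer(round(n))
  structure(list(site_code = site_code, site_name = site_name,
                 center = as.numeric(center), pixel_size = pixel_size,
                 box_side = box_side, nrow = n, ncol = n, crs = crs),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s (%s): %g x %g m box, %d x %d pixels @ %g m\n",
              x$site_code, x$site_name, x$box_side, x$box_side,
              x$nrow, x$ncol, x$pixel_size))
  invisible(x)
}

# corner coordinates of the box polygon (lon/lat degrees, small-angle
# metric approximation around the centre; adequate for a 10 km window)
site_box_coords <- function(site) {
  lat <- site$center[2]
  half <- site$box_side / 2
  dlat <- half / 111320
  dlon <- half / (111320 * max(cos(lat * pi / 180), 1e-6))
  lon <- site$center[1]
  rbind(c(lon - dlon, lat - dlat), c(lon + dlon, lat - dlat),
        c(lon + dlon, lat + dlat), c(lon - dlon, lat + dlat),
        c(lon - dlon, lat - dlat))
}

#' Write a site window as a single-feature GeoJSON polygon
#'
#' @param site a `site_window`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_geojson <- function(site, path) {
  coords <- site_box_coords(site)
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(site_code = site$site_code,
                        site_name = site$site_name,
                        pixel_size = site$pixel_size,
                        box_side = site$box_side,
                        crs = site$crs),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(coords)),
                                                function(i) coords[i, ])))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a site window from a single-feature GeoJSON polygon
#'
#' @param path GeoJSON file with exactly one polygon feature carrying a
#'   `site_code` property.
#' @return a `site_window`.
#' @export
read_site_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (length(feats) != 1L)
    stop("format error: expected exactly 1 feature, found ", length(feats))
  f <- feats[[1]]
  if (!identical(f$geometry$type, "Polygon"))
    stop("format error: geometry must be a Polygon, found ",
         f$geometry$type %||% "none")
  props <- f$properties
  if (is.null(props$site_code))
    stop("format error: feature lacks a 'site_code' property")
  ring <- f$geometry$coordinates[[1]]
  lon <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
  lat <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
  center <- c(mean(range(lon)), mean(range(lat)))
  make_site(props$site_code, center,
            pixel_size = props$pixel_size %||% 3,
            box_side = props$box_side %||% 9999,
            site_name = props$site_name %||% props$site_code,
            crs = props$crs %||% "local-metric")
}
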
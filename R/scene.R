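# Scene objects: one dated 4-band reflectance raster over the site grid.
#
# Bands are stored as a rows x cols x 4 array (blue, green, red, nir) on the
# full site grid; pixels outside the scene footprint are NA and flagged as
# non-image in the unusable mask. Masks follow the provider convention:
# unusable_mask == 0 means usable (not cloud / non-image), usable_mask != 0
# means not contaminated by snow, shadow, haze or cloud.

BAND_NAMES <- c("blue", "green", "red", "nir")

#' Construct a scene
#'
#' @param date acquisition `Date`.
#' @param bands rows x cols x 4 numeric array (blue, green, red, nir).
#' @param unusable_mask integer matrix; 0 = usable, nonzero = cloud or
#'   non-image.
#' @param usable_mask integer matrix; 0 = contaminated (snow/shadow/haze),
#'   nonzero = clear.
#' @param footprint list with `row0`, `row1`, `col0`, `col1` pixel bounds
#'   (inclusive) of the imaged area within the site grid.
#' @param quality_category provider quality string (`"standard"` expected).
#' @param cloud_cover fraction in `[0, 1]`.
#' @param ground_control logical; TRUE when geolocation was tied to ground
#'   control points.
#' @return object of class `scene`.
#' @export
scene <- function(date, bands, unusable_mask, usable_mask,
                  footprint = NULL, quality_category = "standard",
                  cloud_cover = 0, ground_control = TRUE) {
  stopifnot(length(dim(bands)) == 3L, dim(bands)[3] == 4L)
  d <- dim(bands)[1:2]
  if (!identical(dim(unusable_mask), d) || !identical(dim(usable_mask), d))
    stop("mask/band shape mismatch: bands ", paste(d, collapse = "x"))
  footprint <- footprint %||% list(row0 = 1L, row1 = d[1], col0 = 1L, col1 = d[2])
  structure(list(date = as.Date(date), bands = bands,
                 unusable_mask = unusable_mask, usable_mask = usable_mask,
                 footprint = footprint, quality_category = quality_category,
                 cloud_cover = cloud_cover, ground_control = ground_control),
            class = "scene")
}

#' Solve for the NIR reflectance that yields a target EVI2 at a given red
#'
#' Inverts EVI2 = 2.5 (NIR - Red) / (NIR + 2.4 Red + 1) for NIR, which lets
#' the scene simulator back-fill band values so that the index computed
#' downstream reproduces the truth trajectory exactly.
#'
#' @param evi2 target index value(s).
#' @param red red reflectance(s).
#' @return nir reflectance(s).
#' @export
evi2_to_nir <- function(evi2, red) {
  (red * (2.5 + 2.4 * evi2) + evi2) / (2.5 - evi2)
}

#' Simulate a stack of dated scenes over a site window
#'
#' For every retained acquisition date one scene is emitted; with
#' probability `overlap_prob` a date gets two scenes with overlapping
#' partial footprints (left and right swaths), emulating same-day multiple
#' acquisitions. Per scene, a random fraction of in-footprint pixels drawn
#' from `cloud_fraction_range` is marked contaminated in the usable mask.
#' Red reflectance is drawn near a soil value and NIR is back-solved so the
#' index computed downstream equals the truth trajectory plus noise.
#'
#' @param site a `site_window`.
#' @param truth_map a single `truth_pheno` (applied to all pixels) or a list
#'   of length `nrow * ncol` (row-major).
#' @param dates candidate acquisition Dates.
#' @param overlap_prob probability a date carries two overlapping scenes.
#' @param cloud_fraction_range range of per-scene contaminated-pixel
#'   fractions.
#' @param noise_sd radiometric noise on the target index.
#' @param gap_prob probability a date is skipped entirely.
#' @param seed integer random seed.
#' @return list of `scene` objects, chronological.
#' @export
simulate_scene_stack <- function(site, truth_map, dates, overlap_prob = 0.3,
                                 cloud_fraction_range = c(0, 0.25),
                                 noise_sd = 0.02, gap_prob = 0.1, seed = 1L) {
  dates <- as.Date(dates)
  nr <- site$nrow; nc <- site$ncol
  npix <- nr * nc
  if (inherits(truth_map, "truth_pheno")) truth_map <- list(truth_map)
  if (length(truth_map) == 1L) truth_map <- rep(truth_map, npix)
  stopifnot(length(truth_map) == npix)
  set.seed(seed)
  keep <- stats::runif(length(dates)) >= gap_prob
  dates <- dates[keep]
  scenes <- list()
  for (d in seq_along(dates)) {
    date <- dates[d]
    truth_vals <- vapply(truth_map, function(tr) truth_evi2(tr, date), 0)
    two <- stats::runif(1) < overlap_prob
    if (two) {
      # left and right swaths overlapping over the middle fifth
      cut_lo <- floor(nc * 0.4); cut_hi <- ceiling(nc * 0.6)
      fps <- list(list(row0 = 1L, row1 = nr, col0 = 1L, col1 = as.integer(cut_hi)),
                  list(row0 = 1L, row1 = nr, col0 = as.integer(max(cut_lo, 1L)),
                       col1 = nc))
    } else {
      fps <- list(list(row0 = 1L, row1 = nr, col0 = 1L, col1 = nc))
    }
    for (fp in fps) {
      target <- matrix(truth_vals, nr, nc, byrow = TRUE) +
        matrix(stats::rnorm(npix, sd = noise_sd), nr, nc)
      red <- matrix(0.06 + stats::runif(npix, 0, 0.04), nr, nc)
      nir <- evi2_to_nir(target, red)
      bands <- array(NA_real_, c(nr, nc, 4))
      bands[, , 3] <- red
      bands[, , 4] <- nir
      bands[, , 1] <- red * 0.8
      bands[, , 2] <- red * 1.1
      inside <- matrix(FALSE, nr, nc)
      inside[fp$row0:fp$row1, fp$col0:fp$col1] <- TRUE
      for (b in 1:4) { sl <- bands[, , b]; sl[!inside] <- NA_real_; bands[, , b] <- sl }
      unusable <- matrix(0L, nr, nc); unusable[!inside] <- 2L  # non-image
      cf <- stats::runif(1, cloud_fraction_range[1], cloud_fraction_range[2])
      usable <- matrix(1L, nr, nc)
      contaminated <- inside & (matrix(stats::runif(npix), nr, nc) < cf)
      usable[contaminated] <- 0L
      scenes[[length(scenes) + 1L]] <-
        scene(date, bands, unusable, usable, footprint = fp,
              quality_category = "standard", cloud_cover = cf,
              ground_control = TRUE)
    }
  }
  scenes
}

#' Write a scene to disk (multi-band TIFF plus JSON sidecar)
#'
#' Bands go to a 4-channel float TIFF; masks to a 2-channel TIFF; the
#' acquisition date, footprint, quality metadata and georeferencing go to a
#' JSON sidecar next to them. Requires the `tiff` package.
#'
#' @param sc a `scene`.
#' @param stem output path stem; writes `<stem>.tif`, `<stem>_mask.tif`,
#'   `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_scene <- function(sc, stem) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("scene file I/O needs the 'tiff' package")
  b <- sc$bands
  b[is.na(b)] <- -1
  # tiff wants [0,1]; reflectance sits there already, NA coded as -1 -> 0
  tiff::writeTIFF(pmax(pmin(b, 1), 0), paste0(stem, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  m <- array(0, c(dim(b)[1:2], 2))
  m[, , 1] <- sc$unusable_mask / 255
  m[, , 2] <- sc$usable_mask / 255
  tiff::writeTIFF(m, paste0(stem, "_mask.tif"), bits.per.sample = 32L)
  meta <- list(date = format(sc$date), footprint = sc$footprint,
               quality_category = sc$quality_category,
               cloud_cover = sc$cloud_cover,
               ground_control = sc$ground_control,
               bands = BAND_NAMES, na_coded_as = -1)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a scene written by [write_scene()]
#'
#' @param stem path stem used at write time.
#' @return a `scene`.
#' @export
read_scene <- function(stem) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("scene file I/O needs the 'tiff' package")
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  b <- tiff::readTIFF(paste0(stem, ".tif"))
  m <- tiff::readTIFF(paste0(stem, "_mask.tif"))
  unusable <- round(m[, , 1] * 255)
  usable <- round(m[, , 2] * 255)
  fp <- lapply(meta$footprint, as.integer)
  out <- scene(as.Date(meta$date), b, matrix(as.integer(unusable), nrow(unusable)),
               matrix(as.integer(usable), nrow(usable)), footprint = fp,
               quality_category = meta$quality_category,
               cloud_cover = as.numeric(meta$cloud_cover),
               ground_control = isTRUE(meta$ground_control))
  # restore NA outside the footprint
  inside <- matrix(FALSE, nrow(usable), ncol(usable))
  inside[fp$row0:fp$row1, fp$col0:fp$col1] <- TRUE
  for (k in 1:4) { sl <- out$bands[, , k]; sl[!inside] <- NA_real_; out$bands[, , k] <- sl }
  out
}
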
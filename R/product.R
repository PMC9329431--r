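# Product encoding: the 24-layer per-site-per-year integer raster product.
#
# Physical values are divided by the layer scale factor, rounded half away
# from zero to 16-bit integers, checked against the layer valid range
# (out-of-range values become fill and are logged), and written as one
# classic-model netCDF file per site and year.

.layer_spec_table <- function() {
  timing <- function(name, desc) {
    data.frame(name = name, description = desc,
               units = "Day of year (January 1 of target year = 1)",
               scale_factor = 1, valid_min = -181, valid_max = 548,
               fill = 32767, stringsAsFactors = FALSE)
  }
  peak <- function(name) {
    data.frame(name = name, description = "Date of Cycle Peak",
               units = "Day of year (January 1 of target year = 1)",
               scale_factor = 1, valid_min = 1, valid_max = 366,
               fill = 32767, stringsAsFactors = FALSE)
  }
  vi <- function(name, desc, scale, vmax) {
    data.frame(name = name, description = desc, units = "-",
               scale_factor = scale, valid_min = 0, valid_max = vmax,
               fill = 32767, stringsAsFactors = FALSE)
  }
  qa <- function(name, which) {
    data.frame(name = name,
               description = paste("Quality Assurance for", which,
                                   "vegetation cycle"),
               units = "-", scale_factor = 1, valid_min = 1, valid_max = 4,
               fill = NA_real_, stringsAsFactors = FALSE)
  }
  cyc <- function(suffix, label) {
    rbind(
      timing(paste0("OGI", suffix),
             paste0("Onset Greenness Increase (Date of 15% greenness increase)")),
      timing(paste0("50PCGI", suffix),
             "50 Percent Greenness Increase (Date of 50% greenness increase)"),
      timing(paste0("OGMx", suffix),
             "Onset Greenness Maximum (Date of 90% greenness increase)"),
      peak(paste0("Peak", suffix)),
      timing(paste0("OGD", suffix),
             "Onset Greenness Decrease (Date of 10% greenness decrease)"),
      timing(paste0("50PCGD", suffix),
             "50 Percent Greenness Decrease (Date of 50% greenness decrease)"),
      timing(paste0("OGMn", suffix),
             "Onset Greenness Minimum (Date of 85% greenness decrease)"),
      vi(paste0("EVImax", suffix),
         paste("Maximum EVI2 during vegetation cycle"), 0.0001, 10000),
      vi(paste0("EVIamp", suffix),
         paste("EVI2 Amplitude during vegetation cycle"), 0.0001, 10000),
      vi(paste0("EVIarea", suffix),
         paste("Integrated EVI2 during vegetation cycle"), 0.01, 32766))
  }
  rbind(
    data.frame(name = "NumCycles",
               description = "Number of phenological cycles detected in target year",
               units = "Number of cycles", scale_factor = 1,
               valid_min = 0, valid_max = 6, fill = 32767,
               stringsAsFactors = FALSE),
    cyc("", "first"),
    cyc("_2", "second"),
    qa("QA", "first"), qa("QA_2", "second"),
    data.frame(name = "numObs",
               description = "Number of days with clear observations in calendar year",
               units = "Days", scale_factor = 1, valid_min = 0,
               valid_max = 366, fill = 32767, stringsAsFactors = FALSE))
}

#' Product layer specifications
#'
#' The 24 layers of the per-site-per-year product: name, description,
#' units, scale factor, valid range (on the stored integer scale), and
#' fill value (32767 where defined; the QA layers are total and carry no
#' fill). A machine-readable copy ships in
#' `inst/extdata/product_layers.json`.
#'
#' @return data.frame with 24 rows.
#' @export
product_layer_specs <- function() .layer_spec_table()

#' Names of the 24 product layers, in product order
#' @return character vector of length 24.
#' @export
product_layer_names <- function() .layer_spec_table()$name

#' Encode physical phenometric layers into the integer product
#'
#' @param pheno named list of numeric matrices (physical units), one per
#'   product layer; missing values are `NA`.
#' @param site a `site_window` (or any list with `site_code`,
#'   `site_name`).
#' @param year integer target year.
#' @param specs layer specification table.
#' @return object of class `product_cube`: `site_code`, `site_name`,
#'   `year`, `layers` (named list of integer matrices), `specs`, `log`.
#' @export
encode_layers <- function(pheno, site, year, specs = product_layer_specs()) {
  missing_layers <- setdiff(specs$name, names(pheno))
  if (length(missing_layers))
    stop("layer(s) missing from input: ", paste(missing_layers, collapse = ", "))
  layers <- list()
  log <- character(0)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    phys <- pheno[[sp$name]]
    stored <- round_half_away(phys / sp$scale_factor)
    if (sp$name == "NumCycles") {
      n_clamped <- sum(stored > sp$valid_max, na.rm = TRUE)
      if (n_clamped > 0) {
        log <- c(log, sprintf("NumCycles: clamped %d value(s) to %d",
                              n_clamped, sp$valid_max))
        stored[!is.na(stored) & stored > sp$valid_max] <- sp$valid_max
      }
    }
    bad <- !is.na(stored) & (stored < sp$valid_min | stored > sp$valid_max)
    if (any(bad))
      log <- c(log, sprintf("%s: %d value(s) outside [%d, %d] set to fill",
                            sp$name, sum(bad), sp$valid_min, sp$valid_max))
    fill <- if (is.na(sp$fill)) 4L else as.integer(sp$fill)  # QA: no cycle = 4
    stored[bad | is.na(stored)] <- fill
    layers[[sp$name]] <- matrix(as.integer(stored), nrow(phys), ncol(phys))
  }
  structure(list(site_code = site$site_code,
                 site_name = site$site_name %||% site$site_code,
                 year = as.integer(year), layers = layers, specs = specs,
                 log = log),
            class = "product_cube")
}

#' Decode a product layer back to physical units
#'
#' @param cube a `product_cube`.
#' @param layer layer name.
#' @return numeric matrix with fills mapped to `NA`.
#' @export
decode_layer <- function(cube, layer) {
  sp <- cube$specs[cube$specs$name == layer, ]
  if (nrow(sp) != 1L) stop("unknown layer: ", layer)
  m <- cube$layers[[layer]]
  out <- m * sp$scale_factor
  if (!is.na(sp$fill)) out[m == sp$fill] <- NA_real_
  out
}

#' Write a product cube as a per-site-per-year netCDF file
#'
#' The file lands at `<SiteCode__SiteFullName>/PSLP_<Year>.nc` under
#' `out_dir`, with all 24 layers as 16-bit integer variables carrying
#' scale/valid-range/fill attributes, plus georeferencing and provenance
#' global attributes.
#'
#' @param cube a `product_cube`.
#' @param out_dir output root directory.
#' @param crs CRS identifier stored as a global attribute.
#' @param provenance optional string (e.g. a config hash).
#' @return the file path, invisibly.
#' @export
write_product <- function(cube, out_dir, crs = "local-metric",
                          provenance = "") {
  site_dir <- file.path(out_dir, paste0(cube$site_code, "__", cube$site_name))
  dir.create(site_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(site_dir, sprintf("PSLP_%d.nc", cube$year))
  d <- dim(cube$layers[[1]])
  vars <- lapply(seq_len(nrow(cube$specs)), function(i) {
    sp <- cube$specs[i, ]
    atts <- list(long_name = sp$description, units = sp$units,
                 scale_factor = sp$scale_factor,
                 valid_range = nc_typed(as.integer(c(sp$valid_min, sp$valid_max)),
                                        "short"))
    if (!is.na(sp$fill))
      atts$`_FillValue` <- nc_typed(as.integer(sp$fill), "short")
    list(name = sp$name, dims = c("y", "x"), type = NC_SHORT,
         data = cube$layers[[sp$name]], atts = atts)
  })
  tryCatch(
    nc3_write(path, dims = c(y = d[1], x = d[2]), vars = vars,
              global_atts = list(site_code = cube$site_code,
                                 site_name = cube$site_name,
                                 year = cube$year, crs = crs,
                                 provenance = provenance)),
    error = function(e) stop("failed writing product at ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a product file written by [write_product()]
#'
#' @param path netCDF path.
#' @return a `product_cube`.
#' @export
read_product <- function(path) {
  nc <- nc3_read(path)
  specs <- product_layer_specs()
  have <- names(nc$vars)
  missing_layers <- setdiff(specs$name, have)
  extra <- setdiff(have, specs$name)
  if (length(missing_layers) || length(extra))
    stop("schema error in ", path,
         if (length(missing_layers)) paste0("; absent layer(s): ",
                                            paste(missing_layers, collapse = ", ")),
         if (length(extra)) paste0("; unexpected layer(s): ",
                                   paste(extra, collapse = ", ")))
  layers <- lapply(specs$name, function(nm) nc$vars[[nm]]$data)
  names(layers) <- specs$name
  structure(list(site_code = nc$global_atts$site_code,
                 site_name = nc$global_atts$site_name,
                 year = as.integer(nc$global_atts$year),
                 layers = layers, specs = specs, log = character(0)),
            class = "product_cube")
}

#' Write the product layer schema as a JSON sidecar
#'
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_layer_schema_json <- function(path) {
  jsonlite::write_json(product_layer_specs(), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.product_cube <- function(x, ...) {
  cat(sprintf("<product_cube> %s (%s), year %d: %d layers on %d x %d grid\n",
              x$site_code, x$site_name, x$year, length(x$layers),
              nrow(x$layers[[1]]), ncol(x$layers[[1]])))
  invisible(x)
}
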
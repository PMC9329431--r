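# Minimal NetCDF-3 (classic, CDF-1) serialization.
#
# The product files are classic-model netCDF with fixed-size dimensions only
# (no record dimension), which keeps the on-disk grammar small: a big-endian
# header (magic, dimension/attribute/variable tables) followed by one
# contiguous data block per variable at a 4-byte-aligned offset. This file
# implements exactly that subset; files written here open in any mainstream
# netCDF reader and vice versa for files restricted to the same subset.

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L; NC_INT <- 4L
NC_FLOAT <- 5L; NC_DOUBLE <- 6L

.nc3_type_size <- c(1L, 1L, 2L, 4L, 4L, 8L)

.nc3_type_of <- function(x) {
  if (!is.null(attr(x, "nc_type"))) return(attr(x, "nc_type"))
  if (is.character(x)) return(NC_CHAR)
  if (is.integer(x)) return(NC_INT)
  if (is.double(x)) return(NC_DOUBLE)
  stop("cannot map R type '", typeof(x), "' to a netCDF type")
}

#' Tag a value with an explicit netCDF storage type
#'
#' Used mainly to force `_FillValue` and `valid_range` attributes to be
#' stored as 16-bit integers so their type matches the variable they qualify.
#'
#' @param x numeric or character vector.
#' @param type one of `"short"`, `"int"`, `"double"`, `"float"`, `"char"`,
#'   `"byte"`.
#' @return `x` with an internal type tag consumed by [nc3_write()].
#' @export
nc_typed <- function(x, type) {
  code <- switch(type, byte = NC_BYTE, char = NC_CHAR, short = NC_SHORT,
                 int = NC_INT, float = NC_FLOAT, double = NC_DOUBLE,
                 stop("unknown netCDF type: ", type))
  attr(x, "nc_type") <- code
  x
}

.nc3_pad4 <- function(n) as.integer((4L - n %% 4L) %% 4L)

.nc3_put_int <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "big")

.nc3_put_name <- function(con, name) {
  bytes <- charToRaw(name)
  .nc3_put_int(con, length(bytes))
  writeBin(bytes, con)
  pad <- .nc3_pad4(length(bytes))
  if (pad > 0L) writeBin(raw(pad), con)
}

.nc3_put_values <- function(con, values, type) {
  n <- if (type == NC_CHAR) nchar(paste(values, collapse = ""), type = "bytes") else length(values)
  if (type == NC_CHAR) {
    bytes <- charToRaw(paste(values, collapse = ""))
    writeBin(bytes, con)
    nbytes <- length(bytes)
  } else if (type == NC_BYTE) {
    writeBin(as.integer(values), con, size = 1L)
    nbytes <- n
  } else if (type == NC_SHORT) {
    writeBin(as.integer(values), con, size = 2L, endian = "big")
    nbytes <- 2L * n
  } else if (type == NC_INT) {
    writeBin(as.integer(values), con, size = 4L, endian = "big")
    nbytes <- 4L * n
  } else if (type == NC_FLOAT) {
    writeBin(as.double(values), con, size = 4L, endian = "big")
    nbytes <- 4L * n
  } else {
    writeBin(as.double(values), con, size = 8L, endian = "big")
    nbytes <- 8L * n
  }
  pad <- .nc3_pad4(nbytes)
  if (pad > 0L) writeBin(raw(pad), con)
}

.nc3_put_att_list <- function(con, atts) {
  if (length(atts) == 0L) {
    .nc3_put_int(con, 0L); .nc3_put_int(con, 0L)
    return(invisible())
  }
  .nc3_put_int(con, 12L)            # NC_ATTRIBUTE
  .nc3_put_int(con, length(atts))
  for (nm in names(atts)) {
    val <- atts[[nm]]
    type <- .nc3_type_of(val)
    .nc3_put_name(con, nm)
    .nc3_put_int(con, type)
    nelems <- if (type == NC_CHAR) nchar(paste(val, collapse = ""), type = "bytes") else length(val)
    .nc3_put_int(con, nelems)
    .nc3_put_values(con, val, type)
  }
}

.nc3_var_vsize <- function(var, dims) {
  lens <- dims[var$dims]
  n <- if (length(lens) == 0L) 1L else prod(lens)
  sz <- n * .nc3_type_size[var$type]
  as.integer(sz + .nc3_pad4(sz))
}

.nc3_serialize_header <- function(dims, global_atts, vars, begins) {
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con)
  writeBin(as.raw(1L), con)          # CDF-1: 32-bit offsets
  .nc3_put_int(con, 0L)              # numrecs (no record dimension)
  if (length(dims) == 0L) {
    .nc3_put_int(con, 0L); .nc3_put_int(con, 0L)
  } else {
    .nc3_put_int(con, 10L)           # NC_DIMENSION
    .nc3_put_int(con, length(dims))
    for (nm in names(dims)) {
      .nc3_put_name(con, nm)
      .nc3_put_int(con, dims[[nm]])
    }
  }
  .nc3_put_att_list(con, global_atts)
  if (length(vars) == 0L) {
    .nc3_put_int(con, 0L); .nc3_put_int(con, 0L)
  } else {
    .nc3_put_int(con, 11L)           # NC_VARIABLE
    .nc3_put_int(con, length(vars))
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      .nc3_put_name(con, v$name)
      dimids <- match(v$dims, names(dims)) - 1L
      .nc3_put_int(con, length(dimids))
      for (d in dimids) .nc3_put_int(con, d)
      .nc3_put_att_list(con, v$atts)
      .nc3_put_int(con, v$type)
      .nc3_put_int(con, .nc3_var_vsize(v, dims))
      .nc3_put_int(con, begins[i])
    }
  }
  rawConnectionValue(con)
}

#' Write a classic-model netCDF file
#'
#' @param path output file path.
#' @param dims named integer vector of fixed dimension lengths, in definition
#'   order.
#' @param vars list of variable descriptors: `list(name=, dims=<character
#'   vector of dim names, slowest first>, type=<NC_* code>, data=, atts=)`.
#'   Matrix data is interpreted with rows indexing the first listed dimension.
#' @param global_atts named list of global attributes.
#' @return `path`, invisibly.
#' @keywords internal
nc3_write <- function(path, dims, vars, global_atts = list()) {
  dims <- as.integer(dims) |> stats::setNames(names(dims))
  for (v in vars) {
    if (!all(v$dims %in% names(dims)))
      stop("variable '", v$name, "' references undefined dimension")
  }
  # two-pass: header length depends only on structure, not on the begins
  probe <- .nc3_serialize_header(dims, global_atts, vars, rep(0L, length(vars)))
  begin <- length(probe)
  begins <- integer(length(vars))
  for (i in seq_along(vars)) {
    begins[i] <- begin
    begin <- begin + .nc3_var_vsize(vars[[i]], dims)
  }
  header <- .nc3_serialize_header(dims, global_atts, vars, begins)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (v in vars) {
    dat <- v$data
    # file order: last listed dimension varies fastest
    if (is.array(dat) && length(dim(dat)) >= 2L)
      dat <- as.vector(aperm(dat, rev(seq_along(dim(dat)))))
    .nc3_put_values(con, dat, v$type)
  }
  invisible(path)
}

.nc3_get_int <- function(con) readBin(con, "integer", size = 4L, endian = "big")

.nc3_get_name <- function(con) {
  n <- .nc3_get_int(con)
  bytes <- readBin(con, "raw", n)
  pad <- .nc3_pad4(n)
  if (pad > 0L) readBin(con, "raw", pad)
  rawToChar(bytes)
}

.nc3_get_values <- function(con, type, nelems) {
  if (type == NC_CHAR) {
    out <- rawToChar(readBin(con, "raw", nelems))
    nbytes <- nelems
  } else if (type == NC_BYTE) {
    out <- readBin(con, "integer", nelems, size = 1L)
    nbytes <- nelems
  } else if (type == NC_SHORT) {
    out <- readBin(con, "integer", nelems, size = 2L, signed = TRUE, endian = "big")
    nbytes <- 2L * nelems
  } else if (type == NC_INT) {
    out <- readBin(con, "integer", nelems, size = 4L, endian = "big")
    nbytes <- 4L * nelems
  } else if (type == NC_FLOAT) {
    out <- readBin(con, "double", nelems, size = 4L, endian = "big")
    nbytes <- 4L * nelems
  } else {
    out <- readBin(con, "double", nelems, size = 8L, endian = "big")
    nbytes <- 8L * nelems
  }
  pad <- .nc3_pad4(nbytes)
  if (pad > 0L) readBin(con, "raw", pad)
  out
}

.nc3_get_att_list <- function(con) {
  tag <- .nc3_get_int(con)
  n <- .nc3_get_int(con)
  if (tag == 0L || n == 0L) return(list())
  atts <- vector("list", n)
  nms <- character(n)
  for (i in seq_len(n)) {
    nms[i] <- .nc3_get_name(con)
    type <- .nc3_get_int(con)
    nelems <- .nc3_get_int(con)
    atts[[i]] <- .nc3_get_values(con, type, nelems)
  }
  stats::setNames(atts, nms)
}

#' Read a classic-model netCDF file written by [nc3_write()] or any
#' netCDF-3 producer restricted to fixed dimensions
#'
#' @param path file path.
#' @return list with `dims` (named integer vector), `global_atts`, and `vars`
#'   (named list of `list(data=, dims=, atts=, type=)`); 2-D variables come
#'   back as matrices with rows indexing their first dimension.
#' @keywords internal
nc3_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "CDF") || !magic[4] %in% as.raw(1:2))
    stop("not a classic netCDF file: ", path)
  .nc3_get_int(con)                   # numrecs, unused (no record dims here)
  tag <- .nc3_get_int(con); n <- .nc3_get_int(con)
  dims <- integer(0L)
  if (tag == 10L && n > 0L) {
    dims <- integer(n); dnames <- character(n)
    for (i in seq_len(n)) {
      dnames[i] <- .nc3_get_name(con)
      dims[i] <- .nc3_get_int(con)
    }
    names(dims) <- dnames
  }
  global_atts <- .nc3_get_att_list(con)
  tag <- .nc3_get_int(con); n <- .nc3_get_int(con)
  vars <- list()
  if (tag == 11L && n > 0L) {
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      name <- .nc3_get_name(con)
      nd <- .nc3_get_int(con)
      dimids <- if (nd > 0L) vapply(seq_len(nd), function(j) .nc3_get_int(con), 0L) else integer(0L)
      atts <- .nc3_get_att_list(con)
      type <- .nc3_get_int(con)
      .nc3_get_int(con)               # vsize (recomputable)
      begin <- .nc3_get_int(con)
      meta[[i]] <- list(name = name, dims = names(dims)[dimids + 1L],
                        atts = atts, type = type, begin = begin)
    }
    for (m in meta) {
      seek(con, m$begin)
      lens <- dims[m$dims]
      nelems <- if (length(lens) == 0L) 1L else prod(lens)
      dat <- .nc3_get_values(con, m$type, nelems)
      if (length(lens) >= 2L)
        dat <- aperm(array(dat, dim = unname(rev(lens))), rev(seq_along(lens)))
      vars[[m$name]] <- list(data = dat, dims = m$dims, atts = m$atts, type = m$type)
    }
  }
  list(dims = dims, global_atts = global_atts, vars = vars)
}
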
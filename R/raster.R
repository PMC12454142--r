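#' Gridded equal-area raster layer
#'
#' A minimal container for the gridded layers used throughout the package:
#' a numeric matrix on an abstract equal-area grid (no geographic CRS; every
#' cell covers the same area), plus a layer name, a units tag and a nodata
#' marker. Cells outside the modelled domain are `NA` internally and written
#' as the nodata value on disk.
#'
#' @param values numeric matrix (rows = latitude bands, row 1 = highest
#'   latitude; columns = longitude bands).
#' @param layer character layer name, e.g. `"life_restore_density"`.
#' @param units units tag, e.g. `"dE_per_km2"`, `"tonnes"`, `"head_per_km2"`.
#' @param nodata numeric nodata marker used on disk (default -9999).
#' @return An object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:6, 2, 3), layer = "demo", units = "tonnes")
#' dim(r)
#' @export
raster_grid <- function(values, layer = "layer", units = "", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  structure(
    list(values = values, layer = layer, units = units, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %s [%s], %d x %d cells\n",
              x$layer, x$units, nrow(v), ncol(v)))
  cat(sprintf("  range: %s .. %s (%d nodata)\n",
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' Extract the value matrix of a raster layer
#'
#' @param x a `raster_grid` or plain matrix.
#' @return numeric matrix.
#' @export
raster_values <- function(x) {
  if (inherits(x, "raster_grid")) x$values
  else if (is.matrix(x)) x
  else stop("expected a raster_grid or matrix", call. = FALSE)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Values are written with `%.17g` so float64 values round-trip exactly.
#' `NA` cells are written as the nodata marker.
#'
#' @param x a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(x, path) {
  stopifnot(inherits(x, "raster_grid"))
  v <- x$values
  v[is.na(v)] <- x$nodata
  con <- file(path, "wb")  # binary mode: deterministic newlines across platforms
  on.exit(close(con))
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner 0\nyllcorner 0\ncellsize 1\nNODATA_value %s\n",
    ncol(v), nrow(v), format(x$nodata))
  writeChar(hdr, con, eos = NULL)
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeChar(paste0(paste(rows, collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_raster()]
#'
#' @param path file path.
#' @param layer,units metadata to attach (not stored in the ASCII format).
#' @return A `raster_grid`; nodata cells become `NA`.
#' @export
read_ascii_raster <- function(path, layer = basename(path), units = "") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- tolower(keys)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- as.numeric(vals[["nodata_value"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d x %d",
                 length(body), nr, nc), call. = FALSE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, layer = layer, units = units, nodata = nodata)
}
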
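#' Lightweight planar grid raster
#'
#' A minimal matrix-backed raster for planar (projected, metre-unit) grids:
#' a numeric or integer matrix plus an origin and a square cell size. Rows
#' index northing (bottom row = southernmost), columns index easting. This is
#' the container used for categorical landcover/ecoregion layers and for
#' utilization-distribution grids.
#'
#' @param values numeric matrix; `values[i, j]` is the cell in row `i`
#'   (counted northward from the origin) and column `j` (eastward).
#' @param x0,y0 planar coordinates (m) of the grid's lower-left corner.
#' @param cell cell edge length in metres.
#'
#' @return An object of class `soar_raster`.
#' @export
soar_raster <- function(values, x0 = 0, y0 = 0, cell = 100) {
  stopifnot(is.matrix(values), cell > 0)
  structure(
    list(values = values, x0 = x0, y0 = y0, cell = cell),
    class = "soar_raster"
  )
}

#' @export
print.soar_raster <- function(x, ...) {
  cat(sprintf(
    "<soar_raster> %d x %d cells of %g m, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cell, x$x0, x$y0
  ))
  invisible(x)
}

#' @export
dim.soar_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster
#'
#' @param r a [soar_raster].
#' @return A list with numeric vectors `x` (column centres, eastings) and
#'   `y` (row centres, northings).
#' @export
raster_centers <- function(r) {
  list(
    x = r$x0 + (seq_len(ncol(r$values)) - 0.5) * r$cell,
    y = r$y0 + (seq_len(nrow(r$values)) - 0.5) * r$cell
  )
}

#' Look up raster values at point locations
#'
#' Nearest-neighbour (containing-cell) lookup; this is how categorical layers
#' are co-registered to utilization-distribution grids without resampling.
#'
#' @param r a [soar_raster].
#' @param x,y point coordinates in metres.
#' @return Vector of cell values; `NA` for points outside the grid.
#' @export
raster_lookup <- function(r, x, y) {
  col <- floor((x - r$x0) / r$cell) + 1L
  row <- floor((y - r$y0) / r$cell) + 1L
  ok <- col >= 1L & col <= ncol(r$values) & row >= 1L & row <= nrow(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' @method as_tibble soar_raster
#' @export
as_tibble.soar_raster <- function(x, ...) {
  ctr <- raster_centers(x)
  tibble::tibble(
    x = rep(ctr$x, each = nrow(x$values)),
    y = rep(ctr$y, times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Class frequencies of a categorical raster
#'
#' @param r a [soar_raster] with integer-coded classes.
#' @return Tibble with columns `unit` (class code) and `proportion`,
#'   summing to 1.
#' @export
raster_proportions <- function(r) {
  tab <- table(as.vector(r$values))
  tibble::tibble(
    unit = as.integer(names(tab)),
    proportion = as.numeric(tab) / sum(tab)
  )
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange for grid layers (readable by standard GIS tools).
#'
#' @param r a [soar_raster].
#' @param path file path.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [soar_raster].
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$x0),
    sprintf("yllcorner %.10g", r$y0),
    sprintf("cellsize %.10g", r$cell),
    "NODATA_value -9999"
  ), con)
  # ASCII grid rows run north -> south
  for (i in rev(seq_len(nrow(r$values)))) {
    writeLines(paste(format(r$values[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- as.integer(kv(1)); nrows <- as.integer(kv(2))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]
  m[m == -9999] <- NA_real_
  soar_raster(m, x0 = kv(3), y0 = kv(4), cell = kv(5))
}
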
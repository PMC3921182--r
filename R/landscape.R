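#' Generate a synthetic categorical landscape with nested ecoregions
#'
#' Builds a patchy habitat mosaic and a coarser ecoregion partition over a
#' planar rectangular extent, emulating a reclassified landcover raster with
#' habitat nested within ecological subregions. Patches are nearest-seed
#' (Voronoi) cells of randomly placed seed points; habitat classes are cycled
#' over seeds so every class is present and long-run class areas are roughly
#' equal. Deterministic for a given seed.
#'
#' @param seed integer RNG seed.
#' @param extent named numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_classes number of habitat classes (>= 2).
#' @param patch_scale characteristic habitat patch diameter in metres; must
#'   exceed the cell size.
#' @param cell raster cell size in metres (default 100, the analysis grid).
#' @param n_ecoregions number of ecoregion zones (>= 2).
#' @param class_labels optional character labels, length `n_classes`.
#'
#' @return A list of class `soar_landscape`: `habitat` and `ecoregion`
#'   ([soar_raster]s of integer codes), `availability` (tibble of extent-wide
#'   class proportions), `extent`, `cell`, `class_labels`.
#' @export
generate_landscape <- function(seed, extent = c(xmin = 0, xmax = 40000,
                                                ymin = 0, ymax = 40000),
                               n_classes = 12, patch_scale = 4000,
                               cell = 100, n_ecoregions = 4,
                               class_labels = NULL) {
  extent <- validate_extent(extent)
  w <- extent[["xmax"]] - extent[["xmin"]]
  h <- extent[["ymax"]] - extent[["ymin"]]
  if (w < cell || h < cell) {
    stop("invalid extent: smaller than one ", cell, " m cell", call. = FALSE)
  }
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (patch_scale <= cell) stop("patch_scale must exceed the cell size", call. = FALSE)
  if (!is.null(class_labels) && length(class_labels) != n_classes) {
    stop("class_labels must have length n_classes", call. = FALSE)
  }

  nx <- as.integer(floor(w / cell))
  ny <- as.integer(floor(h / cell))
  xc <- extent[["xmin"]] + (seq_len(nx) - 0.5) * cell
  yc <- extent[["ymin"]] + (seq_len(ny) - 0.5) * cell

  seed_rng(seed)
  n_seeds <- max(n_classes, round(w * h / patch_scale^2))
  sx <- stats::runif(n_seeds, extent[["xmin"]], extent[["xmax"]])
  sy <- stats::runif(n_seeds, extent[["ymin"]], extent[["ymax"]])
  cls <- sample(rep_len(seq_len(n_classes), n_seeds))

  lab <- nearest_seed_labels(xc, yc, sx, sy, cls)
  habitat <- soar_raster(lab, x0 = extent[["xmin"]], y0 = extent[["ymin"]],
                         cell = cell)
  habitat$values <- patch_missing_classes(habitat, sx, sy, cls, seq_len(n_classes))

  if (n_ecoregions < 2) stop("n_ecoregions must be >= 2", call. = FALSE)
  ex <- stats::runif(n_ecoregions, extent[["xmin"]], extent[["xmax"]])
  ey <- stats::runif(n_ecoregions, extent[["ymin"]], extent[["ymax"]])
  zlab <- nearest_seed_labels(xc, yc, ex, ey, seq_len(n_ecoregions))
  ecoregion <- soar_raster(zlab, x0 = extent[["xmin"]], y0 = extent[["ymin"]],
                           cell = cell)
  ecoregion$values <- patch_missing_classes(ecoregion, ex, ey,
                                            seq_len(n_ecoregions),
                                            seq_len(n_ecoregions))

  structure(list(
    habitat = habitat,
    ecoregion = ecoregion,
    availability = raster_proportions(habitat),
    extent = extent,
    cell = cell,
    class_labels = class_labels %||% as.character(seq_len(n_classes))
  ), class = "soar_landscape")
}

#' @export
print.soar_landscape <- function(x, ...) {
  cat(sprintf(
    "<soar_landscape> %d habitat classes, %d ecoregions, %d x %d cells of %g m\n",
    nrow(x$availability), length(unique(as.vector(x$ecoregion$values))),
    nrow(x$habitat$values), ncol(x$habitat$values), x$cell
  ))
  invisible(x)
}

validate_extent <- function(extent) {
  if (is.null(names(extent)) || !all(c("xmin", "xmax", "ymin", "ymax") %in% names(extent))) {
    names(extent) <- c("xmin", "xmax", "ymin", "ymax")
  }
  if (extent[["xmax"]] <= extent[["xmin"]] || extent[["ymax"]] <= extent[["ymin"]]) {
    stop("invalid extent: area must be positive", call. = FALSE)
  }
  extent
}

# Nearest-seed labelling, chunked over cells to bound memory; ties broken
# toward the lowest seed index (deterministic).
nearest_seed_labels <- function(xc, yc, sx, sy, cls) {
  nx <- length(xc); ny <- length(yc)
  gx <- rep(xc, each = ny)
  gy <- rep(yc, times = nx)
  n <- nx * ny
  out <- integer(n)
  chunk <- max(1L, floor(2e6 / length(sx)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(gx[s:e], sx, "-")^2 + outer(gy[s:e], sy, "-")^2
    out[s:e] <- cls[max.col(-d2, ties.method = "first")]
  }
  matrix(out, nrow = ny, ncol = nx)
}

# Guarantee every class appears: stamp the cell containing the first seed of
# any missing class.
patch_missing_classes <- function(r, sx, sy, cls, wanted) {
  vals <- r$values
  missing <- setdiff(wanted, unique(as.vector(vals)))
  for (m in missing) {
    i <- which(cls == m)[1]
    col <- min(max(floor((sx[i] - r$x0) / r$cell) + 1L, 1L), ncol(vals))
    row <- min(max(floor((sy[i] - r$y0) / r$cell) + 1L, 1L), nrow(vals))
    vals[row, col] <- m
  }
  vals
}

seed_rng <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Striped equal-area landscape
#'
#' A deterministic landscape of `n_classes` equal-width vertical stripes —
#' the minimal-boundary equal-area partition of a square extent. This is the
#' layout used by the selection-recovery scenarios: with the least possible
#' class boundary, kernel smoothing across boundaries attenuates the
#' estimated selection ratios as little as an equal-area design allows.
#'
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_classes number of stripes (>= 2).
#' @param cell raster cell size in metres.
#' @param n_ecoregions number of equal horizontal ecoregion bands (>= 2).
#' @return A `soar_landscape` (see [generate_landscape()]).
#' @export
stripe_landscape <- function(extent = c(xmin = 0, xmax = 40000,
                                        ymin = 0, ymax = 40000),
                             n_classes = 3, cell = 100, n_ecoregions = 2) {
  extent <- validate_extent(extent)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  nx <- as.integer(floor((extent[["xmax"]] - extent[["xmin"]]) / cell))
  ny <- as.integer(floor((extent[["ymax"]] - extent[["ymin"]]) / cell))
  if (nx < n_classes || ny < n_ecoregions) {
    stop("invalid extent: too small for the requested stripes", call. = FALSE)
  }
  col_class <- sort(rep(seq_len(n_classes), length.out = nx))
  habitat <- soar_raster(matrix(rep(col_class, each = ny), ny, nx),
                         x0 = extent[["xmin"]], y0 = extent[["ymin"]],
                         cell = cell)
  row_zone <- sort(rep(seq_len(n_ecoregions), length.out = ny))
  ecoregion <- soar_raster(matrix(rep(row_zone, times = nx), ny, nx),
                           x0 = extent[["xmin"]], y0 = extent[["ymin"]],
                           cell = cell)
  structure(list(
    habitat = habitat, ecoregion = ecoregion,
    availability = raster_proportions(habitat),
    extent = extent, cell = cell,
    class_labels = as.character(seq_len(n_classes))
  ), class = "soar_landscape")
}
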
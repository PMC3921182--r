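#' Reference bandwidth for a bivariate fixed-kernel estimate
#'
#' The bivariate normal reference ("h_ref") smoothing parameter:
#' `h_ref = sqrt((s_x^2 + s_y^2) / 2) * n^(-1/6)`, with `s_x`, `s_y` the
#' sample standard deviations of the coordinates. This is the standard
#' starting bandwidth for fixed-kernel home-range estimation; it tends to
#' over-smooth multi-modal ranges, which is what the ad-hoc contiguity rule
#' ([select_adhoc_bandwidth()]) exploits by shrinking it.
#'
#' @param points data frame with numeric columns `x_m`, `y_m` (metres).
#' @return Bandwidth in metres.
#' @export
reference_bandwidth <- function(points) {
  if (nrow(points) < 5) stop("need at least 5 points for a bandwidth", call. = FALSE)
  sx <- stats::sd(points$x_m)
  sy <- stats::sd(points$y_m)
  if (sx == 0 && sy == 0) {
    stop("degenerate point spread: all points identical", call. = FALSE)
  }
  sqrt((sx^2 + sy^2) / 2) * nrow(points)^(-1 / 6)
}

#' Fixed-kernel utilization distribution on a regular grid
#'
#' Estimates the utilization distribution (UD) by summing isotropic bivariate
#' Gaussian kernels of bandwidth `h` over a regular grid of square cells,
#' evaluating at cell centres and normalizing the grid to unit mass. The
#' grid covers the points plus a margin of `pad` (default `3h`, which keeps
#' truncated kernel mass below ~1e-3 before renormalization).
#'
#' @param points data frame with columns `x_m`, `y_m`.
#' @param h kernel bandwidth (SD) in metres; must be positive.
#' @param cell grid cell size in metres (default 100).
#' @param pad grid margin in metres (default `3 * h`).
#' @param max_cells guard on grid size (default 4e6); exceeding it raises an
#'   error suggesting a coarser `cell`.
#' @return An object of class `soar_ud`: a [soar_raster] of probability mass
#'   per cell (summing to 1) plus `h`, `h_ref`, `multiplier`, `n_points`.
#' @export
kernel_ud <- function(points, h, cell = 100, pad = NULL, max_cells = 4e6) {
  stopifnot(h > 0, cell > 0)
  pad <- pad %||% (3 * h)
  px <- points$x_m; py <- points$y_m
  x0 <- min(px) - pad; x1 <- max(px) + pad
  y0 <- min(py) - pad; y1 <- max(py) + pad
  nx <- max(1L, as.integer(ceiling((x1 - x0) / cell)))
  ny <- max(1L, as.integer(ceiling((y1 - y0) / cell)))
  if (as.double(nx) * ny > max_cells) {
    stop("UD grid would need ", nx, " x ", ny,
         " cells; increase `cell` (coarser grid) or lower `pad`", call. = FALSE)
  }
  xc <- x0 + (seq_len(nx) - 0.5) * cell
  yc <- y0 + (seq_len(ny) - 0.5) * cell
  # Separable Gaussian: the ny x nx kernel sum is a single matrix product.
  ax <- exp(-outer(xc, px, "-")^2 / (2 * h^2))   # nx x n
  ay <- exp(-outer(yc, py, "-")^2 / (2 * h^2))   # ny x n
  m <- ay %*% t(ax)
  m <- m / sum(m)
  ud <- soar_raster(m, x0 = x0, y0 = y0, cell = cell)
  structure(
    list(raster = ud, h = h, h_ref = NA_real_, multiplier = NA_real_,
         n_points = nrow(points)),
    class = "soar_ud"
  )
}

#' @export
print.soar_ud <- function(x, ...) {
  cat(sprintf(
    "<soar_ud> %d x %d cells of %g m, h = %.1f m%s, %d points\n",
    nrow(x$raster$values), ncol(x$raster$values), x$raster$cell, x$h,
    if (!is.na(x$multiplier)) sprintf(" (%.1f x h_ref)", x$multiplier) else "",
    x$n_points
  ))
  invisible(x)
}

#' @method as_tibble soar_ud
#' @export
as_tibble.soar_ud <- function(x, ...) as_tibble(x$raster)

#' Volume isopleth (home range) of a utilization distribution
#'
#' Selects the smallest set of highest-density cells whose cumulative
#' probability mass reaches `level` (default 0.99, the conventional
#' outer home-range contour), records the contained mass, counts connected
#' components under 8-connectivity, and traces the boundary rings along cell
#' edges.
#'
#' @param ud a [kernel_ud()] result.
#' @param level target cumulative mass in (0, 1).
#' @return An object of class `soar_homerange`: `cells` (logical membership
#'   matrix on the UD grid), `cell_tbl` (tibble of member cell indices and
#'   centre coordinates), `mass`, `level`, `n_components`, `polygons` (list
#'   of closed boundary rings, each a matrix of vertex coordinates), and the
#'   grid geometry (`x0`, `y0`, `cell`).
#' @export
volume_isopleth <- function(ud, level = 0.99) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  v <- as.vector(ud$raster$values)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(cum >= level)[1]
  sel <- logical(length(v))
  sel[ord[seq_len(k)]] <- TRUE
  cells <- matrix(sel, nrow = nrow(ud$raster$values))
  comp <- grid_components(cells)
  ctr <- raster_centers(ud$raster)
  idx <- which(cells, arr.ind = TRUE)
  cell_tbl <- tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    x = ctr$x[idx[, 2]], y = ctr$y[idx[, 1]],
    mass = ud$raster$values[idx]
  )
  structure(list(
    cells = cells, cell_tbl = cell_tbl, mass = cum[k], level = level,
    n_components = comp$n, component = comp$labels,
    polygons = trace_boundary(cells, ud$raster$x0, ud$raster$y0, ud$raster$cell),
    x0 = ud$raster$x0, y0 = ud$raster$y0, cell = ud$raster$cell
  ), class = "soar_homerange")
}

#' @export
print.soar_homerange <- function(x, ...) {
  cat(sprintf(
    "<soar_homerange> %d cells (%.1f km2), mass %.4f at level %.2f, %d component(s)\n",
    nrow(x$cell_tbl), nrow(x$cell_tbl) * (x$cell / 1000)^2, x$mass, x$level,
    x$n_components
  ))
  invisible(x)
}

# Connected components of TRUE cells under 8-connectivity (igraph backend).
grid_components <- function(cells) {
  idx <- which(cells)
  if (length(idx) == 0) return(list(n = 0L, labels = integer(0)))
  ny <- nrow(cells); nx <- ncol(cells)
  row <- (idx - 1L) %% ny + 1L
  col <- (idx - 1L) %/% ny + 1L
  pos <- matrix(0L, ny, nx)
  pos[idx] <- seq_along(idx)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  edges <- NULL
  for (s in shifts) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    j <- integer(length(idx)); j[ok] <- pos[cbind(r2[ok], c2[ok])]
    has <- ok & j > 0L
    if (any(has)) edges <- c(edges, rbind(which(has), j[has]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  cmp <- igraph::components(g)
  list(n = cmp$no, labels = cmp$membership)
}

# Boundary rings of the selected-cell union, traced along cell edges with
# interior on the left (outer rings CCW, holes CW). Returns a list of closed
# two-column matrices (x, y), vertices in metres.
trace_boundary <- function(cells, x0, y0, cell) {
  idx <- which(cells, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  ny <- nrow(cells); nx <- ncol(cells)
  inside <- function(r, c) {
    ok <- r >= 1 & r <= ny & c >= 1 & c <= nx
    res <- logical(length(r))
    res[ok] <- cells[cbind(r[ok], c[ok])]
    res
  }
  r <- idx[, 1]; c <- idx[, 2]
  segs <- list()
  # vertices keyed as (col_grid, row_grid) lattice points; cell (r, c) spans
  # lattice x in [c-1, c], y in [r-1, r]
  add <- function(keep, fx, fy, tx, ty) {
    if (!any(keep)) return()
    segs[[length(segs) + 1]] <<- cbind(fx[keep], fy[keep], tx[keep], ty[keep])
  }
  add(!inside(r - 1, c), c - 1, r - 1, c,     r - 1)  # bottom, L->R
  add(!inside(r, c + 1), c,     r - 1, c,     r)      # right, B->T
  add(!inside(r + 1, c), c,     r,     c - 1, r)      # top, R->L
  add(!inside(r, c - 1), c - 1, r,     c - 1, r - 1)  # left, T->B
  segs <- do.call(rbind, segs)
  from <- paste(segs[, 1], segs[, 2])
  used <- logical(nrow(segs))
  # at pinch vertices two segments may start at the same lattice point; take
  # the first unused one (deterministic)
  by_from <- split(seq_len(nrow(segs)), from)
  rings <- list()
  for (start in seq_len(nrow(segs))) {
    if (used[start]) next
    ring <- segs[start, 1:2, drop = FALSE]
    cur <- start
    repeat {
      used[cur] <- TRUE
      nxt_key <- paste(segs[cur, 3], segs[cur, 4])
      ring <- rbind(ring, segs[cur, 3:4])
      cand <- by_from[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      cur <- cand[1]
    }
    rings[[length(rings) + 1]] <- cbind(x = x0 + ring[, 1] * cell,
                                        y = y0 + ring[, 2] * cell)
  }
  rings
}

#' Ad-hoc bandwidth selection by isopleth contiguity
#'
#' Scans a descending grid of multiples of the reference bandwidth and
#' returns the smallest scanned multiplier whose `level` volume isopleth is a
#' single connected polygon (8-connectivity). This is the ad-hoc smoothing
#' rule ("h_adhoc"): the reference bandwidth over-smooths, so the smallest
#' multiple that keeps the outer contour contiguous minimizes overestimation
#' of the home-range boundary. The scan is exhaustive — every multiplier is
#' evaluated, with no monotonicity assumption.
#'
#' If no scanned multiplier yields a contiguous isopleth, the scan escalates
#' upward in steps of 0.1 to `escalate_cap` and returns the smallest
#' contiguous multiplier found there; failing that it errors.
#'
#' @param points data frame with columns `x_m`, `y_m`.
#' @param level isopleth level (default 0.99).
#' @param multipliers descending scan grid (default `seq(1, 0.1, by = -0.1)`).
#' @param cell grid cell size in metres (default 100).
#' @param max_cells passed to [kernel_ud()].
#' @param escalate_cap upper multiplier bound for the escalation scan
#'   (default 2).
#' @return A list of class `soar_adhoc`: `multiplier`, `h`, `h_ref`, `ud`
#'   (the selected [kernel_ud()]), `home_range` (its [volume_isopleth()]),
#'   and `scan` (tibble of multiplier, h, n_components, mass).
#' @export
select_adhoc_bandwidth <- function(points, level = 0.99,
                                   multipliers = seq(1, 0.1, by = -0.1),
                                   cell = 100, max_cells = 4e6,
                                   escalate_cap = 2) {
  h_ref <- reference_bandwidth(points)
  evaluate <- function(m) {
    ud <- kernel_ud(points, h = m * h_ref, cell = cell, max_cells = max_cells)
    hr <- volume_isopleth(ud, level = level)
    list(ud = ud, hr = hr)
  }
  scan_one <- function(ms) {
    res <- lapply(ms, evaluate)
    tibble::tibble(
      multiplier = ms,
      h = ms * h_ref,
      n_components = purrr::map_int(res, ~ .x$hr$n_components),
      mass = purrr::map_dbl(res, ~ .x$hr$mass),
      fit = res
    )
  }
  scan <- scan_one(sort(multipliers, decreasing = TRUE))
  contig <- scan$multiplier[scan$n_components == 1]
  if (length(contig) == 0 && escalate_cap > max(scan$multiplier)) {
    up <- seq(max(scan$multiplier) + 0.1, escalate_cap, by = 0.1)
    scan_up <- scan_one(up)
    scan <- dplyr::bind_rows(scan, scan_up)
    contig <- scan$multiplier[scan$n_components == 1]
  }
  if (length(contig) == 0) {
    stop("no multiplier up to ", escalate_cap,
         " x h_ref yields a contiguous ", level, " isopleth", call. = FALSE)
  }
  m_sel <- min(contig)
  sel <- scan$fit[[which(scan$multiplier == m_sel)[1]]]
  ud <- sel$ud
  ud$h_ref <- h_ref
  ud$multiplier <- m_sel
  structure(list(
    multiplier = m_sel, h = m_sel * h_ref, h_ref = h_ref,
    ud = ud, home_range = sel$hr,
    scan = scan[, c("multiplier", "h", "n_components", "mass")]
  ), class = "soar_adhoc")
}

#' @export
print.soar_adhoc <- function(x, ...) {
  cat(sprintf(
    "<soar_adhoc> h_adhoc = %.2f x h_ref = %.1f m (h_ref = %.1f m); home range: %d cells, mass %.4f\n",
    x$multiplier, x$h, x$h_ref, nrow(x$home_range$cell_tbl), x$home_range$mass
  ))
  invisible(x)
}

#' Write home-range polygons as GeoJSON
#'
#' Boundary rings become one Polygon feature per ring, with the contained
#' mass, level and component count as feature properties. Coordinates are in
#' the planar metre system of the analysis; consumers projecting to a
#' geographic CRS should do so downstream.
#'
#' @param hr a [volume_isopleth()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_homerange_geojson <- function(hr, path) {
  features <- lapply(seq_along(hr$polygons), function(i) {
    ring <- hr$polygons[[i]]
    list(
      type = "Feature",
      properties = list(ring = i, level = hr$level, mass = hr$mass,
                        n_components = hr$n_components),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(j) c(ring[j, 1], ring[j, 2])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
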
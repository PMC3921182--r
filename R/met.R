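#' Convective thermal velocity scale w*
#'
#' The Deardorff convective velocity scale,
#' `w* = (g * zi * Q0 / theta)^(1/3)`, with `g = 9.81` m/s2, `zi` the
#' boundary-layer (thermal) height in metres, `Q0` the surface kinematic
#' heat flux in K m/s, and `theta` the boundary-layer mean potential
#' temperature in K. It characterizes the updraft speed of convective
#' thermals driven by surface heating over the boundary-layer depth — the
#' lift a soaring bird can exploit. Negative fluxes (stable conditions, no
#' convection) are clipped to zero with a warning.
#'
#' @param flux surface kinematic heat flux (K m/s).
#' @param bl_height boundary-layer height (m).
#' @param theta mean potential temperature (K), must be positive.
#' @return w* in m/s (vectorized).
#' @export
thermal_velocity <- function(flux, bl_height, theta) {
  if (any(theta <= 0)) stop("potential temperature must be positive", call. = FALSE)
  if (any(bl_height < 0)) stop("boundary-layer height must be non-negative", call. = FALSE)
  if (any(flux < 0)) {
    warning(sum(flux < 0), " negative heat flux value(s) clipped to 0 (stable conditions)")
    flux <- pmax(flux, 0)
  }
  (9.81 * bl_height * flux / theta)^(1 / 3)
}

#' Boundary-layer mean wind speed
#'
#' Thickness-weighted mean of level wind speeds over the layer `[0,
#' bl_height]`. Each level represents the slab between the midpoints to its
#' neighbouring levels (first slab extends to the ground, last is capped at
#' the boundary-layer top).
#'
#' @param speeds wind speeds (m/s) at `heights`.
#' @param heights level heights (m), increasing.
#' @param bl_height boundary-layer height (m).
#' @return Mean speed in m/s.
#' @export
bl_mean_wind <- function(speeds, heights, bl_height) {
  stopifnot(length(speeds) == length(heights), !is.unsorted(heights))
  if (!any(heights <= bl_height)) {
    stop("no wind levels at or below the boundary-layer height", call. = FALSE)
  }
  bounds <- c(0, (heights[-1] + heights[-length(heights)]) / 2, Inf)
  lo <- pmin(bounds[-length(bounds)], bl_height)
  hi <- pmin(bounds[-1], bl_height)
  thick <- pmax(hi - lo, 0)
  sum(speeds * thick) / sum(thick)
}

#' Monthly means of mid-day values
#'
#' Averages one-per-day mid-day (21Z) values within each calendar month and
#' then across available years, yielding one climatological value per month.
#' Missing days are simply absent; a month with no values propagates `NA`.
#'
#' @param daily tibble with columns `date` (Date) and `value`, plus
#'   optionally any grouping columns (e.g. `cell_id`, `parameter`) which are
#'   preserved.
#' @return Tibble with the grouping columns, `month`, and `value` (the
#'   across-year mean of within-month means).
#' @export
monthly_midday_mean <- function(daily) {
  grp <- setdiff(names(daily), c("date", "value"))
  daily |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")),
                  month = as.integer(format(.data$date, "%m"))) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .by = dplyr::all_of(c(grp, "year", "month"))) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .by = dplyr::all_of(c(grp, "month"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "month"))))
}

#' Ecoregion-level monthly met means
#'
#' Averages each meteorological parameter over all coarse grid cells that
#' overlap each ecoregion with positive area, per month. A cell overlaps an
#' ecoregion if any fine-raster cell centre of that ecoregion falls inside
#' the cell's square footprint. Ecoregions overlapping no met cell are
#' excluded with a warning (data-poor zones).
#'
#' @param met_cells long tibble from [generate_met_grid()] (columns
#'   `cell_id`, `x`, `y`, `year`, `month`, `parameter`, `value`).
#' @param ecoregion_raster categorical [soar_raster] of ecoregion codes.
#' @param cell_km met cell size in kilometres (default 12).
#' @return Tibble `ecoregion`, `year`, `month`, `parameter`, `value` (the
#'   unweighted mean over overlapping cells).
#' @export
zonal_means <- function(met_cells, ecoregion_raster, cell_km = 12) {
  half <- cell_km * 1000 / 2
  geo <- dplyr::distinct(met_cells[, c("cell_id", "x", "y")])
  ctr <- raster_centers(ecoregion_raster)
  fine <- tibble::tibble(
    fx = rep(ctr$x, each = length(ctr$y)),
    fy = rep(ctr$y, times = length(ctr$x)),
    zone = as.vector(ecoregion_raster$values)
  )
  overlap <- purrr::pmap_dfr(geo, function(cell_id, x, y) {
    z <- unique(fine$zone[fine$fx >= x - half & fine$fx < x + half &
                            fine$fy >= y - half & fine$fy < y + half])
    if (length(z) == 0) return(NULL)
    tibble::tibble(cell_id = cell_id, ecoregion = z)
  })
  if (nrow(overlap) == 0) {
    overlap <- tibble::tibble(cell_id = character(), ecoregion = integer())
  }
  all_zones <- sort(unique(fine$zone))
  covered <- sort(unique(overlap$ecoregion))
  if (length(setdiff(all_zones, covered))) {
    warning("ecoregion(s) overlapping no met cell excluded: ",
            paste(setdiff(all_zones, covered), collapse = ", "))
  }
  dplyr::inner_join(met_cells, overlap, by = "cell_id",
                    relationship = "many-to-many") |>
    dplyr::summarise(
      value = mean(.data$value),
      .by = c("ecoregion", "year", "month", "parameter")
    ) |>
    dplyr::arrange(.data$ecoregion, .data$year, .data$month, .data$parameter)
}
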
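#' Generate a synthetic gridded monthly meteorology series
#'
#' Emulates monthly mid-day averages of soaring-relevant meteorology on a
#' coarse square grid (12 km cells by default, the resolution of mesoscale
#' forecast output): convective boundary-layer (thermal) height, convective
#' thermal velocity and boundary-layer mean wind speed. Each parameter follows
#' a seasonal sinusoid plus an optional west-east spatial gradient and
#' optional cell-level noise:
#'
#' `value = mean + amplitude * cos(2*pi*(month - peak_month)/12) + gradient * u + noise`
#'
#' where `u` in `[-1/2, 1/2]` is the cell centre's normalized easting.
#'
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param months tibble or data frame with columns `year`, `month`.
#' @param met_params named list, one entry per parameter (default the three
#'   soaring parameters), each a list with `mean`, `amplitude`, `peak_month`,
#'   `gradient` (and optionally `noise_sd`). Units: km for `thermal_height`,
#'   m/s for `thermal_velocity` and `wind_speed`.
#' @param cell_km grid cell size in kilometres (default 12).
#'
#' @return Tibble with columns `cell_id`, `x`, `y` (cell centres, m), `year`,
#'   `month`, `parameter`, `value`; one row per cell-month-parameter.
#' @export
generate_met_grid <- function(seed,
                              extent = c(xmin = 0, xmax = 40000,
                                         ymin = 0, ymax = 40000),
                              months = tibble::tibble(year = 2008, month = 1:12),
                              met_params = default_met_params(),
                              cell_km = 12) {
  extent <- validate_extent(extent)
  months <- tibble::as_tibble(months)
  if (nrow(months) == 0) stop("months must be non-empty", call. = FALSE)
  for (p in names(met_params)) {
    if (met_params[[p]]$mean <= 0) {
      stop("invalid met config: parameter '", p,
           "' needs a positive mean", call. = FALSE)
    }
  }

  cs <- cell_km * 1000
  w <- extent[["xmax"]] - extent[["xmin"]]
  h <- extent[["ymax"]] - extent[["ymin"]]
  nx <- max(1L, as.integer(ceiling(w / cs)))
  ny <- max(1L, as.integer(ceiling(h / cs)))
  cells <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny)) |>
    dplyr::mutate(
      cell_id = paste0("c", .data$ix, "_", .data$iy),
      x = extent[["xmin"]] + (.data$ix - 0.5) * cs,
      y = extent[["ymin"]] + (.data$iy - 0.5) * cs,
      u = (.data$x - extent[["xmin"]]) / w - 0.5
    )

  seed_rng(seed)
  grid <- tidyr::expand_grid(
    cells[, c("cell_id", "x", "y", "u")],
    months,
    parameter = names(met_params)
  )
  par_tbl <- purrr::map_dfr(met_params, function(p) {
    tibble::tibble(mean = p$mean, amplitude = p$amplitude %||% 0,
                   peak_month = p$peak_month %||% 6,
                   gradient = p$gradient %||% 0,
                   noise_sd = p$noise_sd %||% 0)
  }, .id = "parameter")
  grid <- dplyr::left_join(grid, par_tbl, by = "parameter") |>
    dplyr::mutate(
      value = .data$mean +
        .data$amplitude * cos(2 * pi * (.data$month - .data$peak_month) / 12) +
        .data$gradient * .data$u
    )
  if (any(par_tbl$noise_sd > 0)) {
    grid$value <- grid$value + stats::rnorm(nrow(grid), 0, grid$noise_sd)
  }
  if (any(grid$value <= 0)) {
    n_bad <- sum(grid$value <= 0)
    warning(n_bad, " non-positive met values clamped to a small positive floor")
    grid$value <- pmax(grid$value, 1e-6)
  }
  grid[, c("cell_id", "x", "y", "year", "month", "parameter", "value")]
}

#' Default seasonal parameters for the three soaring covariates
#'
#' Means and seasonal amplitudes of the order observed over Mediterranean-
#' climate terrain: thermal height ~1.2 +/- 0.6 km peaking in early summer,
#' thermal velocity ~1.8 +/- 0.8 m/s peaking in mid-summer, boundary-layer
#' mean wind ~6 +/- 2 m/s peaking in spring. The staggered peaks keep the
#' three covariates linearly independent across the annual cycle, as they
#' are in real forecast fields, and a small cell-level noise component
#' stands in for synoptic variability — without it the three same-period
#' sinusoids would be exactly collinear (they span only an intercept and one
#' annual harmonic) and no joint model could be fit.
#'
#' @return Named list suitable for [generate_met_grid()]'s `met_params`.
#' @export
default_met_params <- function() {
  list(
    thermal_height = list(mean = 1.2, amplitude = 0.6, peak_month = 6,
                          gradient = 0.4, noise_sd = 0.08),
    thermal_velocity = list(mean = 1.8, amplitude = 0.8, peak_month = 8,
                            gradient = 0.5, noise_sd = 0.12),
    wind_speed = list(mean = 6, amplitude = 2, peak_month = 4,
                      gradient = 1, noise_sd = 0.5)
  )
}
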
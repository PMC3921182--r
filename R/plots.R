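#' Plot a utilization distribution
#'
#' @param object a [kernel_ud()] result.
#' @param ... unused.
#' @return A ggplot raster map of probability mass.
#' @method autoplot soar_ud
#' @export
autoplot.soar_ud <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "UD mass") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot a home-range isopleth
#'
#' @param object a [volume_isopleth()] result.
#' @param ... unused.
#' @return A ggplot of the boundary rings.
#' @method autoplot soar_homerange
#' @export
autoplot.soar_homerange <- function(object, ...) {
  rings <- purrr::imap_dfr(object$polygons, function(m, i) {
    tibble::tibble(ring = i, x = m[, 1], y = m[, 2])
  })
  ggplot2::ggplot(rings, ggplot2::aes(.data$x, .data$y, group = .data$ring)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Easting (m)", y = "Northing (m)",
      title = sprintf("%.0f%% home range (%d component%s)",
                      100 * object$level, object$n_components,
                      if (object$n_components == 1) "" else "s")
    ) +
    ggplot2::theme_minimal()
}

#' Monthly selection-ratio curves by habitat
#'
#' Mean ln(rf) per habitat class and month across birds, with normal-theory
#' 95% confidence bands; one panel per class.
#'
#' @param records habitat-scale selection records (see
#'   [selection_records()]).
#' @param labels optional tibble `class`, `letter`/`label` (e.g.
#'   [condor_habitat_classes()]) for facet labels.
#' @return A ggplot.
#' @export
plot_selection_curves <- function(records, labels = NULL) {
  sm <- records |>
    dplyr::filter(.data$defined) |>
    dplyr::summarise(
      mean = mean(.data$ln_rf), se = stats::sd(.data$ln_rf) / sqrt(dplyr::n()),
      .by = c("unit", "month")
    ) |>
    dplyr::mutate(lower = .data$mean - 1.96 * .data$se,
                  upper = .data$mean + 1.96 * .data$se)
  if (!is.null(labels)) {
    lab <- labels$label %||% labels$letter
    sm$unit <- factor(sm$unit, levels = labels$class, labels = lab)
  }
  ggplot2::ggplot(sm, ggplot2::aes(.data$month, .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit) +
    ggplot2::labs(x = "Month", y = "ln(rf)") +
    ggplot2::theme_minimal()
}

#' Forest plot of model-averaged meteorological effects by ecoregion
#'
#' @param ma_table tibble with columns `ecoregion`, `parameter`, `estimate`,
#'   `lower`, `upper` (see [model_average()]).
#' @return A ggplot.
#' @export
plot_effect_forest <- function(ma_table) {
  ggplot2::ggplot(ma_table,
                  ggplot2::aes(.data$estimate, .data$ecoregion)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "Model-averaged coefficient (95% CI)",
                  y = "Ecoregion") +
    ggplot2::theme_minimal()
}

#' Monthly ln(rf) range per ecoregion
#'
#' The spread (min to max) of monthly mean selection ratios across the
#' annual cycle for each ecoregion, with the overall mean marked.
#'
#' @param records ecoregion-scale selection records.
#' @return A ggplot.
#' @export
plot_monthly_ranges <- function(records) {
  sm <- records |>
    dplyr::filter(.data$defined) |>
    dplyr::summarise(mean = mean(.data$ln_rf), .by = c("unit", "month")) |>
    dplyr::summarise(lo = min(.data$mean), hi = max(.data$mean),
                     mid = mean(.data$mean), .by = "unit")
  ggplot2::ggplot(sm, ggplot2::aes(y = factor(.data$unit))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mid)) +
    ggplot2::labs(x = "Monthly mean ln(rf) range", y = "Ecoregion") +
    ggplot2::theme_minimal()
}
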
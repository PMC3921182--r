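#' Proportional habitat use within a home range
#'
#' Accumulates utilization-distribution mass by habitat class over the home
#' range cells and renormalizes, giving the probability of occurrence in
#' each class within the monthly home range.
#'
#' @param ud a [kernel_ud()] result.
#' @param home_range a [volume_isopleth()] result on the same grid.
#' @param raster categorical [soar_raster] of habitat classes (looked up at
#'   UD cell centres, nearest neighbour).
#' @return Tibble `unit`, `use`; `use` sums to 1.
#' @export
habitat_use <- function(ud, home_range, raster) {
  tbl <- home_range$cell_tbl
  cls <- raster_lookup(raster, tbl$x, tbl$y)
  ok <- !is.na(cls)
  if (!any(ok)) stop("home range does not overlap the raster", call. = FALSE)
  agg <- rowsum(tbl$mass[ok], group = cls[ok])
  tibble::tibble(unit = as.integer(rownames(agg)),
                 use = as.vector(agg) / sum(agg))
}

#' Proportional availability within a home range
#'
#' The proportion of home-range cells (equal-area 100 m cells, so cell count
#' is area) in each class of a categorical layer.
#'
#' @inheritParams habitat_use
#' @return Tibble `unit`, `availability`; sums to 1.
#' @export
availability <- function(home_range, raster) {
  tbl <- home_range$cell_tbl
  cls <- raster_lookup(raster, tbl$x, tbl$y)
  ok <- !is.na(cls)
  if (!any(ok)) stop("home range does not overlap the raster", call. = FALSE)
  tab <- table(cls[ok])
  tibble::tibble(unit = as.integer(names(tab)),
                 availability = as.numeric(tab) / sum(tab))
}

#' Log selection ratios ln(use / availability)
#'
#' Joins use and availability by unit and computes
#' `ln_rf = ln(use / availability)`. The log makes selection symmetric
#' around proportional use: a ratio of 1/2 is as far from 1 as a ratio of 2.
#' Positive values indicate selection, negative avoidance, zero use in
#' proportion to availability.
#'
#' Units with zero availability are excluded (they cannot be used within the
#' range frame). Units available but with zero estimated use have an
#' undefined log ratio; they are kept with `ln_rf = NA` and `defined =
#' FALSE` so callers can count and exclude them, unless `use_floor > 0`
#' substitutes a small floor.
#'
#' @param use tibble `unit`, `use` from [habitat_use()].
#' @param avail tibble `unit`, `availability` from [availability()].
#' @param use_floor optional floor substituted for zero use (default 0 =
#'   off).
#' @return Tibble `unit`, `use`, `availability`, `ln_rf`, `defined`.
#' @export
selection_ratio <- function(use, avail, use_floor = 0) {
  if (all(avail$availability == 0)) {
    stop("invalid panel: all availabilities are zero", call. = FALSE)
  }
  out <- dplyr::full_join(use, avail, by = "unit") |>
    dplyr::mutate(use = dplyr::coalesce(.data$use, 0)) |>
    dplyr::filter(!is.na(.data$availability) & .data$availability > 0)
  u <- out$use
  if (use_floor > 0) u <- pmax(u, use_floor)
  out$defined <- u > 0
  out$ln_rf <- ifelse(out$defined, log(u / out$availability), NA_real_)
  dplyr::arrange(out[, c("unit", "use", "availability", "ln_rf", "defined")],
                 .data$unit)
}

#' Selection records for one bird-month panel
#'
#' Runs use, availability and ln(rf) for one panel at one scale and returns
#' long-format selection records.
#'
#' @inheritParams habitat_use
#' @param bird_id,year,month panel identifiers.
#' @param scale `"habitat"` or `"ecoregion"` label stored on the records.
#' @param use_floor passed to [selection_ratio()].
#' @return Tibble `bird_id`, `year`, `month`, `scale`, `unit`, `use`,
#'   `availability`, `ln_rf`, `defined`.
#' @export
selection_records <- function(ud, home_range, raster, bird_id, year, month,
                              scale = "habitat", use_floor = 0) {
  sr <- selection_ratio(habitat_use(ud, home_range, raster),
                        availability(home_range, raster),
                        use_floor = use_floor)
  tibble::tibble(bird_id = bird_id, year = year, month = month, scale = scale,
                 sr)
}

#' @rdname selection_records
#' @param ecoregion_raster categorical [soar_raster] of ecoregion codes.
#' @export
ecoregion_panel <- function(ud, home_range, ecoregion_raster, bird_id, year,
                            month, use_floor = 0) {
  selection_records(ud, home_range, ecoregion_raster, bird_id, year, month,
                    scale = "ecoregion", use_floor = use_floor)
}

#' Reclassify a categorical landcover raster
#'
#' Replaces raw landcover codes by coarser habitat classes via a
#' user-supplied mapping, the standard first step that collapses a detailed
#' landcover product (hundreds of classes) into a dozen ecologically
#' meaningful habitat types.
#'
#' @param raster categorical [soar_raster] of raw codes.
#' @param mapping data frame with columns `raw` and `class`.
#' @return A [soar_raster] with `class` codes.
#' @export
reclassify_landcover <- function(raster, mapping) {
  raw <- as.vector(raster$values)
  unmapped <- setdiff(unique(raw), mapping$raw)
  if (length(unmapped)) {
    stop("unmapped landcover code(s): ",
         paste(sort(unmapped), collapse = ", "), call. = FALSE)
  }
  new <- mapping$class[match(raw, mapping$raw)]
  out <- raster
  out$values <- matrix(new, nrow = nrow(raster$values))
  out
}

#' Example 12-class habitat scheme
#'
#' The twelve coarse habitat types used for condor-range landcover, labelled
#' A-L: agriculture, coastal dune, coastal rock, deciduous forest, evergreen
#' forest, grassland, modified land, savanna, shrubland, sparse vegetation,
#' unsuitable habitat, wetland.
#'
#' @return Tibble `class` (integer code 1-12), `letter`, `label`.
#' @export
condor_habitat_classes <- function() {
  tibble::tibble(
    class = 1:12,
    letter = LETTERS[1:12],
    label = c("agriculture", "coastal dune", "coastal rock",
              "deciduous forest", "evergreen forest", "grassland",
              "modified land", "savanna", "shrubland", "sparse vegetation",
              "unsuitable habitat", "wetland")
  )
}
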
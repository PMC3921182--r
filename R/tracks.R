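#' Simulate GPS tracks with known habitat selection
#'
#' Draws hourly daytime fixes for each bird under a known preference
#' structure, so that downstream selection estimates can be validated against
#' closed-form ground truth.
#'
#' In `point_process` mode, fixes are i.i.d. draws from a density
#' proportional to `K_hr(x) * w[h(x)]`, where `K_hr` is an isotropic
#' bivariate-normal home-range kernel centred per bird (SD `hr_sd`) and `w`
#' the habitat preference weights. With a uniform kernel (`hr_sd = Inf`) the
#' probability that a fix lands in class `j` is exactly
#' `a_j w_j / sum_k a_k w_k` with `a_k` the landscape availability, so the
#' expected selection ratio is `ln(w_j) - ln(sum_k a_k w_k)`.
#'
#' In `biased_walk` mode a correlated random walk proposes Gaussian steps and
#' accepts them with probability `w/max(w)` (habitat-weight rejection); no
#' closed form, used for robustness checks.
#'
#' @param scenario a [soar_scenario].
#' @param landscape a [soar_landscape] (its extent should match the
#'   scenario's).
#'
#' @return A list of class `soar_simulation`:
#'   * `fixes`: tibble `bird_id`, `t` (POSIXct, fixed UTC-8), `x_m`, `y_m`;
#'   * `birds`: attribute tibble (`bird_id`, `sex`, `age_class`, `breeder`,
#'     `release_site`, `rearing`);
#'   * `truth`: list with `expected_lnrf` tibble (`unit`, `lnrf`) and the
#'     per-bird kernel centres;
#'   * `n_fixes`: total fixes emitted (the generator's report, for round-trip
#'     checks).
#' @export
simulate_tracks <- function(scenario, landscape) {
  stopifnot(inherits(scenario, "soar_scenario"),
            inherits(landscape, "soar_landscape"))
  w <- scenario$habitat_weights
  classes <- sort(unique(as.vector(landscape$habitat$values)))
  if (length(w) != length(classes)) {
    stop("habitat_weights length (", length(w),
         ") must match the number of landscape classes (", length(classes), ")",
         call. = FALSE)
  }
  names(w) <- classes

  seed_rng(scenario$seed)
  ctr <- raster_centers(landscape$habitat)
  ny <- length(ctr$y); nx <- length(ctr$x)
  cls_vec <- as.vector(landscape$habitat$values)  # column-major: row fast
  w_cell <- unname(w[as.character(cls_vec)])
  if (all(w_cell == 0)) stop("degenerate scenario: all habitat weights are zero inside the extent", call. = FALSE)
  gx <- rep(ctr$x, each = ny)
  gy <- rep(ctr$y, times = nx)
  ext <- scenario$extent

  centers <- draw_bird_centers(scenario)
  birds <- draw_bird_attributes(scenario)
  slots <- fix_schedule(scenario)

  fixes <- purrr::map_dfr(seq_len(scenario$n_birds), function(b) {
    n_fix <- nrow(slots)
    if (scenario$movement_mode == "point_process") {
      if (is.finite(scenario$hr_sd)) {
        k <- exp(-((gx - centers$x[b])^2 + (gy - centers$y[b])^2) /
                   (2 * scenario$hr_sd^2))
      } else {
        k <- 1
      }
      p <- w_cell * k
      idx <- sample.int(length(p), size = n_fix, replace = TRUE, prob = p)
      cellsz <- landscape$cell
      x <- gx[idx] + stats::runif(n_fix, -cellsz / 2, cellsz / 2)
      y <- gy[idx] + stats::runif(n_fix, -cellsz / 2, cellsz / 2)
    } else {
      xy <- biased_walk(n_fix, centers$x[b], centers$y[b], scenario$step_sd,
                        landscape, w, ext)
      x <- xy$x; y <- xy$y
    }
    tibble::tibble(bird_id = sprintf("bird_%02d", b), t = slots$t,
                   x_m = x, y_m = y)
  })

  if (scenario$drop_rate > 0) {
    keep <- stats::runif(nrow(fixes)) >= scenario$drop_rate
    fixes <- fixes[keep, ]
  }

  avail <- landscape$availability
  lnZ <- log(sum(avail$proportion * unname(w[as.character(avail$unit)])))
  truth <- list(
    expected_lnrf = tibble::tibble(unit = avail$unit,
                                   lnrf = log(unname(w[as.character(avail$unit)])) - lnZ),
    centers = centers
  )

  structure(list(fixes = fixes, birds = birds, truth = truth,
                 n_fixes = nrow(fixes), scenario = scenario),
            class = "soar_simulation")
}

# One timestamp per scheduled slot across all study months, on the hour,
# within the 0500-2000 daytime window (fixed UTC-8; no DST).
fix_schedule <- function(scenario) {
  hours <- unique(round(seq(5, 20, length.out = scenario$fixes_per_day)))
  purrr::pmap_dfr(scenario$months, function(year, month) {
    nd <- days_in_month(year, month)
    tidyr::expand_grid(day = seq_len(nd), hour = hours) |>
      dplyr::mutate(t = ISOdatetime(year, month, .data$day, .data$hour, 0, 0,
                                    tz = "Etc/GMT+8"))
  })
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- seq(first, by = "1 month", length.out = 2)[2]
  as.integer(nxt - first)
}

draw_bird_centers <- function(scenario) {
  ext <- scenario$extent
  m <- if (is.finite(scenario$hr_sd)) {
    min(scenario$hr_sd, (ext[["xmax"]] - ext[["xmin"]]) / 4,
        (ext[["ymax"]] - ext[["ymin"]]) / 4)
  } else 0
  tibble::tibble(
    bird_id = sprintf("bird_%02d", seq_len(scenario$n_birds)),
    x = stats::runif(scenario$n_birds, ext[["xmin"]] + m, ext[["xmax"]] - m),
    y = stats::runif(scenario$n_birds, ext[["ymin"]] + m, ext[["ymax"]] - m)
  )
}

draw_bird_attributes <- function(scenario) {
  am <- scenario$attribute_marginals
  n <- scenario$n_birds
  draw <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  age <- draw(am$age_class)
  breeder <- ifelse(
    age == "adult",
    names(am$breeder_given_adult)[sample.int(2, n, replace = TRUE,
                                             prob = am$breeder_given_adult)],
    "no"
  )
  tibble::tibble(
    bird_id = sprintf("bird_%02d", seq_len(n)),
    sex = draw(am$sex),
    age_class = age,
    breeder = breeder,
    release_site = draw(am$release_site),
    rearing = draw(am$rearing)
  )
}

biased_walk <- function(n, x0, y0, step_sd, landscape, w, ext) {
  x <- numeric(n); y <- numeric(n)
  cx <- x0; cy <- y0
  wmax <- max(w)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      px <- cx + stats::rnorm(1, 0, step_sd)
      py <- cy + stats::rnorm(1, 0, step_sd)
      if (px < ext[["xmin"]] || px > ext[["xmax"]] ||
          py < ext[["ymin"]] || py > ext[["ymax"]]) next
      cls <- raster_lookup(landscape$habitat, px, py)
      if (is.na(cls)) next
      if (stats::runif(1) <= unname(w[as.character(cls)]) / wmax) break
    }
    cx <- px; cy <- py
    x[i] <- cx; y[i] <- cy
  }
  list(x = x, y = y)
}

#' Write simulation outputs to plain-text files
#'
#' Fixes and attributes as CSV, the habitat and ecoregion layers as ESRI
#' ASCII grids.
#'
#' @param sim a [simulate_tracks()] result.
#' @param landscape the matching [soar_landscape].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fixes = file.path(dir, "fixes.csv"),
    birds = file.path(dir, "birds.csv"),
    habitat = file.path(dir, "habitat.asc"),
    ecoregion = file.path(dir, "ecoregion.asc")
  )
  fx <- sim$fixes
  fx$timestamp <- format(fx$t, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(fx[, c("bird_id", "timestamp", "x_m", "y_m")],
                   paths[["fixes"]])
  readr::write_csv(sim$birds, paths[["birds"]])
  write_ascii_grid(landscape$habitat, paths[["habitat"]])
  write_ascii_grid(landscape$ecoregion, paths[["ecoregion"]])
  invisible(paths)
}
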
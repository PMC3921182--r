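#' Define a synthetic telemetry scenario
#'
#' A scenario bundles everything needed to simulate a multi-bird, multi-month
#' GPS telemetry study with known selection structure: the landscape extent,
#' per-class habitat preference weights, the fix schedule (hourly daytime
#' slots), the home-range kernel, and attribute marginals.
#'
#' @param seed integer RNG seed.
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param habitat_weights positive preference weights, one per habitat class
#'   (class `j` is used proportionally to `availability_j * w_j` in
#'   point-process mode).
#' @param n_birds number of birds.
#' @param months tibble with columns `year`, `month`.
#' @param fixes_per_day number of hourly fixes per day, at most 16 (the
#'   0500-2000 h daytime duty cycle).
#' @param movement_mode `"point_process"` (i.i.d. draws from the
#'   habitat-tilted home-range density; closed-form ground truth) or
#'   `"biased_walk"` (correlated walk with habitat-weight rejection).
#' @param hr_sd SD (m) of the isotropic bivariate-normal home-range kernel
#'   centred per bird; `Inf` gives uniform availability over the extent.
#' @param step_sd per-step SD (m) of the biased walk.
#' @param drop_rate fraction of scheduled fixes dropped at random
#'   (missingness; default 0).
#' @param met_params passed to [generate_met_grid()].
#' @param attribute_marginals named list of marginal frequencies for bird
#'   attributes; see [default_attribute_marginals()].
#'
#' @return An object of class `soar_scenario`.
#' @export
soar_scenario <- function(seed = 1,
                          extent = c(xmin = 0, xmax = 40000,
                                     ymin = 0, ymax = 40000),
                          habitat_weights = rep(1, 12),
                          n_birds = 20,
                          months = tibble::tibble(year = 2008, month = 1),
                          fixes_per_day = 16,
                          movement_mode = c("point_process", "biased_walk"),
                          hr_sd = 5000,
                          step_sd = 1500,
                          drop_rate = 0,
                          met_params = default_met_params(),
                          attribute_marginals = default_attribute_marginals()) {
  extent <- validate_extent(extent)
  if (any(habitat_weights <= 0)) {
    stop("all habitat_weights must be positive", call. = FALSE)
  }
  if (fixes_per_day > 16 || fixes_per_day < 1) {
    stop("fixes_per_day must be in 1..16 (hourly slots 0500-2000 h)",
         call. = FALSE)
  }
  if (drop_rate < 0 || drop_rate >= 1) stop("drop_rate must be in [0, 1)", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    extent = extent,
    habitat_weights = habitat_weights,
    n_birds = as.integer(n_birds),
    months = tibble::as_tibble(months),
    fixes_per_day = as.integer(fixes_per_day),
    movement_mode = match.arg(movement_mode),
    hr_sd = hr_sd,
    step_sd = step_sd,
    drop_rate = drop_rate,
    met_params = met_params,
    attribute_marginals = attribute_marginals
  ), class = "soar_scenario")
}

#' @export
print.soar_scenario <- function(x, ...) {
  cat(sprintf(
    "<soar_scenario> %d birds, %d month(s), %d fixes/day, mode=%s, seed=%d\n",
    x$n_birds, nrow(x$months), x$fixes_per_day, x$movement_mode, x$seed
  ))
  invisible(x)
}

#' Default bird-attribute marginal frequencies
#'
#' Defaults reflect a realistic managed-release population: a male-biased sex
#' ratio (43:31), three release sites splitting 53/27/20%, half the birds of
#' breeding age, and mostly captive-reared individuals. All configurable.
#'
#' @return Named list of probability vectors.
#' @export
default_attribute_marginals <- function() {
  list(
    sex = c(M = 43 / 74, F = 31 / 74),
    age_class = c(immature = 0.5, adult = 0.5),
    breeder_given_adult = c(yes = 0.4, no = 0.6),
    release_site = c(site_1 = 0.53, site_2 = 0.27, site_3 = 0.20),
    rearing = c(captive = 0.8, wild = 0.2)
  )
}
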
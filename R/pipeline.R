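#' Configuration for an end-to-end selection analysis run
#'
#' Collects every tunable of the pipeline with the conventional defaults:
#' 100 m analysis grid, 99% isopleth, 100-fix monthly minimum, descending
#' ad-hoc bandwidth scan, strict 0.01 screening alpha. Either a synthetic
#' `scenario` or paths to fix/attribute/landscape/met inputs must be given.
#'
#' @param scenario optional [soar_scenario] for a synthetic run.
#' @param fixes_path,attributes_path,habitat_path,ecoregion_path,met_path
#'   input files for a data run (CSV / ESRI ASCII grids), ignored when a
#'   scenario is supplied.
#' @param cell UD grid cell size, metres.
#' @param level isopleth level.
#' @param min_fixes monthly minimum fix count.
#' @param multipliers ad-hoc bandwidth scan grid.
#' @param global_multiplier if non-`NULL`, skip per-panel selection and use
#'   this fixed multiple of h_ref for every panel.
#' @param base_terms bird-characteristic terms held in every candidate model
#'   (default none; enable e.g. `c("sex", "release_site")` when the panel
#'   set is large enough to support them).
#' @param met_terms meteorological covariates defining the candidate set.
#' @param alpha screening threshold.
#' @param use_floor zero-use handling (see [selection_ratio()]).
#' @param seed integer seed for any stochastic stage.
#' @param out_dir optional output directory; when set, stage outputs are
#'   written as CSV and a checksum manifest is produced.
#' @return List of class `soar_config`.
#' @export
soar_config <- function(scenario = NULL, fixes_path = NULL,
                        attributes_path = NULL, habitat_path = NULL,
                        ecoregion_path = NULL, met_path = NULL,
                        cell = 100, level = 0.99, min_fixes = 100,
                        multipliers = seq(1, 0.1, by = -0.1),
                        global_multiplier = NULL,
                        base_terms = character(),
                        met_terms = c("thermal_height", "thermal_velocity",
                                      "wind_speed"),
                        alpha = 0.01, use_floor = 0, seed = 1,
                        out_dir = NULL) {
  stopifnot(level > 0, level < 1, min_fixes >= 1, cell > 0)
  structure(as.list(environment()), class = "soar_config")
}

#' Run the selection-analysis pipeline end to end
#'
#' Stages: ingest (or simulate) -> daytime window filter -> bird-month
#' panels -> per-panel ad-hoc bandwidth, UD and 99% home range -> selection
#' records at habitat and ecoregion scales -> ecoregion met join -> AICc
#' candidate models and model averaging per ecoregion -> report tables.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config a [soar_config()].
#' @param stop_after optional stage name (`"ingest"`, `"panels"`, `"ud"`,
#'   `"selection"`, `"met"`, `"models"`); later stages are skipped.
#' @return List of class `soar_run` with elements `panels`,
#'   `bandwidth_report`, `habitat_records`, `ecoregion_records`,
#'   `ecoregion_met`, `model_tables`, `screen_table`, `manifest` (when
#'   `out_dir` is set), plus the inputs used.
#' @export
run_pipeline <- function(config, stop_after = NULL) {
  stopifnot(inherits(config, "soar_config"))
  stages <- c("ingest", "panels", "ud", "selection", "met", "models")
  if (!is.null(stop_after)) stop_after <- match.arg(stop_after, stages)
  done <- function(stage) {
    !is.null(stop_after) && stage == stop_after
  }
  run <- list(config = config)

  # -- ingest ----------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    landscape <- generate_landscape(
      seed = sc$seed, extent = sc$extent,
      n_classes = length(sc$habitat_weights), cell = config$cell
    )
    sim <- simulate_tracks(sc, landscape)
    fixes <- sim$fixes
    birds <- sim$birds
    met <- generate_met_grid(seed = sc$seed, extent = sc$extent,
                             months = sc$months, met_params = sc$met_params)
    run$truth <- sim$truth
  } else {
    if (is.null(config$fixes_path)) {
      stop("config needs either a scenario or input paths", call. = FALSE)
    }
    fixes <- read_fixes(config$fixes_path)
    birds <- read_bird_attributes(config$attributes_path)
    landscape <- list(habitat = read_ascii_grid(config$habitat_path),
                      ecoregion = read_ascii_grid(config$ecoregion_path))
    met <- if (!is.null(config$met_path)) {
      readr::read_csv(config$met_path, show_col_types = FALSE)
    }
  }
  run$fixes <- fixes
  run$birds <- birds
  run$landscape <- landscape
  run$met <- met
  if (done("ingest")) return(finish_run(run))

  # -- panels ----------------------------------------------------------------
  windowed <- window_filter(fixes)
  run$panels <- build_panels(windowed, min_fixes = config$min_fixes)
  if (nrow(run$panels) == 0) stop("panel stage: no bird-month passed the fix minimum", call. = FALSE)
  if (done("panels")) return(finish_run(run))

  # -- ud / home ranges ------------------------------------------------------
  uds <- purrr::pmap(run$panels, function(bird_id, year, month, n_fixes, fixes) {
    tryCatch({
      if (!is.null(config$global_multiplier)) {
        h_ref <- reference_bandwidth(fixes)
        ud <- kernel_ud(fixes, h = config$global_multiplier * h_ref,
                        cell = config$cell)
        ud$h_ref <- h_ref; ud$multiplier <- config$global_multiplier
        hr <- volume_isopleth(ud, level = config$level)
        list(multiplier = config$global_multiplier, h = ud$h, h_ref = h_ref,
             ud = ud, home_range = hr)
      } else {
        select_adhoc_bandwidth(fixes, level = config$level,
                               multipliers = config$multipliers,
                               cell = config$cell)
      }
    }, error = function(e) {
      stop("ud stage failed for panel ", bird_id, " ", year, "-", month, ": ",
           conditionMessage(e), call. = FALSE)
    })
  })
  run$uds <- uds
  run$bandwidth_report <- dplyr::bind_cols(
    run$panels[, c("bird_id", "year", "month", "n_fixes")],
    tibble::tibble(
      h_ref = purrr::map_dbl(uds, "h_ref"),
      multiplier = purrr::map_dbl(uds, "multiplier"),
      h = purrr::map_dbl(uds, "h"),
      mass = purrr::map_dbl(uds, ~ .x$home_range$mass),
      n_components = purrr::map_int(uds, ~ .x$home_range$n_components)
    )
  )
  if (done("ud")) return(finish_run(run))

  # -- selection -------------------------------------------------------------
  sel <- purrr::map2_dfr(seq_len(nrow(run$panels)), uds, function(i, u) {
    p <- run$panels[i, ]
    dplyr::bind_rows(
      selection_records(u$ud, u$home_range, landscape$habitat,
                        p$bird_id, p$year, p$month, scale = "habitat",
                        use_floor = config$use_floor),
      ecoregion_panel(u$ud, u$home_range, landscape$ecoregion,
                      p$bird_id, p$year, p$month,
                      use_floor = config$use_floor)
    )
  })
  run$habitat_records <- sel[sel$scale == "habitat", ]
  run$ecoregion_records <- sel[sel$scale == "ecoregion", ]
  n_zero_use <- sum(!sel$defined)
  if (n_zero_use > 0) {
    message(n_zero_use, " record(s) with zero use flagged (excluded from models)")
  }
  if (done("selection")) return(finish_run(run))

  # -- met join --------------------------------------------------------------
  if (!is.null(met)) {
    run$ecoregion_met <- zonal_means(met, landscape$ecoregion)
    met_wide <- tidyr::pivot_wider(run$ecoregion_met,
                                   names_from = "parameter",
                                   values_from = "value")
    run$model_data <- run$ecoregion_records |>
      dplyr::filter(.data$defined) |>
      dplyr::rename(ecoregion = "unit") |>
      dplyr::inner_join(met_wide, by = c("ecoregion", "year", "month")) |>
      dplyr::inner_join(birds, by = "bird_id")
  }
  if (done("met") || is.null(met)) return(finish_run(run))

  # -- models ----------------------------------------------------------------
  run$model_tables <- model_stage(run$model_data, config)
  finish_run(run)
}

# Per-ecoregion candidate fits + model averaging; ecoregions with too little
# data to support the largest model are skipped (mirrors eliminating
# data-poor zones).
model_stage <- function(model_data, config) {
  max_k <- length(config$base_terms) + length(config$met_terms) + 4
  purrr::map(split(model_data, model_data$ecoregion), function(d) {
    enough <- length(unique(d$bird_id)) >= 2 &&
      any(stats::ave(if ("month_index" %in% names(d)) d$month_index else d$month,
                     d$bird_id,
                     FUN = function(x) length(unique(x))) >= 2) &&
      nrow(d) > max_k + 2
    if (!enough) {
      return(list(skipped = TRUE,
                  reason = sprintf("inadequate data (%d rows, %d birds)",
                                   nrow(d), length(unique(d$bird_id)))))
    }
    cand <- fit_candidates(d, base_terms = config$base_terms,
                           met_terms = config$met_terms)
    list(skipped = FALSE, candidates = cand,
         model_average = model_average(cand, parameters = config$met_terms))
  })
}

finish_run <- function(run) {
  cfg <- run$config
  if (!is.null(cfg$out_dir)) {
    run$manifest <- write_run_outputs(run, cfg$out_dir)
  }
  structure(run, class = "soar_run")
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p)
    paths[[name]] <<- p
  }
  if (!is.null(run$fixes)) {
    fx <- run$fixes
    fx$timestamp <- format(fx$t, "%Y-%m-%dT%H:%M:%S")
    put(fx[, c("bird_id", "timestamp", "x_m", "y_m")], "fixes.csv")
  }
  if (!is.null(run$birds)) put(run$birds, "birds.csv")
  if (!is.null(run$bandwidth_report)) put(run$bandwidth_report, "bandwidth_report.csv")
  if (!is.null(run$habitat_records)) put(run$habitat_records, "selection_habitat.csv")
  if (!is.null(run$ecoregion_records)) put(run$ecoregion_records, "selection_ecoregion.csv")
  if (!is.null(run$ecoregion_met)) put(run$ecoregion_met, "ecoregion_met.csv")
  if (!is.null(run$model_tables)) {
    ma <- purrr::imap_dfr(run$model_tables, function(m, z) {
      if (isTRUE(m$skipped)) return(NULL)
      dplyr::mutate(tibble::as_tibble(m$model_average), ecoregion = z,
                    .before = 1)
    })
    if (nrow(ma)) put(ma, "model_average.csv")
  }
  tibble::tibble(
    file = names(paths),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
}

#' @export
print.soar_run <- function(x, ...) {
  cat("<soar_run>\n")
  if (!is.null(x$panels)) cat("  panels:", nrow(x$panels), "\n")
  if (!is.null(x$habitat_records)) {
    cat("  habitat records:", nrow(x$habitat_records), "\n")
  }
  if (!is.null(x$model_tables)) {
    fitted <- sum(!purrr::map_lgl(x$model_tables, "skipped"))
    cat("  ecoregion model sets fitted:", fitted, "\n")
  }
  invisible(x)
}

#' Summary report tables and figures for a pipeline run
#'
#' Builds the standard outputs: monthly habitat selection-ratio curves with
#' confidence bands, a per-ecoregion model-averaged effect forest plot, and
#' a monthly ln(rf) range plot. Missing stages produce an explanatory note
#' instead of a figure.
#'
#' @param run a [run_pipeline()] result.
#' @return List with `selection_curves`, `effect_forest`, `monthly_ranges`
#'   (ggplot objects or `NULL` with a `notes` entry explaining the gap) and
#'   `model_average_table`.
#' @export
make_report <- function(run) {
  notes <- character()
  out <- list()
  if (!is.null(run$habitat_records) && nrow(run$habitat_records)) {
    out$selection_curves <- plot_selection_curves(run$habitat_records)
    out$monthly_ranges <- plot_monthly_ranges(run$ecoregion_records)
  } else {
    notes <- c(notes, "selection stage missing: run the pipeline through 'selection'")
  }
  if (!is.null(run$model_tables)) {
    ma <- purrr::imap_dfr(run$model_tables, function(m, z) {
      if (isTRUE(m$skipped)) return(NULL)
      dplyr::mutate(tibble::as_tibble(m$model_average), ecoregion = z, .before = 1)
    })
    out$model_average_table <- ma
    if (nrow(ma)) {
      out$effect_forest <- plot_effect_forest(ma)
    } else {
      notes <- c(notes, "no ecoregion had enough data for models; forest plot skipped")
    }
  } else {
    notes <- c(notes, "model stage missing; forest plot skipped")
  }
  out$notes <- notes
  out
}
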
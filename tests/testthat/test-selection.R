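# A hand-built UD/home-range pair on a small grid, for exact arithmetic.
toy_panel <- function(vals, classes, cell = 100) {
  stopifnot(all(dim(vals) == dim(classes)))
  vals <- vals / sum(vals)
  ud <- structure(
    list(raster = soar_raster(vals, 0, 0, cell), h = 1, h_ref = NA_real_,
         multiplier = NA_real_, n_points = 0L),
    class = "soar_ud"
  )
  hr <- volume_isopleth(ud, level = 1 - 1e-12)
  list(ud = ud, hr = hr, raster = soar_raster(classes, 0, 0, cell))
}

test_that("use and availability reduce to the obvious answers", {
  # single-class raster: all use, all availability
  tp <- toy_panel(matrix(stats::runif(16), 4), matrix(1L, 4, 4))
  expect_equal(habitat_use(tp$ud, tp$hr, tp$raster),
               tibble::tibble(unit = 1L, use = 1))
  expect_equal(availability(tp$hr, tp$raster),
               tibble::tibble(unit = 1L, availability = 1))

  # uniform UD over a 30/70 class split is proportional to cell counts
  cls <- matrix(1L, 10, 10); cls[, 4:10] <- 2L
  tpu <- toy_panel(matrix(1, 10, 10), cls)
  expect_equal(habitat_use(tpu$ud, tpu$hr, tpu$raster)$use, c(0.3, 0.7))
  expect_equal(availability(tpu$hr, tpu$raster)$availability, c(0.3, 0.7))
})

test_that("use matches a direct per-cell accumulation oracle", {
  set.seed(31)
  vals <- matrix(stats::runif(400), 20)
  cls <- matrix(sample(1:4, 400, replace = TRUE), 20)
  tp <- toy_panel(vals, cls)
  got <- habitat_use(tp$ud, tp$hr, tp$raster)
  # oracle: loop over home-range cells
  acc <- stats::setNames(numeric(4), 1:4)
  for (i in seq_len(nrow(tp$hr$cell_tbl))) {
    row <- tp$hr$cell_tbl$row[i]; col <- tp$hr$cell_tbl$col[i]
    acc[as.character(cls[row, col])] <- acc[as.character(cls[row, col])] +
      tp$ud$raster$values[row, col]
  }
  acc <- acc / sum(acc)
  expect_equal(got$use, unname(acc[as.character(got$unit)]), tolerance = 1e-12)
  expect_equal(sum(got$use), 1, tolerance = 1e-6)
  av <- availability(tp$hr, tp$raster)
  expect_equal(sum(av$availability), 1, tolerance = 1e-6)
})

test_that("selection ratios are symmetric and zero under proportional use", {
  u <- tibble::tibble(unit = 1:2, use = c(0.25, 0.75))
  a <- tibble::tibble(unit = 1:2, availability = c(0.25, 0.75))
  expect_equal(selection_ratio(u, a)$ln_rf, c(0, 0))

  # use/availability of 1/2 and 2 are equidistant from 0 on the log scale
  u2 <- tibble::tibble(unit = 1:2, use = c(1 / 3, 2 / 3))
  a2 <- tibble::tibble(unit = 1:2, availability = c(2 / 3, 1 / 3))
  lr <- selection_ratio(u2, a2)$ln_rf
  expect_equal(lr, c(-log(2), log(2)))
  expect_equal(abs(lr[1]), abs(lr[2]))
})

test_that("zero and missing cases follow the stated contract", {
  u <- tibble::tibble(unit = 1L, use = 1)
  a <- tibble::tibble(unit = 1:2, availability = c(0.5, 0.5))
  sr <- selection_ratio(u, a)
  expect_equal(nrow(sr), 2)
  expect_false(sr$defined[sr$unit == 2])
  expect_true(is.na(sr$ln_rf[sr$unit == 2]))
  # a use floor substitutes a defined value
  srf <- selection_ratio(u, a, use_floor = 1e-4)
  expect_true(all(srf$defined))
  # availability-zero units are excluded
  a0 <- tibble::tibble(unit = 1:2, availability = c(1, 0))
  expect_equal(selection_ratio(u, a0)$unit, 1L)
  expect_error(selection_ratio(u, tibble::tibble(unit = 1L, availability = 0)),
               "invalid panel")
})

test_that("mass-weighted use minus availability sums to zero", {
  set.seed(33)
  vals <- matrix(stats::runif(100), 10)
  cls <- matrix(sample(1:3, 100, replace = TRUE), 10)
  tp <- toy_panel(vals, cls)
  sr <- selection_ratio(habitat_use(tp$ud, tp$hr, tp$raster),
                        availability(tp$hr, tp$raster))
  expect_equal(sum(sr$use - sr$availability), 0, tolerance = 1e-12)
})

test_that("ln(rf) is invariant to relabeling and whole-cell translation", {
  set.seed(35)
  vals <- matrix(stats::runif(144), 12)
  cls <- matrix(sample(1:3, 144, replace = TRUE), 12)
  tp <- toy_panel(vals, cls)
  base <- selection_ratio(habitat_use(tp$ud, tp$hr, tp$raster),
                          availability(tp$hr, tp$raster))
  # relabel classes 1,2,3 -> 11,12,13
  relab <- tp$raster; relab$values <- relab$values + 10L
  shifted <- selection_ratio(habitat_use(tp$ud, tp$hr, relab),
                             availability(tp$hr, relab))
  expect_equal(shifted$ln_rf, base$ln_rf)
  # translate both grids by a whole number of cells
  tr_ud <- tp$ud; tr_ud$raster$x0 <- tr_ud$raster$x0 + 300
  tr_hr <- volume_isopleth(tr_ud, 1 - 1e-12)
  tr_ras <- tp$raster; tr_ras$x0 <- tr_ras$x0 + 300
  moved <- selection_ratio(habitat_use(tr_ud, tr_hr, tr_ras),
                           availability(tr_hr, tr_ras))
  expect_equal(moved$ln_rf, base$ln_rf)
})

test_that("ecoregion records mirror the habitat formulas at zone scale", {
  # home range inside one zone -> single record with ln_rf = 0
  tp <- toy_panel(matrix(stats::runif(25), 5), matrix(7L, 5, 5))
  rec <- ecoregion_panel(tp$ud, tp$hr, tp$raster, "b1", 2008, 6)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$ln_rf, 0)
  expect_equal(rec$scale, "ecoregion")
  # uniform UD split across two zones: both records zero
  zs <- matrix(1L, 6, 6); zs[, 4:6] <- 2L
  tp2 <- toy_panel(matrix(1, 6, 6), zs)
  rec2 <- ecoregion_panel(tp2$ud, tp2$hr, tp2$raster, "b1", 2008, 6)
  expect_equal(rec2$ln_rf, c(0, 0))
})

test_that("selection recovers known weights in a point-process scenario", {
  # weights (1, 2, 4) on equal-area stripes with uniform availability: the
  # estimated ln(rf) ordering matches the preference weights and the
  # contrasts recover ln 2 and ln 4 up to the kernel-smoothing attenuation
  # (bounded below 25% for this design; see the methods vignette)
  ls <- stripe_landscape()
  sc <- soar_scenario(seed = 42, extent = ls$extent,
                      habitat_weights = c(1, 2, 4), n_birds = 6,
                      hr_sd = Inf, fixes_per_day = 16)
  sim <- simulate_tracks(sc, ls)
  recs <- purrr::map_dfr(unique(sim$fixes$bird_id), function(b) {
    pts <- sim$fixes[sim$fixes$bird_id == b, ]
    sel <- select_adhoc_bandwidth(pts, cell = 100)
    selection_records(sel$ud, sel$home_range, ls$habitat, b, 2008, 1)
  })
  means <- recs |>
    dplyr::filter(.data$defined) |>
    dplyr::summarise(lnrf = mean(.data$ln_rf), .by = "unit") |>
    dplyr::arrange(.data$unit)
  expect_true(all(diff(means$lnrf) > 0))
  expect_lt(means$lnrf[1], 0)  # avoided class
  expect_gt(means$lnrf[3], 0)  # selected class
  c2 <- means$lnrf[2] - means$lnrf[1]
  c4 <- means$lnrf[3] - means$lnrf[1]
  expect_true(c2 > 0.75 * log(2) - 0.2 && c2 < log(2) + 0.2)
  expect_true(c4 > 0.75 * log(4) - 0.2 && c4 < log(4) + 0.2)
})

test_that("landcover reclassification pools codes and flags gaps", {
  raw <- soar_raster(matrix(c(1L, 2L, 3L, 4L), 2), cell = 100)
  # identity mapping leaves the raster unchanged
  ident <- tibble::tibble(raw = 1:4, class = 1:4)
  expect_equal(reclassify_landcover(raw, ident)$values, raw$values)
  # 4 raw codes to 2 classes: cell counts pool additively
  mp <- tibble::tibble(raw = 1:4, class = c(1L, 1L, 2L, 2L))
  rc <- reclassify_landcover(raw, mp)
  expect_equal(as.vector(table(rc$values)), c(2, 2))
  expect_error(reclassify_landcover(raw, mp[1:2, ]), "unmapped.*3, 4")
  # the shipped example scheme has the twelve A-L classes
  sch <- condor_habitat_classes()
  expect_equal(nrow(sch), 12)
  expect_equal(sch$letter, LETTERS[1:12])
  expect_equal(sch$label[c(1, 12)], c("agriculture", "wetland"))
})

test_that("the shipped example landcover mapping drives reclassification", {
  mp <- readr::read_csv(system.file("extdata", "example_landcover_mapping.csv",
                                    package = "soarsel"),
                        show_col_types = FALSE)
  expect_setequal(unique(mp$class), 1:12)
  raw <- soar_raster(matrix(sample(1:24, 64, replace = TRUE), 8), cell = 100)
  rc <- reclassify_landcover(raw, mp)
  expect_true(all(rc$values %in% 1:12))
  # pooling: counts of a class equal the summed counts of its raw codes
  cls1_raw <- mp$raw[mp$class == 1]
  expect_equal(sum(rc$values == 1), sum(raw$values %in% cls1_raw))
})
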
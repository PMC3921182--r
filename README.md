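# soarsel

Resource selection analysis for soaring birds from GPS telemetry.

Large soaring scavengers (condors, vultures) move by thermal and orographic
lift, so the resources that shape their space use include both terrestrial
habitat and the meteorology of the convective boundary layer. soarsel
implements the full analysis chain for quantifying that selection from
hourly GPS fixes:

- **Monthly fixed-kernel utilization distributions (UDs)** on a 100 m grid,
  with the bandwidth chosen by the *ad-hoc contiguity rule*: scan descending
  multiples of the reference bandwidth
  `h_ref = sqrt((s_x² + s_y²)/2) · n^(−1/6)` and keep the smallest multiple
  whose 99% volume isopleth is a single connected polygon.
- **Home ranges** as 99% volume isopleths (smallest set of highest-density
  cells holding 99% of UD mass), with boundary rings and component counts.
- **Selection ratios** `ln(rf) = ln(use / availability)` per habitat class
  and per ecoregion within each monthly home range: `> 0` selection,
  `0` proportional use, `< 0` avoidance, symmetric on the log scale.
- **Soaring meteorology**: convective boundary-layer (thermal) height,
  Deardorff thermal velocity `w* = (g·zi·Q₀/θ)^(1/3)`, and boundary-layer
  mean wind, aggregated from a 12 km grid to ecoregion-month means.
- **Repeated-measures mixed models** of `ln(rf)` (random bird intercept,
  AR(1) months; ML via nlme) with **AICc model averaging** over the subsets
  of the three meteorological covariates: model-averaged coefficients,
  unconditional SEs, 95% CIs, and importance weights.
- A **synthetic-data generator** (landscapes, met grids, bird attributes,
  GPS tracks) with known preference weights and closed-form expected
  `ln(rf)`, so the whole pipeline is testable end to end.

The package is tidyverse-native: tabular inputs and outputs are tibbles,
fitted objects have `tidy()`/`glance()` methods, and result types have
`autoplot()`/`plot_*()` figures.

## Worked example

Simulate five birds on an equal-area three-stripe landscape with preference
weights (1, 2, 4), pick the ad-hoc bandwidth for one bird-month, and compute
its selection ratios:

```r
library(soarsel)
library(dplyr)

ls <- stripe_landscape()                      # 40 x 40 km, three stripes
sc <- soar_scenario(seed = 1, extent = ls$extent,
                    habitat_weights = c(1, 2, 4),
                    n_birds = 5, hr_sd = Inf, fixes_per_day = 16)
sim <- simulate_tracks(sc, ls)

sim$truth$expected_lnrf
#> # A tibble: 3 × 2
#>    unit   lnrf
#>   <int>  <dbl>
#> 1     1 -0.846
#> 2     2 -0.153
#> 3     3  0.540

pts <- filter(sim$fixes, bird_id == "bird_01")
sel <- select_adhoc_bandwidth(pts, cell = 200)
sel
#> <soar_adhoc> h_adhoc = 0.20 x h_ref = 786.2 m (h_ref = 3931.0 m); home range: 36911 cells, mass 0.9900

selection_records(sel$ud, sel$home_range, ls$habitat, "bird_01", 2008, 1)
#> # A tibble: 3 × 9
#>   bird_id  year month scale    unit   use availability  ln_rf defined
#>   <chr>   <dbl> <dbl> <chr>   <int> <dbl>        <dbl>  <dbl> <lgl>
#> 1 bird_01  2008     1 habitat     1 0.161        0.265 -0.498 TRUE
#> 2 bird_01  2008     1 habitat     2 0.299        0.354 -0.167 TRUE
#> 3 bird_01  2008     1 habitat     3 0.540        0.381  0.348 TRUE
```

One bird-month is noisy, but the signs and ordering already track the known
weights (stripe 3, the most preferred habitat, is used 54% against 38%
availability, `ln(rf) = 0.35`); averaging over birds recovers the
ground-truth contrasts `ln 2` and `ln 4` up to a documented smoothing
attenuation of roughly 10% (see the methods vignette).

On the model side, a model-averaged `ln(rf)` slope converts to a
multiplicative effect on the selection ratio:

```r
effect_multiplier(1.080, 1)   # per 1 km of thermal height
#> [1] 2.94468
```

i.e. each additional kilometre of thermal height nearly triples the
selection ratio.

The full pipeline — ingest, panels, UDs, selection at both scales, met
join, candidate models, model averaging, report tables — runs from one
configuration object:

```r
cfg <- soar_config(scenario = sc, cell = 200, out_dir = "out", seed = 1)
run <- run_pipeline(cfg)
rep <- make_report(run)   # figures + model-average table
```

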
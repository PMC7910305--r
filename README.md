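# rivershift

Riverbank habitat dynamics, regime shifts, and crocodylian nesting.

## The problem

Gharials (*Gavialis gangeticus*) nest exclusively on open sandy riverbanks
and mid-river sandbars. In regulated rivers, reduced flow lets woody
vegetation colonise those banks, and nesting collapses. Quantifying that
process from a satellite archive takes four linked analyses, and this
package implements all of them as tested, reusable R functions:

1. **EVI computation and seasonal aggregation.** The Enhanced Vegetation
   Index is derived per scene from blue, red, and near-infrared surface
   reflectance,

   EVI = G (NIR − Red) / (NIR + C₁·Red − C₂·Blue + L),

   with the standard Landsat coefficients G = 2.5, C₁ = 6, C₂ = 7.5,
   L = 1, and assembled into per-site time series and nesting-season
   (March–April) averages.

2. **Habitat classification and validation.** Ground plots are labelled
   from cover fractions (water/sand/grass/shrub/tree, evaluated
   woodiest-first); EVI is classified by threshold intervals
   (water < 0; sand 0–0.08; grass 0.05–0.13; shrub 0.13–0.215;
   tree 0.215–0.325), or by the merged three-class scheme — water (EVI < 0),
   sandy grassland (0 ≤ EVI < 0.13), woody vegetation (EVI ≥ 0.13) — that
   the downstream analyses use. Thresholds can be recalibrated on a random
   80% plot split and validated on the held-out 20% with confusion
   matrices, producer's/user's accuracies, and Cohen's kappa
   κ = (p₀ − pₑ)/(1 − pₑ).

3. **Changepoints and the "no return" regime-shift rule.** Per-site EVI
   series are segmented by penalised Gaussian cost minimisation — mean-only
   or mean-and-variance — with PELT (exact, pruned), exhaustive dynamic
   programming (exact, unpruned), or greedy binary segmentation, all
   re-implemented here. A changepoint is promoted to a *regime shift* when
   the habitat never returns to its prior modal class: the fraction of
   later observations classified into the pre-shift modal class must stay
   at or below a tolerance (default 0.05).

4. **Nest-count ~ EVI relation.** Linear, exponential
   (on log(nests + 1)), and shifted-logarithmic forms are fitted by least
   squares, compared by R² on the count scale, and the winner's slope
   p-value is averaged over 1000 random 80% subsamples.

Because the original Landsat scenes and field plots are not deposited
anywhere, a seeded synthetic riverscape generator reproduces the
statistical structure the analyses assume — seasonal water/sand
oscillation, abrupt/gradual/via-water woody conversion around a
disturbance year, class-conditional EVI distributions with sand/grass
overlap, and negative-binomial nest counts declining with EVI — so every
stage is testable offline.

## Worked example

```r
library(rivershift)

## Nest-site usage, 2015-2019 (packaged fixture)
tb <- read_nest_table_csv(table2_path())
summarize_year(tb, 2017)
#> $total 32   $active_sites 7   $max_count 21   $max_site "N4"
percent_decline(35, 19)$rounded
#> [1] 46

## Synthetic riverscape: one site, 1988-2019, abrupt woody shift in 2010
cfg <- synthetic_config(seed = 42)
s <- generate_evi_series(cfg, 4)
s
#> EVI series 'S4': 384 observations (1988-01-15 to 2019-12-15), range [-0.071, 0.281]
rs <- find_regime_shift(s, detect_changepoints(s))
rs
#> Site 'S4': regime shift at 2009-12-15 (sandy_grassland -> woody, return fraction 0.000)

## Threshold calibration and held-out validation
plots <- generate_habitat_plots(cfg, n_plots = 400)
cal <- calibrate_thresholds(plots, train_fraction = 0.8, seed = 43)
held <- plots[cal$test, ]
validate(merge_classes(held$class),
         merge_classes(classify_evi_5(held$evi, cal$scheme)))
#> overall accuracy: 0.988  mean class accuracy: 0.988  kappa: 0.980

## Nest counts decline with EVI
evi <- seq(0, 0.3, length.out = 24)
nt <- generate_nest_table(cfg, data.frame(site = sprintf("S%d", 1:24),
                                          year = 2017, evi = evi))
fit <- nest_evi_fit(data.frame(evi = evi, nests = nt$nests),
                    n_boot = 1000, seed = 44)
summary(fit)
#>         form intercept   slope r_squared   p_slope
#>       linear    15.663 -62.200    0.5371 4.642e-05
#>  exponential     2.883  -8.803    0.6242 8.627e-08
#>  logarithmic    -9.377  -7.497    0.7093 2.459e-07
#> selected: logarithmic; mean subsample p = 5.46e-05 (1000 replicates, 0 skipped)
```

Reading the output: the regime shift lands at the last observation before
the configured 2010 disturbance; the held-out kappa near 1 says the
synthetic class-conditional EVI spreads barely cross the merged
thresholds; and the selected nest-relation slope is negative — fewer
nests where vegetation is denser — with a subsample-averaged p-value far
below 0.05.

## Package layout

* `R/synthetic.R` — riverscape generator (`synthetic_config`,
  `generate_evi_series`, `generate_habitat_plots`, `generate_nest_table`,
  `write_synthetic_csvs`)
* `R/evi.R` — `compute_evi`, `evi_series`, `seasonal_average`,
  `build_timeseries`
* `R/classify.R` — `classify_plot`, `classify_evi_5`, `classify_evi_3`,
  `published_scheme`, `calibrate_thresholds`, `validate`
* `R/changepoint.R` — `detect_changepoints` (PELT / binseg / exhaustive),
  `find_regime_shift`, `batch_dynamics`
* `R/nestfit.R` — `fit_models`, `select_best`, `bootstrap_p`,
  `nest_evi_fit` with print/summary/coef/predict/plot/simulate methods
* `R/nesting.R` — `parse_nest_table`, `summarize_year`,
  `percent_decline`, packaged fixture via `table2_path()`
* `vignettes/habitat-regime-shifts.Rmd` — the methods notes: model
  assumptions, parameter choices, and limitations
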
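# roadproxy

Validation tools for road-traffic proxy indicators of personal PM2.5
exposure.

In most of sub-Saharan Africa, ground-based air quality monitoring is too
sparse to characterise fine-particulate (PM2.5) exposure directly, and
indirect *proxy indicators* built from open geodata — road networks,
gridded population — are an attractive substitute. But their validity is
context-dependent: where non-traffic sources (agricultural burning,
marketplaces) dominate, proximity-to-road proxies can even reverse sign.
`roadproxy` implements an end-to-end framework for deriving road-traffic
proxies at village level and validating them against minute-resolution
personal-monitor measurements, together with a synthetic-data generator so
the entire pipeline can be exercised, tested and benchmarked with no access
to any cohort data.

## What it computes

**Proxies** (per village, in a metric planar frame):

- **WRND** — population-weighted road network density. A fishnet grid
  aligned to the 100 m population raster is intersected with the village
  boundary; per-cell road density `RND = road length / cell area`
  (km/km²) is combined with the per-cell population count:

  `WRND = Σ(RND_cell × Pop_cell) / Σ(Pop_cell)`

- **EM / EH** — Euclidean (straight-line) distance from the village
  centroid to the nearest main road / highway (km), with the nearest point
  allowed in a segment interior.

**Mobility filter**: personal-monitor GPS traces are classified
indoor/outdoor by a displacement-speed threshold (default 100 m/min),
validated by point-in-polygon tests against building footprints, reconciled
via a confusion matrix with the building label as ground truth, and
restricted to outdoor periods.

**Validation**: village-level outdoor PM2.5 means are aggregated onto a
5 km hexagonal tessellation with bivariate class codes; proxy–PM2.5
association is measured by Spearman rank correlation (per stratum and
pooled); predictive utility by a random-forest land-use regression
(ntree = 50, mtry = ⌊√p⌋, 3-fold cross-validation) reporting out-of-fold
R², RMSE, MAE, mean bias error, binned bias profiles and feature
importance.

## Worked example

```r
library(roadproxy)

ls <- generate_landscape(seed = 1, n_villages = 4)
ls
#> Synthetic landscape
#>   extent: [0, 10000] x [0, 10000] m
#>   roads: 5 (highway=2, main=3)
#>   villages: 4; buildings: 100; hotspots: 0
#>   population: 100 x 100 cells of 100 m, total 6171

village_proxy_table(ls)
#>   village_id  wrnd    em     eh flags
#> 1 village_01 0.000 0.913 5.7980
#> 2 village_02 0.605 1.956 0.3273
#> 3 village_03 1.472 1.742 0.0536
#> 4 village_04 0.000 0.819 4.2216
```

WRND is in km/km² (population-weighted over the village's fishnet cells),
EM/EH in km; a village with no road inside its boundary has WRND 0 while
still having finite road distances.

```r
tr <- simulate_traces(ls, exposure_params(seed = 2),
                      n_participants = 5, minutes_per_participant = 600)
cl <- classify_readings(tr, ls$buildings, coverage = ls$extent)
cl$confusion
#> Speed-vs-building confusion matrix (covered readings, pre-correction)
#>              building
#> speed         outdoor indoor
#>   outdoor         188     66
#>   not-outdoor     716   2030
#> accuracy 0.739, sensitivity 0.208, specificity 0.969 (n = 3000)
```

The speed rule alone is conservative (most walking minutes fall below
100 m/min), which is why the building-footprint validation matters: after
reconciliation the labels recover the simulated microenvironment with
better than 99% accuracy here.

```r
d <- simulate_proxy_observations(seed = 1, n = 150)
fit <- fit_rf_cv(d, c("wrnd", "em", "eh"), seed = 1)
fit
#> Random-forest LUR (3-fold CV): pm25 ~ wrnd + em + eh
#>   n = 150, ntree = 50, mtry = 1, seed = 1
#>   out-of-fold: R2 = 0.356, RMSE = 3.91, MAE = 3.15, MBE = -0.14 ug/m3
round(feature_importance(fit), 3)
#>  wrnd    em    eh
#> 0.337 0.281 0.382
```

`fit_rf_cv()` returns a classed object with `print`, `summary`, `predict`,
`residuals` and `plot` (observed vs predicted) methods; `binned_bias()`
produces the bias-profile analogue with a bootstrap 95% CI band.

The whole chain — simulate, classify, filter, proxies, hexagons,
correlations, models — runs from one (optionally YAML) config:

```r
run_pipeline(list(seed = 7, outdir = "run1"))
```

which writes every stage's outputs (CSV/GeoJSON/JSON) plus a manifest, and
is byte-reproducible for a fixed config. A thin CLI wrapper lives at
`inst/cli/roadproxy.R`.

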
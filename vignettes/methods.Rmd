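---
title: "Road-traffic proxy validation for personal PM2.5 exposure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Road-traffic proxy validation for personal PM2.5 exposure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadproxy)
```

`roadproxy` validates road-traffic proxy indicators of PM2.5 exposure in
settings where ground monitoring is sparse. This vignette is the package's
account of the models it implements, the parameters that matter, and the
design choices made where the design was genuinely open.

## The proxies

All computation happens in a metric planar frame (metres). In a real-data
application, inputs should be projected to the UTM zone of the study-area
centroid before use; the package performs no geodetic computation itself.

**Population-weighted road network density (WRND).** A *fishnet* grid of
square cells, exactly aligned to the population raster (cell corners
coincide), is intersected with the village boundary. The road network is
first clipped to the boundary, then split along the gridlines; per cell,

$$\mathrm{RND}_{cell} = \frac{\text{road length in cell (km)}}{\text{cell area (km}^2)},\qquad
\mathrm{WRND} = \frac{\sum_{cells} \mathrm{RND}_{cell}\,\mathrm{Pop}_{cell}}{\sum_{cells} \mathrm{Pop}_{cell}}.$$

Open choices, resolved as follows:

- *Cell membership*: a cell belongs to a village when its polygon overlaps
  the boundary with positive area (> 1e-9 m²); cells that merely share an
  edge with the boundary are excluded. Because road lengths are computed on
  the boundary-clipped network, edge cells contribute only in-boundary road
  length either way.
- *Population in edge cells*: by default a cell contributes its full raster
  count (mirroring the common extract-and-assign workflow); an alternative
  that scales edge-cell counts by their overlap fraction is available via
  `wrnd(..., area_weight_population = TRUE)`.
- *Zero-population villages*: the weighted mean is undefined when
  $\sum \mathrm{Pop} = 0$; the unweighted mean density is returned with a
  `zero-population-fallback` flag rather than an error or NA.

**Distance proxies (EM, EH).** Straight-line distance (km) from the
village centroid to the nearest main road and highway respectively,
computed point-to-polyline with interior projection (the nearest location
may fall inside a segment, not only at vertices). A region with no road of
the requested class yields a flagged missing value, since study regions
genuinely may lack highways. Zero-length segments are dropped with a
warning. For real road data the class mapping is configurable; the default
maps motorway/trunk tags to `highway` and primary/secondary to `main`.

## Indoor/outdoor classification

Personal monitors record one-minute positions and PM2.5; only outdoor
movement periods isolate the traffic-related signal. Classification is a
two-stage rule:

1. **Speed threshold.** Per participant, speed at minute $i$ is the
   displacement from minute $i-1$ divided by the elapsed time; the first
   reading carries the second's speed back. The default threshold is
   **100 m/min** (≈ 1.67 m/s). Thresholds in this area are variously
   quoted in m/min and in m/s (1.5–1.55 m/s); the canonical parameter here
   is in m/min and configurable, and the two conventions differ by ~10%.
   The boundary is inclusive (speed exactly at threshold is outdoor).
   Speeds across gaps longer than 5 minutes (configurable) are treated as
   missing, and missing speeds label the reading *not-outdoor*: the
   conservative direction, since the cost of calling a stationary indoor
   period "outdoor" exceeds the converse for proxy validation.
2. **Building-footprint validation.** Point-in-polygon tests against
   building footprints give an independent label: *indoor* inside or on
   the boundary of any footprint, *outdoor* otherwise — but only within
   the *coverage region* of the building data. The coverage concept keeps
   "no building here" distinct from "no building data here"; outside
   coverage a reading is *uncovered* and keeps its speed-based label.
   Within coverage, the building label is taken as ground truth and
   overrides the speed label; the speed-vs-building confusion matrix is
   reported on the pre-correction labels, with outdoor as the positive
   class.

Both boundary conventions (threshold inclusive; on-edge points indoor) are
fixed for determinism and stated in the function documentation.

## Hexagonal aggregation

Village-level values are averaged over a tessellation of regular flat-top
hexagons with **flat-to-flat width 5 km** by default. "5 km" could equally
denote edge length or spacing; flat-to-flat width was chosen and both the
width and orientation are configurable. Villages join the hexagon
containing their centroid; a centroid exactly on an edge goes to the
lowest hexagon id. Display classes use fixed breakpoints for WRND
(0–10, 10–20, > 20 km/km²) and EM (0–2, 2–4, > 4 km), left-closed and
right-open; EH, which has no conventional scheme, uses data-driven
terciles, and PM2.5 uses quintile indices (the sequential colour ramp
realised as class codes — rendering itself is out of scope). When a
distribution is degenerate (all values equal) all hexagons fall in class 1.

## Association and prediction

**Spearman correlation.** Mid-ranks for ties; the two-sided p-value uses
the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ for $n \ge 10$ and
the exact permutation distribution (all $n!$ permutations) below that.
A constant input makes rank correlation undefined: $\rho = 0$, $p = 1$
are returned with a `constant-input` flag. Correlations are computed at
village level (one outdoor PM2.5 mean per village against its proxies),
per stratum and pooled; no multiple-testing correction is applied, and
raw p-values are starred at 0.05/0.01/0.001.

**Random-forest land-use regression.** `fit_rf_cv()` uses 50 trees,
`mtry = max(1, floor(sqrt(p)))` and 3 folds by default. Observations are
shuffled once with the model seed and split into near-equal folds; headline
metrics (R², RMSE, MAE, MBE) are computed on the *pooled out-of-fold
predictions* rather than averaged across folds (per-fold values are also
retained) — pooling is the less noisy choice at village-level sample
sizes. Feature importances are mean impurity decrease averaged over folds
and normalised to sum to one; they are reported for combined (multi-
feature) models only, where relative attribution is meaningful. The RF
itself is the standard `randomForest` implementation (unlimited depth,
minimum node size 1); no hyperparameter search is performed. The unit of
analysis is the village by default, but any observation table (e.g.
per-reading with village proxies attached) can be passed.

**Bias profiles.** `binned_bias()` bins observations by observed PM2.5
(20 µg/m³ bins from zero) and reports per-bin mean and median bias
(predicted − observed) with a nonparametric bootstrap 95% CI of the mean
(1000 seeded resamples); bins with fewer than 3 observations are flagged.
The bootstrap was chosen over a normal approximation because upper
concentration bins are typically small and skewed.

## The synthetic-data generator

No suitable personal-monitoring dataset is publicly available, so the
generator produces landscapes and traces with known ground truth. It
emulates the *structure* of the real inputs — classed road vectors,
a 100 m clustered population raster, village polygons with interior
centroids, small rectangular building footprints, minute-resolution traces
mixing indoor dwells and outdoor walks — not the marginal distributions of
any particular study region.

The exposure model at position $p$ is

$$\mathrm{PM}_{2.5}(p) = \Big[B + A_t e^{-d_{road}(p)/L_t} + \sum_h A_h e^{-d_h(p)/L_h}\Big]\, e^{\varepsilon}\cdot a^{\,[indoor]},\quad \varepsilon \sim N(0, \sigma_{log}^2)$$

with defaults $B = 15$ µg/m³ (a plausible rural background),
$A_t = 40$ µg/m³ and $L_t = 250$ m (traffic increments decaying over a few
hundred metres, the scale reported for near-road gradients),
indoor attenuation $a = 0.6$, and $\sigma_{log} = 0.3$ (multiplicative
noise of the right order for minute-level optical monitors). The form was
chosen so that both a traffic-dominated distance-decay regime and a
hotspot-dominated regime (non-traffic sources such as agricultural burning
placed away from highways, which *reverses* the sign of the EH–PM2.5
association) are reachable by parameter choice alone. Mobility is episodic
— geometric-length indoor dwells (mean 30 min, position jittered < 2 m
inside the home building) alternating with outdoor walks (mean 12 min,
steps uniform 60–110 m/min, i.e. 1.0–1.8 m/s adult walking speed, with
heading persistence and reflection at the landscape edge). Humidity and
temperature are diurnal sinusoids plus noise, carried but unused
downstream. Positions are generated before concentrations, so trajectories
are invariant to exposure parameters under a fixed seed — which is what
makes monotonicity checks (e.g. raising the traffic amplitude never lowers
an outdoor reading) exact.

`scenario_villages()` packages the two regimes at a fixed design: an
8 × 8 km landscape, two highways, 60 villages, one outdoor walker per
village for 60 minutes. In the distance-decay scenario the traffic decay
length is set to 800 m — of the order of the inter-village spacing, so the
gradient is resolvable *across* villages rather than extinguished within a
few cells; in the hotspot scenario traffic is switched off and three
1200 m-decay sources are placed at sampled points maximising distance from
the highways.

What the generator does **not** emulate: GPS positioning error, traffic
volume or fleet composition, meteorology-driven dispersion, seasonality,
geodetic coordinates, and the monitor's own measurement artefacts beyond
lognormal noise. Passing tests therefore demonstrate that the *pipeline*
is correct and that the statistical machinery recovers known structure;
they do not certify proxy performance on any real population.

## Numerical choices

- Geometry is exact up to floating point: polygon areas by the shoelace
  formula; segment–polygon clipping by parametric intersection with
  midpoint-inclusion tests; polygon–rectangle clipping by
  Sutherland–Hodgman (cells are convex clip windows). Points on a polygon
  boundary count as inside (tolerance 1e-9 m).
- Conservation tolerances: fishnet splitting conserves clipped road length
  to 1e-6 relative; cell–boundary overlap areas sum to the boundary area
  to the same tolerance.
- Near-parallel segment–edge intersections (|determinant| < 1e-12) are
  treated as non-crossing; degenerate (zero-length) segments are dropped.
- All stochastic components (landscape, traces, fold assignment, forests,
  bootstrap) are seeded, and seed handling restores the caller's RNG
  state, so a configuration reproduces its outputs byte for byte.

## Test problem sizes

The shipped tests run the classification-recovery check at 5 participants
× 600 minutes over 20 seeds, the scenario sign checks at 60 villages over
20 seeds, the model comparisons at 150 observations over 20 seeds, and the
geometry oracles at 100 random instances each — sizes at which the
Monte-Carlo margins in the assertions are comfortable while the whole
suite completes in well under a minute per file.

## Known limitations

- Real-data mode expects pre-projected planar inputs; no CRS handling.
- The fishnet inclusion rule and full-count population assignment can
  differ from GIS workflows that area-weight population or use
  centroid-in-boundary cell selection; both choices are explicit and one
  is switchable.
- Hexagon "5 km" is width, not edge length; compare carefully with grids
  produced by other tools.
- The speed rule alone has low sensitivity at walking speeds below the
  threshold; it is designed to be corrected by building validation, and
  uncovered regions fall back to the conservative speed label.
- Spearman p-values for 10 ≤ n ≲ 25 rely on the t approximation, adequate
  at the precision the pipeline reports but not exact.
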
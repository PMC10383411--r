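---
title: "Methods: lodging severity, SAN estimation and risk mapping"
author: "sanlodge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lodging severity, SAN estimation and risk mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanlodge)
```

## Overview

`sanlodge` implements a two-branch field analysis on a shared 1 m mesh:
a *lodging branch* that turns photogrammetric surface models into an
inclination-angle severity map, and a *fertility branch* that turns
bare-soil multispectral reflectance plus point soil chemistry into a
soil-available-nitrogen (SAN) map. A *risk stage* joins the two and
flags each cell against absorbable-nitrogen thresholds. This vignette
records the models, the assumptions behind them, the tunable parameters
and the numerical choices, and what the synthetic test bed does and
does not demonstrate.

## Raster model and zonal statistics

Rasters are square-pixel grids in planar metre coordinates, origin at
the top-left corner, rows southward; pixel (i, j) has its centre at
`origin + ((j − 0.5)·cs, −(i − 0.5)·cs)`. Nodata is `NA` and propagates
through all algebra. Zone membership — for buffer circles at survey and
sampling points and for mesh cells — is decided by the *pixel centre*,
the standard GIS zone-statistics rule; no area weighting is done. Mesh
cells are half-open squares `[x, x+c) × [y, y+c)` anchored at the
boundary's minimum bounding-box corner, so every pixel centre belongs
to exactly one cell. A cell belongs to the grid iff its centre is
inside the boundary polygon, and is an *edge* cell iff its centre lies
strictly within `edgeWidth` of the boundary polyline (Euclidean
distance to the closed polyline). For a W × H rectangle with integer
dimensions and edge width e this makes the inside cells exactly the
(W − 2e) × (H − 2e) interior rectangle; with the reference 55 × 80 m
field and e = 4 m, 3384 inside cells of 4400 — a 76.9% inside share.

On a 5 cm grid a 0.15 m buffer circle contains about 28 pixel centres
(not a fixed 60); buffer pixel counts here always follow the geometry,
and `zonalMeanCircle()` reports the count it used.

## Lodging branch

With DSM the crop surface and DTM the bare terrain:

* `CHM = DSM − DTM`, clamped below at 0 (photogrammetric noise can put
  the surface under the terrain);
* `δCHM = r − y`, r the seasonal-maximum CHM and y the harvest CHM,
  clamped at 0;
* `θ = arcsin(y / r)` in degrees, with `y/r` clipped to [0, 1] before
  the arcsine. The model assumes plant length at harvest equals the
  seasonal maximum, so a falling canopy rotates rather than shrinks.

Pixels with r below `rMin = 0.05 m` are set to nodata: the ratio is
unstable on bare patches, and a 5 cm canopy is not a crop. No bias
correction is applied to the CHM even though photogrammetric canopy
heights typically read low by a few decimetres: an additive bias cancels
exactly in `δCHM` and perturbs θ only modestly, which is within the
tolerance of an 18° class width. `chmVsMeasured()` quantifies the bias
against ground-surveyed heights (0.15 m buffers) for reporting.

Severity levels quantize θ into six classes in 18° increments: level 0
for θ ∈ (72°, 90°], 1 for (54°, 72°], 2 for (36°, 54°], 3 for
(18°, 36°], 4 for (0°, 18°], and 5 only at exactly 0°. The six-level
scale is stated in increments only, so the interval convention
(half-open above, the completely-lodged class reserved for a flat
canopy) is a package choice; both printed anchor statements — levels
4–5 below 18°, levels 0–1 at 55–90° — hold under it. The per-cell level
is computed from the *cell-mean* θ, not the mean of per-pixel levels:
the map answers "how lodged is this square metre", and a mean of
quantized levels would depend on the quantization noise.

## Fertility branch

The feature inventory enumerates, over (green, red, Red edge, NIR) in
fixed order: 4 single bands, 6 pairwise differences, 6 sums, 6 ratios
and 6 NDIs `(Rᵢ − Rⱼ)/(Rᵢ + Rⱼ)` — 28 features. For each soil sample the
four band means over a buffer circle (default radius 0.5 m; 0.15 and
0.25 m are supported for comparison) are computed first and the
features derived from those means. Screening ranks features by absolute
Pearson correlation with the explained soil variable, ties broken by
inventory order; a zero-variance feature is kept with a missing
correlation rather than dropped, so the ranking is always over all 28.

The estimating equation is ordinary least squares of SAN *on* the
selected feature (not inverse regression — the map is evaluated in the
SAN direction), reported with R² and a Gaussian AIC
`n·ln(RSS/n) + 2k`, k = 2, constant terms dropped; only AIC differences
between candidate features are meaningful. Prediction applies the
equation per pixel (fitting uses buffer means; rasterization implies
per-pixel evaluation), propagates nodata, and aggregates to the mesh,
flagging each cell against the agronomic optimum range
(80–200 mg N kg⁻¹ by default).

## Soil-line classifier

Clean bare-soil pixels fall on a line in red–NIR space; residue mixels
sit above it. The classifier is logistic regression of the clean/mixel
label on the four band DNs, `p = 1/(1 + e^−(α + Σ βᵢ Xᵢ))`, fitted by
iteratively reweighted least squares on standardized predictors:
coefficients start at zero, iteration stops when the coefficient change
drops below 1e−8 or after 100 iterations, and a singular weighted
normal system receives a 1e−6 ridge jitter. Coefficients are mapped
back to the original DN scale for reporting. Complete separation —
the *expected* outcome when the two pixel clouds are visually distinct
— is detected by coefficient-norm divergence (or by all fitted
probabilities saturating) and reported as a valid classified result
rather than an error. The decision threshold defaults to p = 0.5 and is
configurable, as is the training labelling: labels can be supplied, or
derived by fitting a provisional red–NIR line on all pixels and
splitting its NIR residuals by 2-means with centres initialised at the
residual extremes (deterministic). The soil line itself is OLS of NIR
on red over the clean class, with its residual RMSE as the tightness
measure.

## Risk stage

The lodging and fertility mesh tables join on cell id; cells missing
either value are dropped and counted. The SAN–θ relationship (Pearson r
and the OLS line of θ on SAN, matching the axes the relationship is
usually plotted on) uses *inside* cells only: the edge strip lodges
from transplanter fertilizer overlap regardless of SAN and would dilute
the correlation. Fertilizer N converts to a tillage-layer concentration
as `rate / (10 · depth · bulkDensity)` (70 kg N ha⁻¹, 0.1 m, 1.0 Mg m⁻³
→ 70 mg N kg⁻¹), absorbable N is the sum of the SAN estimate and that
concentration, and each cell gets independent flags:
`lodging_possible` at SAN ≥ 140 mg N kg⁻¹, `above_guideline` at
absorbable N ≥ 200 mg N kg⁻¹, and `edge_caution` for edge cells — kept
separate because edge lodging is an application artefact, not a soil
property. Both thresholds are parameters: the onset is read off the
observed scatter, not estimated by a change-point procedure, and is
field-specific.

## Synthetic field generator

The generator emulates the survey a real campaign would deliver, driven
by one latent SAN surface so every downstream statistic has a known
truth.

* **Latent SAN** — a deterministic trend (higher north and centre,
  lower south) plus a spatially correlated component, clipped to
  `sanRange` (78–200 mg N kg⁻¹). The correlated part is bilinear
  interpolation of a white-noise lattice with spacing equal to
  `sanCorrelationLength` (10 m, sd 20 mg N kg⁻¹). A lattice field was
  chosen over moving-average smoothing of per-pixel noise because it is
  a single well-defined function of (x, y): the band grid (0.051 m),
  the elevation grid (0.05 m) — deliberately non-coincident, as the two
  sensors' ground sample distances differ — and the point samples all
  see the *same* truth. When the correlation length does not exceed the
  cell size the field degrades to i.i.d. pixel noise.
* **Bands** — the green−red difference inverts the estimating relation,
  `green − red = (287.86 − SAN)/0.046` plus per-pixel noise
  (sd 50 DN), so the printed coefficients are recoverable from
  noise-free samples. Red carries a weak SAN coupling (−8 DN per
  mg N kg⁻¹ around a base of 8500) plus a smooth additive
  soil-brightness field (sd 2000 DN) shared with green: brightness
  cancels exactly in the difference and shifts clean NIR *along* the
  soil line `NIR = 2000 + 1.2·red`. Red edge co-varies with green, and
  Red edge and NIR each carry their own smooth idiosyncratic component
  (0.8× and 0.25× the brightness sd). These choices reproduce the
  correlation structure observed on real bare-soil scenes — the
  difference is by far the strongest SAN proxy, while ratios, NDIs and
  every Red-edge/NIR combination are heavily diluted by brightness and
  band-specific variation. A `residueFraction` (10%) of mixel pixels
  gets an NIR lift of 2500 + |N(0, 800)| DN and half of it in Red edge.
  The DN scale itself is arbitrary; it is fixed so the estimating
  equation's printed coefficients are self-consistent.
* **Canopy** — the terrain is a plane at 4.7 m sloping 0.15° (north end
  higher); maximum canopy height grows linearly from 0.5 to 0.7 m
  across the SAN range. The lodging response is a stand-in, not a
  mechanistic model: θ = 90° below the onset SAN (140 mg N kg⁻¹),
  falling linearly to 10° at the top of the range, with a 4 m edge
  strip capped at 15° regardless of SAN; surface models get 0.03 m
  noise.
* **Samples** — 20 + 15 points on a jittered grid, measured SAN =
  latent SAN at the point + N(0, 8) noise; total carbon ~2% and total
  N ≈ TC/11.5 with a weak positive SAN link, mimicking the weak
  chemistry–band correlations of real tables.

Determinism: every stochastic component draws from its own seed derived
from `cfg@seed` (offsets 101–505), so each generator stage is
individually reproducible and the caller's RNG state is untouched.

**What passing tests show — and don't.** The synthetic field has
Gaussian noise, a linear band–SAN link, a piecewise-linear lodging
response and cleanly separable mixels. Real surveys add radiometric
calibration error, moisture-driven reflectance shifts, SfM artefacts,
heteroscedastic chemistry and lodging driven by weather as much as by
nitrogen. Tests passing on the synthetic field validate the *pipeline's
arithmetic and statistics* (oracle-equal zonal statistics, coefficient
recovery, sign and bookkeeping of the correlation), not the agronomic
transferability of any threshold.

## Numerical choices and degenerate inputs

* Raster alignment requires identical shape, origin and cell size to
  within 1e−9 m; anything else is an error, never a silent resample.
* Negative CHM and δCHM clamp to 0; `y/r` clips to [0, 1]; θ outside
  [0°, 90°] is rejected.
* Empty buffer circles and single-class logistic labels are errors that
  name the offending sample; a constant explained variable, a
  zero-variance feature and a constant θ are reported as such rather
  than returning NaN statistics.
* ASCII-grid I/O writes 17 significant digits, so round trips are
  bit-exact; the nodata sentinel is chosen below the data minimum.
* Ties in screening are broken by the fixed inventory order, making the
  ranking deterministic.

## Problem sizes used by the test suite

Unit and property tests run on a 20 × 28 m field at 0.2 m grids (the
statistical structure is scale-free in the mesh sense: the closed-form
inside fraction, parameter recovery and correlation signs hold at any
extent), with oracle comparisons up to 200 × 200-pixel rasters and
20-seed replication for the stochastic properties. The acceptance
script runs the full 55 × 80 m reference field at the native 0.051 m
band and 0.05 m elevation grids.

## Known limitations

* No reprojection, multi-band rasters or area-weighted zonal
  statistics; inputs must share one planar metre frame.
* The SAN model is a single regression by design; multi-feature or
  nonlinear regressors are out of scope.
* The lodging onset and absorbable-N guideline are configurable
  constants, not estimated quantities; transfer to other fields,
  varieties or seasons needs local calibration.
* The synthetic lodging response θ(SAN) is a labelled stand-in for an
  unknown field response; only its sign structure (more nitrogen, more
  lodging, edge strip lodged) is asserted anywhere.
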
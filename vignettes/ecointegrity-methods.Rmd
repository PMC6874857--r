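---
title: "Methods: threat surfaces, the ecological integrity index, and cross-validated model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threat surfaces, the ecological integrity index, and cross-validated model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecointegrity)
```

## The problem this package addresses

Freshwater conservation planning over large watersheds rarely has the
budget to measure river condition in the field everywhere. A common
surrogate is the *anthropogenic threat map*: a raster in which every pixel
carries the summed, distance-decayed impact of nearby human activities
(settlements, mining, agriculture, power plants, oil infrastructure, water
users, roads). Whether such maps actually track the ecological condition
of rivers is an empirical question, answered by regressing an in-situ
*Ecological Integrity Index* (EII) on the mapped threat values and
checking how well the fitted models predict held-out sites.

`ecointegrity` implements that whole chain as a tested pipeline: threat
surface construction, EII scoring from field tables, Moran's I screening,
microbasin aggregation, all-subsets model selection under AICc with
collinearity exclusion, repeated k-fold cross-validation, and prediction
mapping — plus a seeded synthetic-landscape generator so every stage is
testable without the (undistributed) original field and GIS data.

## Threat surfaces

Each threat category has a magnitude of impact $m \in (0,1]$ and a maximum
impact distance $D$ (meters). A feature contributes

$$ i(d) = m\,\bigl(1 - d/D\bigr)_+ $$

at Euclidean distance $d$ from its geometry (edge distance for lines and
polygon boundaries; $d = 0$ inside polygons). Surfaces are evaluated at
pixel centers on a square grid (default pixel 500 m, i.e. ~0.25 km²).
Overlapping buffers add; the default `"cap"` policy truncates sums at 1 so
pixel values keep the absolute interpretation of the registry magnitudes.
A `"rescale"` policy (divide by the global maximum when it exceeds 1) is
available — the published workflow says only that summed overlaps were
"scaled between zero and one", so the choice is ours; capping was chosen
because it does not let a single crowded neighbourhood rescale the whole
basin.

Two registry rules are interpretations rather than published constants,
and both are overridable in the registry file:

* **Hydroelectric impact distance** is published as "scaled to plant size"
  with a 30 km maximum and no formula. We use
  $D = 30\,\mathrm{km} \times m / 0.375$ — linear in the category
  magnitude, with the largest operating class at the cap.
* **Settlement population-density scaling** is published alongside fixed
  per-category magnitudes (0.65 urban, 0.35 village); we default to the
  fixed magnitudes. Aquaculture farms and water withdrawals scale their
  magnitude linearly from the observed water-volume range onto
  [0.1, 1], as published.

## The Ecological Integrity Index

The EII of a site is the mean of three components, each itself the mean of
parameters scaled to $[0,1]$ with 1 = reference condition:

* **Biotic**: a BMWP-style family-tolerance index (the sum of tolerance
  scores over distinct benthic macroinvertebrate families present) and its
  richness-standardised form, average score per taxon (ASPT). Higher
  values mean more pollution-sensitive families, so these scale without
  inversion. The published regional tolerance list is not redistributed
  here: the tolerance table is a required input
  (`synthetic_tolerance_table()` ships for testing).
* **Habitat**: riparian-quality (QBR-Am) and fluvial-habitat (IHF-Am)
  field indices, consumed as raw scores against declared maxima (default
  100 each); the field scoring sheets are out of scope.
* **Physical-chemical**: absolute deviations of pH, conductivity,
  dissolved oxygen and temperature from reference values, inverted so that
  sitting at reference scores 1. Reference values and deviation bounds
  default to plausible Andean-Amazon stream values (pH 7.0, 150 µS/cm,
  8 mg/L, 18 °C) because the published ones live in an unreleased
  supplement; they are global (not elevation-banded) and overridable.

Normalisation is min–max against empirical bounds across the site set by
default, or fixed bounds from configuration. A constant parameter column
carries no evidence of impairment and maps to 1.0 with a warning ("benefit
of the doubt"). Besides the arithmetic mean, a biology-weighted variant
(weights 2:1:1 for biotic:habitat:physical-chemical) is computed; the two
obey the exact identity
$\mathrm{EII}_{arith} - \mathrm{EII}_{wt} = (h + p - 2b)/12$,
which the tests assert per site.

## Modeling

All predictors — the nine threat values and, in the environmental
scenarios, elevation and slope — enter min–max scaled to $[0,1]$.
"Gaussian GLM" fitting is ordinary least squares (the identical
estimator), with the Gaussian log-likelihood evaluated at the MLE variance
and

$$ \mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}, $$

where $k$ counts intercept, slopes and the variance parameter. Candidate
models are all predictor subsets up to a size limit (7 at the local scale,
2 at the microbasin scale, where $n$ is only a few dozen), excluding any
subset containing a pair with $|r| > 0.7$ (screened once on the full data,
not per fold). Ties in AICc break toward fewer terms, then
lexicographically — the published workflow is silent on ties, so a
deterministic rule was invented. The full AICc table is retained for
sub-optimal-model reporting.

Predictive performance is repeated k-fold cross-validation (default 7
folds × 20 repeats): each repeat randomly partitions sites into
near-equal folds (sizes differ by at most 1 — exact equality is impossible
at n = 140 or 29), refits the selected subset on k−1 folds and scores the
held-out fold. Held-out $R^2$ is the squared Pearson correlation between
observed and predicted (the convention of the standard CV tooling); the
$1 - SSE/SST$ variant is available as an option. The four scenarios are:
(a) local ~ threats, (b) local ~ threats + environment, (c) microbasin ~
threats, (d) microbasin ~ threats + environment. Scenarios c and d run
independently even when they end up selecting identical models.

For the regional scale, sites map to microbasin polygons by point-in-
polygon (even-odd rule; pixel centers decide zonal membership — the
published workflow does not state an inclusion rule); the response is the
mean EII over member sites and predictors are zonal means over pixels.
Moran's I uses inverse-distance weights with zero diagonal and no row
standardisation by default (the common desktop-GIS default), with the
normality-assumption variance for the Z score and a randomisation variant
available.

## The synthetic world: what it does and does not establish

`generate_landscape()` draws a seeded landscape whose statistical
structure matches what the analysis assumes:

* A 40 × 40 km grid of 500 m pixels. The default feature mix is
  calibrated so relative threat footprints match what is reported for
  Andean-Amazon basins: agriculture the most widespread (~half the basin),
  settlements ~a fifth (one city, many villages), mining ~15%, oil ~10%,
  power plants and water users spatially limited. The grid is deliberately
  large enough that individual buffers stay local features; on toy-sized
  grids a single 10 km urban buffer becomes a basin-wide gradient and
  produces spurious |r| > 0.7 collinearity with the terrain, which the
  real basin does not show (its best model contains settlements,
  elevation and slope jointly, which the screening would have forbidden).
* Elevation descends ~3,000 m across the grid along a concave profile
  (steep highlands flattening into lowlands), giving the moderate
  positive elevation-slope correlation (~0.5) of real mountain-to-
  floodplain basins; slope is central finite differences on the pixel
  lattice.
* 140 river sites, placed the way such studies place them: half spread
  uniformly, half deliberately covering the anthropogenic pressure
  gradient (within a random feature's impact buffer) — purely uniform
  placement undersamples spatially rare threats like oil infrastructure
  and makes their published effects unidentifiable at n = 140. True EII is
  $\beta_0 + \sum_j \beta_j x_{ij} + \varepsilon_i$,
  $\varepsilon \sim N(0, \sigma^2)$, clamped to $[0,1]$ afterwards with
  the clamp count logged (the real index is bounded by construction, and
  clamping is rare — <1% of sites under the defaults). Predictors are the
  sampled surfaces min–max scaled over the *basin-wide* range — the same
  0-1 convention the fitted models use, and scaling by the grid rather
  than the sample keeps sampled sites off the exact extremes.
* Default $\beta$ takes the signs and magnitudes of the published
  local-scale model (settlements −0.165, roads −0.121, oil −0.136,
  elevation −0.176, slope +0.199, intercept 0.762). The residual standard
  deviation is not published; by default $\sigma$ is calibrated at
  generation time so the analytic signal fraction
  $R^2 = \mathrm{var}(X\beta)/(\mathrm{var}(X\beta) + \sigma^2)$ equals
  0.25, the weak local-scale regime of the study; recovery experiments use
  0.5.

A green test on this world establishes that the pipeline's estimators and
selection machinery behave correctly under the model the analysis assumes
— linear effects, Gaussian noise, spatially random residuals. It does
*not* establish anything about real rivers: the generator has no river
network topology, no spatially autocorrelated error field (the study found
integrity spatially random, and reproducing its Moran Z = 1.55 would
require the unreleased site coordinates and weight scheme), no non-linear
stressor-response forms, and its physical-chemical reference values are
package defaults rather than the published supplement.

`simulate_site_parameters()` inverts the scoring pipeline for round-trip
tests: given target component scores it constructs 10-family assemblages
whose mean tolerance tracks the target ASPT (granularity 1/90 on the
biotic score, well inside the 0.02 round-trip tolerance), habitat raw
scores, and reference-offset water chemistry, together with the fixed
normalisation bounds under which the round trip is exact. Constant
richness keeps a single fixed bound valid for the summed biotic index
across sites.

## Numerical choices and degenerate inputs

* Pixel lookups use the containing pixel, with boundary points pulled to
  the nearest pixel; sites outside the grid are an error, never silently
  dropped.
* Constant predictors (e.g. a threat with no features) are dropped from
  the candidate set with a warning; a constant response makes Moran's I
  and CV meaningless and errors.
* Coincident points under inverse-distance weights get a 1 m distance
  floor.
* All randomness flows from named seeds; identical config + seed
  reproduces byte-identical serialized outputs (coordinates that round
  trip through decimal GeoJSON text can differ by 1 ulp between the
  in-memory and file route; replaying a stage from the same files is
  exact).
* File formats are plain text throughout: GeoJSON for vectors, ESRI ASCII
  grid for rasters, CSV for tables, JSON for config and manifests. (No
  GeoTIFF/shapefile dependency exists in this environment; the ASCII grid
  carries the identical grid metadata.) One planar projected CRS per run;
  no reprojection.

## Known limitations

Radial buffers only (no downstream routing of impacts); no temporal
change; family-level biotic index only; no model averaging or spatial
regression. The microbasin scenarios inherit whatever polygons they are
given — the hydrological delineation itself is out of scope, and the
rectangular tiling generator used in tests is a spatial stand-in, not a
drainage model.
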
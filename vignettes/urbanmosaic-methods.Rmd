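---
title: "From tagged features to occupancy models: the urbanmosaic methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tagged features to occupancy models: the urbanmosaic methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanmosaic)
```

Global land-cover products typically collapse whole cities into a single
"built" class, which makes them nearly useless for urban wildlife questions:
a raccoon does not experience a golf course, a six-lane motorway and a
residential block as the same habitat. `urbanmosaic` rebuilds that missing
heterogeneity from community-mapped geographic features — polygons and lines
carrying key–value tags in the OpenStreetMap vocabulary — and carries the
result through to ecological inference: a 28-class 30 m land-cover raster, an
urbanization index, and autologistic occupancy models for camera-trap data.

This vignette is the package's own account of how each step works, which
knobs matter, and where the genuinely open design choices were made.

## The classification framework

Features are classified by an editable **rule registry**
(`default_registry()`): 27 classes in three categories — human land use
(residential, commercial, industrial, institutional, recreation, cemetery,
construction sites, agriculture), green cover graded by the shelter it offers
(protected-unknown, forest, low vegetation, open green, plus barren and
water), and infrastructure (buildings, parking, and the linear classes:
motorway down to service road, paths, railways, fences, linear construction).
Class 28, *developed unknown*, is reserved for cells the global product calls
built but for which no detailed feature exists.

Three codes play diagnostic roles and are pinned: 7 (vegetation under
protection whose type is unknown), 17 (roads whose type is unknown), 26
(linear features under construction or abandoned). Together with 28 they
drive the completeness diagnostics: a large share of any of them means the
source database lacks the attribute detail the subcategorization needs.

The published supplementary tag tables behind the original 27-class scheme
are not bundled; the default registry is a documented reconstruction that
preserves the categories, the diagnostic codes and the priority narrative.
Because the registry serializes to YAML (`write_registry()`), a user holding
the published tables can substitute them without touching code.

A feature may satisfy several rules (a tagged building inside a park belongs
to both the buildings and the open-green class). Classification is therefore
deliberately multi-membership; conflicts are resolved later, on the raster,
by priority — not by vector precedence. This mirrors how the overlay is
meant to work and makes classification order-independent, which the test
suite asserts by shuffling inputs.

## Buffering, rasterization, priority merge

Linear features become polygons before rasterization. Roads get a total
width of **6 m per lane**; the lane count comes from the feature's `lanes`
tag when parseable and otherwise from a per-type mean (motorway 4, primary 3,
secondary/tertiary/residential/unknown 2, service 1 — editable in the
registry). Paths (2 m), railways (6 m) and fences (1 m) use fixed widths.
Buffers are flat-capped rectangles per segment with round joins at vertices;
for a straight segment the area is exactly width × length, which the tests
use as an oracle.

Rasterization uses **cell-center containment** at 30 m: a cell takes a class
iff its center lies inside some polygon of that class. This matches the
default of the common raster engines, and has a documented consequence: a
12 m road crossing 30 m cells away from their centers can paint no cells at
all. The fixture tests quantify this rather than hide it — the synthetic
city deliberately places its road centerlines on the cell-center lattice so
every road paints a strip, and the test geometry places buffer edges off the
center lattice so containment is never ambiguous at floating-point level.

The per-class masks are merged by a strict priority ranking (higher rank
wins the cell): land use lowest, then green cover, then barren and water,
then buildings and parking, then roads in ascending traffic order, and
hiking paths, railways and fences above everything — these run uninterrupted
across landscapes and act as corridors or barriers for wildlife, so they
must not be severed by overlaps. Elevated segments (bridge/tunnel tags) can
be excluded from their road layer so they do not overwrite the habitat
beneath; this is a declared stand-in for a procedure the source framework
leaves unstated. The merge is exactly reproducible tile by tile
(`tile_and_merge()`), so arbitrarily large areas can be processed piecewise
with bit-identical output — an invariant the acceptance tests check over
random stacks and tile sizes, including tiles larger than the grid.

Cells still empty after the merge are backfilled from a reclassified global
raster (`reclass_global()` + `integrate_global()`); built/developed global
codes map to class 28 so missing detail is never mistaken for known land
use. Global rasters on a different grid are aligned by nearest neighbor
only — categorical data cannot be interpolated.

## Validation

`completeness()` reports the fraction of cells the detailed map covers
before backfill, the per-class absolute area difference against the global
picture (plus a normalized `min(1, detail/global)` ratio for cross-city
comparability — both are emitted because the absolute difference alone is
scale-dependent), the area share of codes 7/17/28, and the urban proportion
(land-use + infrastructure + developed-unknown area over total).

Accuracy assessment follows the stratified-points design:
`stratified_sample()` draws up to *n* cells per class without replacement
(classes with fewer cells are exhausted, classes absent from the raster are
absent from the sample), `confusion()` tallies predicted × reference counts
with **predicted on rows** — fixed so that the row-normalized diagonal is
per-class precision, "how often does this class correctly describe the
ground" — and `kappa_statistic()` gives chance-corrected agreement. The
number of points per class is a user parameter; the original assessment's
per-class breakdown of its 2,123 points is not published. Building-area
comparisons across cities use plain OLS (`area_regression()`), reference
areas on the response side.

## The urbanization index

The index is an arithmetic weighted sum on the 30 m grid of four components,
each in [0, 1]:

* shelter-weighted vegetation: `(3·P_forest + 2·P_lowveg + 1·P_open)/6`,
  focal proportions in a **900 m** window (3:2:1 reflects the shelter each
  type offers wildlife);
* building proportion in a **450 m** window (the common 500 m-radius
  occupancy scale);
* proximity to major roads and railways (1 − min–max-normalized distance);
* proximity to water.

The source description gives the vegetation ratio, the window sizes (its
"900 m²/450 m²" are read as window side lengths — the stated aggregation
factor of 30 on a 30 m grid yields exactly 900 m blocks, so the squared unit
is taken as a typo), the 0–1 distance normalization and the phrase
"arithmetic weighted sum", but not the component weights or signs. Those are
therefore explicit configuration (`index_config()`), with defaults chosen so
the index rises with urban intensity: vegetation −1, buildings +1, road
proximity +0.5, water proximity −0.25 (water access reads as habitat
quality, hence "less urban"; the sign is configurable because the source
leaves it open). The tests pin down the *contract* — strictly increasing in
buildings, decreasing in vegetation under the configured signs, bounded by
the weight sums — never the default numbers themselves.

Focal proportions use block aggregation (factor = window/cell) followed by
block-constant disaggregation; edge blocks use the cells actually present.
Distances are exact Euclidean distances between cell centers, computed with
the separable parabolic-envelope distance transform, and `normalize01()`
maps the observed minimum and maximum to exactly 0 and 1 (a constant
distance field has no defined normalization and errors). By default the
theoretical index range implied by the weights is mapped affinely to
[0, 100]; this is presentation only, and `output_scale = "identity"`
disables it.

## Occupancy models

Camera-trap records (`site, season, week, detected`) become site × season ×
week arrays; unsampled weeks are `NA` and are skipped as missing-at-random
(real seasons run 1–7 weeks). `naive_occupancy()` reports the per-season
fraction of sites with ≥ 1 detection, the standard uncorrected summary.

The model is the first-order autologistic reduction of a dynamic occupancy
model. With site covariate *x*:

* season 1: `psi_1 = invlogit(beta0 + beta1 x)`;
* season *t* > 1: `psi_t = invlogit(beta0 + beta1 x + theta z_{t-1})`, where
  `z_{t-1}` is the previous season's latent occupancy;
* detection: weekly Bernoulli(`p z_t`), `p = invlogit(alpha)`,
  intercept-only by default since no detection covariates are named.

`loglik_autologistic()` marginalizes the latent chain exactly with a scaled
forward algorithm (vectorized over sites; per-site-season sufficient
statistics make each evaluation cheap). The first season carries no
autologistic term — there is no prior state. The suite verifies the
likelihood against exhaustive latent-state enumeration at tolerance 1e-10,
against independent-season products at `theta = 0`, and checks it is a
proper distribution (site likelihoods sum to 1 over all possible histories).

`fit_autologistic()` maximizes by BFGS from five documented starts (zeros
plus four seeded uniform perturbations in [−1, 1], guarding against the
occasional flat start), keeps the best finite optimum, and reports
observed-information standard errors; non-convergence is flagged, never
silent. A single season is refused by name: `theta` is not identified.
`compare_aic()` ranks models by AIC with Akaike weights and cumulative
weights, flagging models within 2 ΔAIC as competitive.

`occupancy_ratio()` compares expected occupancy between two covariate
values. "Expected occupancy" is defined as the stationary probability of
the two-state chain, `pi = psi0 / (psi0 + 1 − psi1)` with
`psi0 = invlogit(x'beta)`, `psi1 = invlogit(x'beta + theta)` — the long-run
simulated occupancy, which the tests confirm by forward simulation; at
`theta = 0` it reduces to the plain logistic ratio. A self-consistent
("mean-field") fixed point `psi = invlogit(x'beta + theta psi)` was
considered and rejected because it disagrees with the long-run behavior of
the generative chain whenever `theta` is nonzero.

## What the synthetic data does and does not emulate

`generate_city()` builds a gridded city: a road lattice with cycling road
types (lane tags present, absent, or unparseable, to exercise imputation), a
land-use/green mosaic over blocks, buildings and parking on slots inside
developed blocks, a water body, one specimen feature per registry rule
(so the registry-coverage test is exact), one unclassifiable feature, and —
critically — a ground-truth raster computed by **interval arithmetic on the
placement table**, a code path disjoint from the classify/buffer/ray-cast
pipeline. Agreement between the two is the framework's primary correctness
surface and holds cell-for-cell on the default 200 × 200-cell city
(~390 features).

A share of blocks (default 8%) is left void: their true class is drawn and
recorded in a separate full-coverage `reference` raster but no feature is
emitted. This creates honest voids for the completeness and integration
invariants, and gives the accuracy machinery something real to measure: the
integrated map errs exactly where the global backfill guesses a withheld
class. Defaults (600 m blocks, 30% building-slot occupancy, 20% green
fraction) were chosen once as a plausible mid-density city mosaic.

What the fixtures do *not* emulate: curved or diagonal roads (the interval
ground truth needs axis-aligned shapes), multipolygon relations with holes,
tagging noise beyond the planted unparseable lane values, and any spatial
correlation between the synthetic global raster and the city (the global
product is an independent random field with a built core). Passing tests
therefore demonstrate the correctness of the machinery, not the accuracy of
any real-world tag vocabulary.

`generate_global_lulc()` thresholds smoothed random fields, pinning the
built-class fraction exactly (up to ties) and concentrating it at the
extent center. `simulate_detections()` draws from the autologistic model
itself; the simulation-recovery study (100 sites × 4 seasons × 6 weeks,
`beta = (−0.5, 0.8)`, `theta = 1`, `alpha = 0.5`) shows nominal-level Wald
coverage and decisive AIC preference for the covariate model at that effect
size. Those problem sizes — 200 replicates in the test suite, 60 in the
acceptance script — were chosen to keep Monte-Carlo error on coverage below
about two percentage points while the whole suite stays comfortably fast.

## Numerical choices and degenerate inputs

* Raster nodata is 0; framework codes are 1–28. A legend colliding with the
  nodata code is refused at construction.
* Geometry lives in one projected, meter-unit CRS; geographic (degree)
  inputs are rejected with a message rather than silently reprojected,
  because buffering in meters is meaningless in degrees.
* Degenerate rings (< 4 vertices or zero area) are dropped during repair;
  features with nothing left are dropped with a warning. Zero-length lines
  are dropped at buffering, with a warning.
* The distance transform stores "no site" as a large finite value (1e12)
  rather than infinity — the parabola-intersection step would otherwise
  produce NaN.
* Kappa's degenerate single-class case (`p_e = 1`, `p_o = 1`) returns 1 by
  convention. Precision for a never-predicted class is `NA`, not 0.
* `area_regression()` refuses fewer than 3 points or zero-variance
  predictors; a constant response yields slope 0 and R² 0.
* Ties in the merge cannot occur (ranks are unique by construction); ties
  at the built-fraction threshold of the synthetic global raster are
  resolved deterministically.

## Known limitations

Vector output of the classified map is out of scope (the product is the
raster). Stacked infrastructure is flattened by priority — a park under an
overpass is an overpass, unless the segment is flagged elevated. GeoJSON
parsing accepts the common single- and multi-part geometries but not
relation assembly from raw members. The occupancy machinery is
maximum-likelihood only (no Bayesian fitting) and assumes no spatial
autocorrelation between sites.
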
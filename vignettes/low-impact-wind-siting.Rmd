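---
title: "Methods: low-impact wind siting on disturbed lands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-impact wind siting on disturbed lands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windsift)
```

## The model

`windsift` formalizes a siting heuristic: wind development has low
incremental impact on wildlife where the land is already disturbed, the
wind resource is economically viable, and no overriding wildlife
sensitivity applies. All computation happens as boolean mask algebra on a
shared projected, meter-unit, equal-area grid; the low-impact mask is

\[
L = \mathrm{filter}(D) \wedge V \wedge \neg E \wedge \neg P \wedge
\neg U \wedge \neg W
\]

with `D` the disturbance footprint, `filter` the patch-size/isolation
filter, `V` wind viability, `E` the compiled wildlife exclusions, `P`
GAP 1–2 protected areas, `U` urban cores and `W` water/wetland cover.
Capacity follows as a per-cell lookup by wind power class.

The underlying assumptions are worth stating plainly. First, disturbance
is treated as a one-way valve: land mapped as cropland, developed, mined
or oil/gas field is assumed to have lost most of its value for the
species of concern, so adding turbines there is "low impact". Second,
wildlife sensitivity that survives disturbance (a crane stopover on
cropland, high waterfowl pair density) is handled by explicit exclusion
rules that override the disturbance signal. Third, capacity scales
linearly with area at a class-specific density — a planning-level
approximation that ignores parcel shape, setbacks and transmission.

## Pipeline stages and parameters

**Disturbance footprint.** Six sources are OR-ed together
(`disturbanceMask()`), each a mask in its own right:

* *Land cover*: codes 82, 21–24, 81 of the NLCD-style schema
  (`landcoverSchema()`) are disturbed. The schema and code set are
  configurable; hay/pasture is included, natural grassland is not.
* *Impervious surface*: any mapped impervious fraction (strict threshold,
  default 0) counts as disturbed.
* *Topographic change*: per-cover thresholds, constrained to
  10.21–17.57 m, flag surface mines and similar engineered relief.
* *Well fields*: a quartic (biweight) kernel density of well points,
  in wells/km². The kernel has finite support equal to its bandwidth
  (default 1,000 m), which makes the density an exact finite sum — every
  value is reproducible by direct summation, which the tests exploit. The
  default threshold is 1 well/km². Bandwidth and threshold are genuinely
  free parameters of the method: the source analyses cite a kernel
  density without fixing either, so both are required configuration with
  documented defaults.
* *Linear infrastructure*: roads/pipelines/rail/transmission are
  rasterized by an exact supercover traversal at 30 m sub-cells; an
  analysis cell is disturbed if any of its sub-cells is crossed. This
  "any hit" aggregation is deliberately conservative (inclusion-biased).
* *Settlements*: hamlet points buffered by 300 m (cell-center distance).

**Patch filter.** Connected components of the disturbed mask are labeled
(default 8-connectivity; 4 is available) and a patch is dropped iff its
area is below 1 km² *and* its minimum cell-center distance to any patch
of at least 1 km² exceeds 800 m. Three conventions had to be fixed where
the procedure is otherwise ambiguous, and are chosen for reproducibility:

* 8-connectivity by default, which merges diagonal neighbors and is the
  more conservative (more-retaining) choice;
* distances between *cell centers*, not polygonized patch edges — simple,
  unambiguous, and exactly reproducible by a brute-force all-pairs scan;
* patches of exactly 1 km² are retained and serve as anchors (the
  "≥" reading of the area threshold).

**Wildlife exclusions.** Each jurisdiction is a declarative `RuleSet` of
`ExclusionRule`s (YAML on disk, `inst/rulesets/`): operators
`polygon_burn`, `category_at_least`, `category_in_set`,
`density_at_least`, `point_buffer`, `line_buffer` and
`repeated_stopover_buffer`. Composition is a union, so rule order is
irrelevant and every contributing rule id lands in the mask's provenance.
Notable parameter choices:

* *Waterfowl*: pair density ≥ 104 pairs/km² (boundary inclusive, per the
  "or greater" phrasing).
* *Crane stopovers*: observations are clustered into sites by
  single-linkage within a configurable radius (default: one cell). A site
  qualifies if its observations span ≥ 2 calendar years or ≥ 3 distinct
  days within one year; qualifying sites are buffered by 3.2 km.
  Observations-to-sites clustering is our construction — the rule is
  stated over "sites" without defining them operationally.
* *River corridors*: 1.6 km buffers around lines whose `name` attribute
  matches the designated migratory rivers (an attribute filter, so the
  same mechanism serves any named-feature subset).
* *Sensitivity scales*: for the Nebraska-style 1–6 ranking, "the four
  most sensitive categories" is read as {3,4,5,6} (6 = most sensitive);
  for Montana-style 4-class layers the top two codes are excluded. The
  numeric orientation of such layers is a data convention, not a fact the
  method can infer, so category sets are explicit in the YAML and can be
  inverted per layer.

**Suitability and capacity.** Wind power class ≥ 3 (≥ 6.4 m/s at 50 m)
is viable; the boundary is inclusive. Capacity densities are a printed
lookup — WPC 3: 4.3, 4: 4.8, 5: 5.2, 6: 5.5, 7: 6.0 MW/km²; the 5 MW/km²
at 44.5% capacity factor reference is carried as metadata only, because
per-class capacity factors are not available to re-derive the table.
Percent-of-goal is computed from unrounded GW and then rounded half away
from zero; the Total row sums goals and GW before dividing. This is the
only scheme consistent with most of the published regional rows
(e.g. 139/5.26 → 2643%); two rows (Alberta, Wyoming) only reproduce from
unrounded GW inputs, which we document rather than assert.

**Turbine audit.** A turbine takes the value of the mask cell containing
it under a half-open convention (a cell owns its top and left edges), so
boundary points classify deterministically. Out-of-bounds points are
flagged and counted as not low-impact, with a warning, rather than
dropped.

## Numerical conventions

* Nodata semantics differ by role: in a union of disturbance sources, a
  missing value contributes 0 and a cell is nodata only if *all* sources
  are missing; in the candidate intersection, missing disturbance or
  viability makes a cell non-candidate, while missing exclusion data
  means "not excluded". Low-impact cells with missing wind class
  contribute 0 GW and are counted and reported.
* All distances are Euclidean in the projected plane, on cell centers.
* Grids must share georeferencing exactly; a nearest-neighbor regrid
  (`regridNearest()`) is provided for wind layers delivered at other
  resolutions (200 m US, 5 km Canadian pixels).
* Connected-component labeling is iterative minimum-label propagation;
  its fixed point is the component partition regardless of iteration
  order, and it is verified against an independent flood fill and an
  external image-labeling routine in the tests.

## The synthetic-landscape generator

No real input layers ship with the package; `generateLandscape()` builds
all of them with controlled statistical structure:

* *Land cover* is a smoothed Gaussian random field thresholded at the
  quantiles of the target class proportions — contiguous, NLCD-like
  patches with class fractions matching the targets up to the ±0.05
  realization noise we test for at 256×256.
* *Wind power class* discretizes a second, much smoother field
  (correlation length 5 km by default, reflecting the coarse resolution
  of gridded wind atlases).
* *Wells* follow a Thomas cluster process (default 500 wells, 2 km
  cluster spread): clustered like real oil/gas fields, and demonstrably
  more aggregated than a uniform process of equal intensity.
* *Crane observations* are generated on a jittered lattice of sites with
  per-site observation patterns covering both qualifying clauses of the
  stopover rule and near-miss negatives, with ground-truth labels shipped
  alongside — the rule's recovery of those labels is part of the
  acceptance suite.
* Rectangular priority/protected/sensitivity/urban polygons, crossing
  roads and named rivers, hamlets, and uniformly placed turbines with
  `existing`/`proposed` status complete the layer map. Development goals
  are scaled to the window area at roughly the regional goal intensity
  (~30 GW per 1.5M km²).

One master seed drives independent per-layer substreams (fixed offsets),
so changing one layer's parameters does not perturb another layer's
realization — a property the tests assert. Defaults describe a 25.6 km
window at 100 m resolution in a cropland-dominated northern-plains
setting (45% cropland, 30% grassland, 8% hay/pasture, smaller shares of
shrub, wetland, water, forest and developed cover).

What the generator does *not* emulate: real geography (actual state
boundaries, river networks, the spatial covariance between wind class
and terrain), calibrated ecological niche structure, or realistic
turbine-placement economics. Passing tests therefore demonstrate the
*correctness of the computation* under controlled conditions, not the
reproduction of any region's absolute numbers — those depend on the
real data products, which are out of scope by design.

## Problem sizes in the test suite

The suite verifies each stage against independent brute-force oracles at
sizes where those oracles are exact and fast: 64×64 grids for the
kernel-density and patch-filter equivalences (the latter across 100
random seeds), 32×32 for capacity aggregation (100 seeds) and line
rasterization, 256×256 for the generator's distributional properties,
and a 96×96 (9.6 km) window for end-to-end runs — large enough that a
single 3.2 km stopover buffer does not blanket the study window, which
it would at 64×64.

## Known limitations

* Exclusion polygons are single outer rings; holes and multipolygons are
  not represented (union-of-rings covers the shipped rule sets).
* The pipeline requires all grids pre-aligned on one CRS; it deliberately
  performs no reprojection.
* Kernel-density bandwidth/threshold and the sensitivity-scale
  orientation are data-dependent choices the user must confirm against
  their own layers.
* Percent-of-goal rows computed from rounded GW inputs can differ by a
  few percent from values computed on unrounded capacity; the package
  always computes from whatever precision it is given.
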
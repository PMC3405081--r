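# windsift

Identify low-impact areas for wind energy development on already-disturbed
land, and convert them into installable capacity.

Wind energy has a larger land footprint per GW than most other generation,
and in grassland regions its expansion competes directly with some of the
least-protected wildlife habitat on the continent. One siting strategy
avoids most of the conflict: put turbines on land that is *already*
disturbed — cropland, developed areas, oil and gas fields, mined land —
provided the wind resource there is economically viable and the site is not
wildlife-sensitive for other reasons (migratory stopovers, high breeding
densities, protected status). `windsift` implements that analysis as a
reusable, fully tested raster/vector pipeline for landscape ecologists and
conservation planners, together with a seeded synthetic-landscape generator
so every stage can be exercised and verified without any external data
downloads.

## The method

The pipeline composes binary masks on a shared projected, meter-unit,
equal-area grid:

1. **Disturbance footprint** `D` — union of: disturbed land-cover classes
   (cultivated crops, all developed intensities, hay/pasture), any mapped
   impervious surface, significant topographic change (per-cover thresholds
   in 10.21–17.57 m, capturing surface mines), oil/gas well fields (quartic
   kernel density of well points, wells/km², thresholded), linear
   infrastructure rasterized at 30 m, and settlements buffered by 300 m.
2. **Patch filter** — disturbed patches smaller than 1 km² and farther than
   800 m from any patch of at least 1 km² are removed (too small and
   isolated to support development).
3. **Wildlife exclusions** `E` — a declarative, jurisdiction-specific rule
   set compiled to a mask: polygon burns (priority areas, sage-grouse
   cores, important bird areas), category thresholds on sensitivity
   rankings, waterfowl breeding-pair density ≥ 104 pairs/km², repeated
   whooping-crane stopover sites (observations in ≥ 2 years or ≥ 3 days of
   one year) buffered by 3.2 km, and 1.6 km river-corridor buffers. Five
   rule sets ship as YAML under `inst/rulesets/`.
4. **Suitability** — wind power class ≥ 3 (mean wind speed ≥ 6.4 m/s at
   50 m) is viable `V`; GAP 1–2 protected areas `P`, urban cores `U` and
   NLCD water/wetland `W` are unsuitable. The low-impact mask is

   `L = D ∧ V ∧ ¬E ∧ ¬P ∧ ¬U ∧ ¬W`

5. **Capacity** — each low-impact cell contributes its area times a
   capacity density by wind power class (WPC 3–7: 4.3, 4.8, 5.2, 5.5,
   6.0 MW/km²; below 3: 0), aggregated per region into GW and percent of
   the regional development goal.
6. **Turbine audit** — existing and proposed turbine points are classified
   against `L` and summarized per region and status.

## Worked example

```r
library(windsift)

ls <- generateLandscape(landscapeParams(gridShape = c(96, 96), seed = 8,
                                        nWells = 60,
                                        nTurbinesExisting = 30L,
                                        nTurbinesProposed = 50L))
res <- runLandscapePipeline(ls)     # Dakotas-style rule set by default
res$regionSummary
#>   region goal_gw low_impact_gw pct_of_goal
#> 1   east  0.0009      0.026739        2971
#> 2   west  0.0009      0.060855        6762
#> 3  Total  0.0018      0.087594        4866
res$turbineSummary
#>   region   status n_turbines n_low_impact pct_low_impact
#> 1   east existing         14            0              0
#> 2   west existing         16            7             44
#> 3   east proposed         27            4             15
#> 4   west proposed         23            6             26
#> 5  Total existing         30            7             23
#> 6  Total proposed         50           10             20
```

The synthetic 9.6 km × 9.6 km window carries 0.088 GW of low-impact
capacity — 4866% of its (area-scaled) development goal, echoing the
region-scale finding that low-impact potential exceeds goals by more than
an order of magnitude. 7 of 30 existing and 10 of 50 proposed turbines in
this realization fall inside the identified low-impact areas.

`runPipeline()` accepts any layer map, rule set and goals table;
`runPipelineConfig()` drives the same pipeline from a YAML file of layer
paths, and `inst/scripts/windsift.R` wraps both as a small CLI
(`simulate`, `run`).

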
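# mesobreak

Range-edge breakpoint analysis of mesopredator suppression from predator
bounty records.

## The problem

Where an apex predator (grey wolf, dingo) is common, mid-ranking predators
(coyote, golden jackal, red fox) tend to be rare — the *Enemy Constraint
Hypothesis* (ECH) predicts that a mesopredator's abundance declines with
distance into a top predator's range and approaches zero near the range
core. Government bounty archives are the only abundance proxy available at
the spatial scale this prediction lives at: counts of predators killed per
hunting unit, collected over years and attributable to a unit centroid.

`mesobreak` is for ecologists who have such per-unit count tables and want a
reproducible, testable version of the whole analysis chain:

1. **Standardize** — bounty counts / collection years; drop units where
   *both* species are zero (no effort signal).
2. **Range surface** — weighted bivariate Gaussian kernel density estimate
   of the top predator's bounty point pattern on a metric grid (default
   2.5 km cells), bandwidth by Silverman / plug-in / smoothed
   cross-validation.
3. **Range edge** — the 85% volume isopleth of that surface (marching
   squares with linear interpolation), i.e. the tightest density contour
   containing 85% of the probability mass.
4. **Signed distance** — Euclidean distance from each unit centroid to the
   nearest point on the edge, multiplied by −1 outside the range.
5. **Breakpoint model** — continuous one-breakpoint piecewise linear
   regression of the z-scored abundance index on signed distance,

   E[z | d] = β₀ + β₁·d + β₂·(d − b)₊,

   with b found by exhaustive search plus golden-section refinement,
   case-resampling bootstrap CIs (2.5/97.5 percentiles, 1,000 replicates)
   and a bootstrap sign test for the slope change β₂.
6. **Diagnostics** — standardized residuals mapped at unit coordinates,
   plus a permutation Moran's I with k-nearest-neighbour weights.

A synthetic landscape generator (`synthetic_config()` /
`generate_landscape()`) draws Poisson bounty counts on a unit grid around a
circular top-predator range with a known mesopredator breakpoint, so every
stage can be verified against ground truth without any field data.

## Worked example

```r
library(mesobreak)

cfg <- synthetic_config(seed = 42)     # 150 units, true breakpoint 300 km
ls1 <- generate_landscape(cfg)

report <- run_ech_analysis(ls1$dataset, cell_size = 10,
                           n_boot = 1000, seed = 1)
print(report)
```

```
<ech_report> region: synthetic
  units: 150 analysed (0 double-zero excluded)
  edge: 1 ring(s), contained mass 0.85
  top  breakpoint   -116.5 km  CI [-146.4, 193.6]  R²=0.74  p=0.06  [no clear breakpoint: p_slope_change]
  meso breakpoint    298.3 km  CI [-236.8, 315.8]  R²=0.95  p=0.332  [no clear breakpoint: ci_span]
```

Reading this: the 85% isopleth captured 0.85 of the surface mass; the
mesopredator index declines at −0.0053 z/km from far outside the range and
flattens 298 km inside the edge — within 2 km of the generator's true
300 km breakpoint. The bootstrap CI is honest about the weakly populated
core plateau (few units lie deeper than 300 km inside this range), so the
run is flagged `no clear breakpoint: ci_span`; with denser core sampling
the interval tightens. The top predator fit reports the location where its
own index starts rising, with the analogous uncertainty flags.

Per-unit outputs (`distance_profile.csv`), the edge polygon
(`edge.geojson`), residual diagnostics, the JSON report and the two
scatter-plus-segments figures are written when `out_dir` is given.

A thin command-line wrapper over these functions ships in
`inst/scripts/run_ech.R` (`simulate`, `run` and `fit` subcommands).

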
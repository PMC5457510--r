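---
title: "Methods: range-edge breakpoint analysis of mesopredator suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: range-edge breakpoint analysis of mesopredator suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesobreak)
```

## The analysis in one paragraph

`mesobreak` asks a geometric question of count data: *how far inside a top
predator's range does a mesopredator persist?* Bounty counts per hunting
unit, divided by collection years, act as a relative abundance index for
each species. The top predator's index, placed at unit centroids and
smoothed with a weighted bivariate Gaussian kernel, yields a utilization
surface; its 85% volume isopleth is taken as the range edge. Each unit then
gets a signed distance to that edge (negative outside), and both species'
z-scored indices are regressed on distance with a continuous one-breakpoint
piecewise linear model. The mesopredator's breakpoint — where its decline
flattens onto a floor — is the quantity of interest; a case-resampling
bootstrap supplies its confidence interval and a sign test for the slope
change.

## Model and assumptions

The regression mean is a linear spline with one knot,

$$\mathrm{E}[z \mid d] = \beta_0 + \beta_1 d + \beta_2 (d-b)_+ ,$$

continuous at $b$ ("where the lines meet"), with left slope $\beta_1$ and
right slope $\beta_1+\beta_2$. Implicit assumptions worth stating:

* bounty counts scale with abundance comparably across units (units with a
  zero for *both* species are treated as unsampled and removed; a zero for
  one species is kept — it is exactly the suppression signal);
* the projected coordinates are metric (km); the package validates
  magnitudes but never reprojects;
* errors are independent across units — checked only descriptively, by
  mapping standardized residuals and a permutation Moran's I; no spatially
  correlated error model is fitted;
* one knot suffices. The no-breakpoint detector guards the interpretation,
  not the fit: a breakpoint is reported "unclear" when its 95% CI spans
  more than half the observed distance range or the slope-change p-value
  exceeds 0.05.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cell_size` | 2.5 | km | grid resolution of the density surface; standard for continental bounty data. Synthetic-landscape examples in this package use 10 km, matched to 100 km unit spacing |
| `level_p` | 0.85 | — | isopleth level defining the range edge; levels above 0.9 over-extend ranges, lower levels clip occupied area |
| `bandwidth_method` | `"silverman"` | — | weighted normal-reference rule on marginal s.d.s; `"plugin"` (full covariance) and `"scv"` (smoothed cross-validation, minimized over a scalar multiple of the plug-in matrix with a plug-in pilot) are available and recorded in provenance |
| `padding` | 3 × max kernel s.d. | km | guarantees the grid holds ≥ 98% of the kernel mass (enforced; error otherwise) |
| `ddof` | 1 | — | sample s.d. in z-scores |
| `n_boot` | 1000 | — | bootstrap replicates; percentile CI at 2.5/97.5% |
| `min_distinct_side` | 2 | — | distinct distances required each side of a candidate knot (identifiability) |
| `k_neighbors`, `n_perm` | 8, 999 | — | Moran's I weight scheme and permutation count |

## Numerical choices

* **Breakpoint search.** Candidates are every distinct distance value and
  every midpoint of consecutive distinct values (so the attained RSS is
  never above a midpoint-only grid's), followed by golden-section
  refinement inside the bracketing intervals, tolerance $10^{-10}$ times
  the distance range. Golden section is used instead of Brent's method
  because it is exactly translation- and scale-covariant, which keeps the
  estimator equivariant under coordinate changes up to floating rounding.
  Within the RSS valley floor — where RSS differences fall below floating
  noise — the refined knot is defined only to roughly metre precision on a
  km scale; ties across candidates break toward the smallest $b$.
* **Per-candidate least squares** is solved in closed form from suffix-sum
  sufficient statistics (a symmetric 3×3 Cramer solve), with RSS from
  $z'z-\hat\beta'X'y$ clamped at zero; agreement with an exhaustive
  `lm()`-per-candidate oracle is asserted to $10^{-9}$ in the test suite.
* **Isopleth threshold.** The density threshold is the largest value whose
  super-level cells hold at least `level_p` of the surface mass; all cells
  tied at the threshold are included (overshoot is reported, never hidden).
  A perfectly uniform surface degenerates to "everything included" with a
  warning. Contained mass is reported by cell accounting and, as a bracket,
  by interpolated ring area.
* **Ring topology.** Contours come from marching squares with linear
  interpolation (`grDevices::contourLines`). Rings are closed; an open
  polyline (possible only when the surface is truncated at the grid
  boundary, which the padding contract prevents for pipeline-built
  surfaces) is closed with a warning. Hole rings are handled by the
  even-odd rule, so the interior of a hole counts as outside the range and
  distances see hole boundaries too.
* **Signed distance** is exact vector geometry: minimum point-to-segment
  distance over all rings, sign from even-odd membership. No raster
  distance transform is involved, so results are independent of cell size
  given the rings.
* **Bootstrap degeneracies.** Resamples that cannot support a knot (fewer
  than two distinct distances on a side) are redrawn and counted; more
  than 20% redraws triggers a warning. The slope-change p-value is the
  bootstrap sign probability $2\min(\Pr(\beta_2^*\le 0),
  \Pr(\beta_2^*\ge 0))$; an asymptotic t-test at the fixed knot
  (`slope_change_ttest()`) is provided as a cross-check and is
  anti-conservative by construction.
* **Determinism.** Every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from its `seed` argument, and identical inputs
  yield byte-identical JSON/CSV outputs.

## What the synthetic generator emulates — and what it does not

`generate_landscape()` draws hunting units on a regular grid (default
15 × 10 units spaced 100 km, the resolution of historical 100 × 100 km
bounty tallies) around a circular top-predator range of radius 450 km. The
top predator's expected bounty rate rises linearly from zero at the edge to
a 5/yr plateau over 50 km — a sharp range boundary. The mesopredator's
expected rate declines linearly with distance into the range, passing
6/yr at the edge, and flattens at 0.3/yr from the true breakpoint
(300 km) inward: a continuous profile with a *single* knee, which is what a
one-breakpoint model can identify. Counts are Poisson draws of rate ×
years (default 10 years). The generator emits counts only; z-scores arise
downstream through the pipeline's own standardization, mirroring the real
data flow.

The circular range is a deliberate design choice: the fitted isopleth of
any bounded point pattern is a closed curve, so under a straight-edge truth
the nearest-edge distances of deep-core units would be capped by the study
area's own extent rather than by the range geometry. A disc makes the true
signed distance well defined in two dimensions for every unit and
commensurate with what the pipeline measures. A `"halfplane"` geometry
remains available for one-dimensional checks, with exactly this caveat.

What passing tests on these landscapes do **not** show about real data:
real hunting units are irregular polygons with uneven effort, counts are
over-dispersed relative to Poisson, abundance surfaces are anisotropic and
multi-modal, collection spans differ between species and units, and spatial
autocorrelation of residuals is the rule rather than the exception. The
generator provides ground truth for the *machinery*, not realism for the
*ecology*.

## Problem sizes in the tests and acceptance script

The acceptance layer fits on one CPU in a few minutes by choice of scale:
oracle-equivalence over 50 seeded datasets of 30–200 points; breakpoint
recovery over 100 landscapes of 150 units; CI coverage over 200 landscapes
at 500 bootstrap replicates; geometry and KDE oracles on 50 random
polygon/centroid cases and grids of a few thousand cells; and the full
pipeline (1,000 bootstrap replicates) on the default 150-unit landscape
with 10 km cells.

## Known limitations

* The exact smoothing used for the historical continental surfaces is not
  recoverable; the bandwidth method is declared configuration, recorded in
  provenance, not a reproduction guarantee.
* One knot only; systems with both a rise and a fall inside the observed
  window (two knees) will pull the single knot to whichever bend dominates
  the fit — the top predator's edge-side fit on the default landscape is a
  deliberate example, and the no-clear-breakpoint flag is the honest
  output there.
* Percentile bootstrap CIs for a knot on a thinly populated plateau are
  wide and can be bimodal; the `ci_span` rule exists precisely to surface
  that.
* No GLM/count-likelihood variant: the response is the z-scored rate, by
  design, so slopes are comparable across regions.
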
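---
title: "Modeling larval dispersal and reef connectivity with reefconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling larval dispersal and reef connectivity with reefconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefconn)
```

## The biophysical model

`reefconn` estimates *potential connectivity*: the exchange of passive
larvae among reef habitats that ocean currents alone would produce, given
only two biological constraints — a fixed pelagic larval duration (PLD) and
a map of settlement habitat. Larval behavior, swimming, vertical migration,
mortality and variable competency windows are deliberately absent; the
package models the physical transport null hypothesis against which such
biology can later be weighed.

A virtual larva released at position $\mathbf{x}_0$ evolves as

$$\mathbf{x}_{k+1} = \mathbf{x}_k + \int_{t_k}^{t_k+\Delta t}
\mathbf{u}(\mathbf{x}, t)\,dt + \boldsymbol{\eta}_k, \qquad
\boldsymbol{\eta}_k \sim \mathcal{N}\!\left(0,\; 2K\Delta t\, I_2\right),$$

i.e. deterministic advection through the horizontal velocity field
$\mathbf{u}$ plus an uncorrelated Gaussian random walk whose per-axis
variance grows as $2K\Delta t$ — the standard Lagrangian representation of
a scalar eddy diffusivity $K$. Tracking is two-dimensional, on a single
velocity layer: the vertical structure of the flow is collapsed into the
choice of which model layer (e.g. the layer near the typical larval depth)
supplies $\mathbf{u}$.

Settlement is evaluated **once**, at the end of day `pld_days`: the
particle settles onto the nearest habitat pixel whose center lies within
`settle_radius_km`, ties broken to the lowest `pixel_id` so each particle
produces exactly one settlement event and counts are conserved. Evaluating
at the final day only (rather than over a competency window) isolates the
physical drivers of dispersal; settlement-window variants would need a
different fate accounting and are out of scope.

## Parameters that matter

| parameter | default | units | why this default |
|---|---|---|---|
| `pld_days` | 45 | days | representative PLD for most reef fish |
| `settle_radius_km` | 5 | km | one habitat-pixel scale: within sensory/settlement range of a 4-km² reef pixel |
| `eddy_diffusivity` | 250 | m²/s | consistent with drifter dispersion in subtropical island wakes |
| `dt_seconds` | 3600 | s | resolves sub-daily shear; must divide the PLD evenly |
| `particles_per_pixel_per_day` | 50 | – | balances Monte-Carlo error against run size |
| `replicates` | 3 | – | random-walk replicates averaged for consistency |
| `integrator` | rk4 | – | 4th-order accuracy on smooth fields; `euler` retained for oracle comparisons |

The default release schedule is daily from 2009-05-02 to 2014-04-10 (1805
release days — with 687 pixels and 50 particles each, just over 62 million
particles per replicate, a size the package enumerates but does not
instantiate in tests). Seasonal analyses (default May–June, the peak reef
fish spawning season) are a **post-hoc filter on release dates** of one
particle set, not a separate simulation, so year-round and seasonal metrics
are always computed from the same events.

## Numerical choices

- **Longitude convention.** All longitudes live on $[0, 360)$ internally,
  because archipelago-scale domains commonly straddle the antimeridian;
  I/O accepts either convention. Distances are seam-free by construction
  (tested against mirrored configurations at longitude 0).
- **Metre–degree conversion.** Velocities (m/s) convert to angular rates
  per RK4 stage using the stage latitude:
  $\Delta\lambda = \Delta x / (M \cos\varphi)$,
  $\Delta\varphi = \Delta y / M$ with $M = \pi R/180$ metres per degree and
  $R = 6371$ km (the package-wide sphere radius, configurable via
  `options(reefconn.earth_radius_km=)` since some geodesy libraries default
  to the equatorial 6378.137 km). Tracking is refused poleward of
  ±89.4° where $\cos\varphi$ degenerates.
- **Interpolation.** Bilinear in lon/lat (exact for globally linear
  fields, exact at grid nodes) and linear in time between snapshots. No
  extrapolation: off-grid queries return a sentinel and the particle is
  lost (absorbing boundaries — the conservative choice when boundary
  behavior is unspecified). Masked land cells likewise signal `masked`
  rather than silently contributing zero velocity; a masked corner of the
  bilinear stencil only masks queries that give it nonzero weight.
- **Seeding.** One master seed; each (replicate, cohort) pair derives an
  independent stream by a fixed affine counter scheme kept below
  $2^{31}-1$, so cohorts are order-independent and a fixed seed reproduces
  the experiment byte-identically.
- **Zero-denominator conventions.** Islands with no settlers yield flagged
  all-zero probability rows and `NA` self-recruitment / mean distance
  (missing, never silently 0); the source–sink index is defined as 0 when
  an island's total flux is 0, consistent with the balanced-flux reading
  of the index.

## Design choices where the design was open

- **Rearward orientation.** The rearward normalization divides by
  receiving-site totals while its natural reading has rows summing to 1;
  both hold simultaneously if rearward **rows are receiving islands**
  (row = origin composition of that island's settlers). The orientation is
  tagged on the object and in the CSV header, and `matrix_difference()`
  refuses to mix directions.
- **Mantel variant.** Connectivity matrices are asymmetric and are not
  distance matrices, so `mantel_test()` computes Pearson correlation over
  all off-diagonal cells under simultaneous row/column permutation of one
  matrix. The diagonal is excluded by default so self-recruitment — often
  an order of magnitude larger than off-diagonal transfer — does not
  dominate r; `include_diagonal = TRUE` exposes the other variant. The
  permutation p is one-sided with the observed value counted,
  $p = (\#\{r^* \ge r\} + 1)/(n_{perm}+1)$.
- **Releases at pixel centers, 00:00 UTC.** Sub-pixel release placement is
  unspecified at the 4-km² pixel scale; centers are reproducible and
  consistent with the 5-km settlement geometry.
- **Settlement-fraction denominator.** Per-island settlement fractions
  divide by all particles released archipelago-wide (so island fractions
  partition the total settlement fraction); the per-island-release
  denominator is available as a switch.
- **Distances within islands** are true geodesics (not forced to zero), so
  a particle settling on a different pixel of its own island contributes
  its real displacement.

## What the synthetic scenarios do and do not show

The generator emulates the statistical structure the analysis assumes — a
linear island chain with grouped pixels, differential reachability, and
diffusion-limited retention:

- `conveyor`: $K=0$ uniform flow moving each island's larvae exactly one
  spacing downstream per PLD; the island matrix is superdiagonal in closed
  form. Conveyor speeds are computed from the spacing, and the 5-km
  settlement radius absorbs the ~0.1–1 km residual between great-circle
  island placement and constant-latitude advection at the chosen
  latitudes.
- `broken_chain`: one gap enlarged beyond the per-PLD reach — an
  engineered connectivity break with exactly zero flux across it.
- `isolated_atoll`: one island placed $10\times$ beyond the advective
  $+\,3\sigma$ diffusive range; all its settlers are self-recruits, so
  self-recruitment is exactly 1 and the source–sink index exactly 0,
  conditional on at least one settler.
- `diffusion_only`: zero velocity; final displacement variance is $2Kt$
  per axis, and `estimate_diffusivity()` recovers $K$ within 5% at
  $n = 10{,}000$ (the binomial/χ² Monte-Carlo bound at that $n$, which is
  why tests at the configured seeds are not flaky).

Passing these scenarios demonstrates that the tracker integrates, loses and
settles particles correctly and that every statistic implements its
definition. It does **not** demonstrate realism of any particular ocean:
real current fields have mesoscale eddies, seasonal reversals, shear
dispersion and coastline complexity that no analytic field reproduces, and
real connectivity estimates inherit the circulation model's biases.
Problem sizes in the test-suite runs (3–4 islands, 4–9 pixels each, 1–2
release days, 10–100 particles per pixel per day) were chosen as the
smallest sizes at which every expected structure is resolvable; the
full-scale five-year schedule is enumerated exactly but exercised only
through its arithmetic.

## Validation architecture

Two independent routes to every deterministic result: the production
tracker (RK4, hourly steps) and `brute_force_connectivity()` (forward
Euler at 60-second steps, written separately) must produce **identical**
island matrices on every $K=0$ scenario. Stochastic results are checked
against closed forms (random-walk variance, estimator consistency,
permutation-null uniformity) at sample sizes with stated Monte-Carlo
bounds. `haversine_km` is cross-checked against an independent spherical
law-of-cosines implementation and against `geosphere` on the same sphere;
`mantel_test` against `vegan::mantel` on symmetric distance matrices,
where both are defined.

## Known limitations

- Single-layer 2-D transport; no vertical migration or 3-D shear.
- No larval biology: behavior, mortality, competency windows, variable PLD.
- Absorbing domain boundaries; no coastline interaction beyond the land
  mask.
- Gridded input is the package's plain-text snapshot dialect or in-memory
  arrays; velocities must already be in m/s (non-m/s units are a hard
  error, never converted).
- The Gaussian random walk assumes constant isotropic $K$; spatially
  varying diffusivity would require the drift-correction term of the
  corresponding stochastic differential equation, which is not
  implemented.
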
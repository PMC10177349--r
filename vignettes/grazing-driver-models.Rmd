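---
title: "Modelling grazing drivers from GPS collar data with grazeRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grazing drivers from GPS collar data with grazeRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazeRF)
```

## The problem

Sheep distribute themselves over a paddock in response to forage quality,
terrain, shelter, water and weather, and GPS collars let us observe that
choice at high frequency. grazeRF implements a complete analysis chain for
such studies: collar fix quality control, movement summaries, a gridded
**Livestock Residency Index (LRI)** as the response variable, a
12-predictor covariate table, and random-forest models that rank and test
candidate drivers of residency. Because collar studies rarely deposit raw
data, the package also ships a seeded simulator that generates entire
synthetic studies with *known* driver weights, so every stage — and the
inference itself — can be validated by parameter recovery.

## Fix cleaning

Collars log bursts of five fixes (0, 15, 30, 45, 60 s) each five-minute
duty cycle, i.e. 60 fixes per animal-hour. Cleaning applies three rules, in
order, with exact bookkeeping (the per-rule counts plus the retained count
always equal the input count):

1. **Time-to-fix**: fixes that took *strictly longer* than 16 s to log are
   discarded; a fix of exactly 16 s is kept. The threshold is a quality
   proxy — slow fixes come from poor satellite geometry.
2. **Boundary**: fixes outside the paddock polygon are discarded. Points
   *on* the fence line are kept deliberately: fence-line camping is a real
   and interesting behaviour, and partial-dependence curves typically peak
   0–2 m from fences, so edge fixes must survive.
3. **Duplicates**: repeated (animal, timestamp) rows keep the first
   occurrence — a collar cannot be in two places at once.

Trial hours are categorical, half-open bins:
`hour = 1 + floor((t - trialStart)/3600)`, so every fix belongs to exactly
one hour and re-application is a no-op.

## The Livestock Residency Index

The paddock is gridded at 5 m (cells half-open, the origin snapped down to
a multiple of the cell size). The hourly LRI of a cell is the number of
fixes falling in it that hour. Two conventions exist in the field — raw
counts and hourly proportions — and both are supported; the default
normalises by the hour's total so that each defined hour sums to one over
cells. We prefer the proportion form because it makes hours with collar
dropout comparable, and it puts per-cell values on the small (~10^-3 to
10^-2) scale on which published residency models report their mean squared
errors. Hours with no fixes have an *undefined* LRI (`NA`), never zero:
an unobserved hour is missing, not empty.

The model target is the **treatment-level** LRI (all collared animals
pooled) looked up at each retained fix's cell-hour, giving one model row
per fix. Aggregate maps average the hourly LRI over defined hours, so an
hour with few fixes carries the same weight as a busy one.

## The 12 predictors

Each model row carries: animal identity (A, integer-coded levels),
eastings and northings (EA, NO, included to absorb spatial structure),
near distances to trees (NT), water troughs (NW) and fence lines (NF, the
boundary ring when no separate fence layer exists), NDVI, aspect (AS) and
elevation (EL) sampled at the fix, and hourly temperature (T), rainfall
(R) and a sheep chill index (WC).

Numerical conventions worth stating:

* **Near distances** are exact point-to-point or point-to-segment Euclidean
  minima, in metres.
* **Aspect** uses Horn's 3x3 gradient stencil; the value is the compass
  bearing of the downslope direction (0° = north, clockwise), so a plane
  rising northwards has aspect 180° everywhere. Cells with gradient
  magnitude below tolerance are flat and flagged `NA`; rows sampled there
  are dropped rather than given a fictitious bearing.
* **NDVI surfaces** from transect samples are interpolated by inverse
  distance weighting (power 2, all neighbours). IDW is deterministic,
  exactly reproducible, convex (bounded by the sample range) and honours
  samples exactly at zero distance; an ordinary-kriging replacement can be
  slotted in where variogram fitting is warranted. NDVI is measured once
  per trial and held constant across its days.
* **Chill index**: `WC = (11.7 + 3.1 v^0.5)(40 - T) + 481 + 418(1 -
  e^{-0.04 R})` with wind in m/s, temperature in °C and rain in mm/h —
  the conventional sheep chill-stress formulation on the kJ m^-2 h^-1
  scale (roughly 500–1200 over temperate winter conditions). The formula
  is pluggable (`windChill(formula=)`) because chill indices vary between
  studies.
* **Weather** joins by flooring timestamps to the hour, the native
  resolution of airport station series; gaps are an error, not silent NA.
* **Collinearity**: `vifFilter()` iteratively drops the largest
  variance-inflation factor (`1/(1 - R^2)` from regressing each column on
  the rest) while any exceeds 5, with name-order tie-breaks for
  determinism. In weather data this typically removes apparent
  temperature, dew point, humidity and the redundant wind variants,
  leaving T and R.

## Random-forest driver models

Models are regression forests (via `ranger`) of LRI on the 12 predictors,
fitted separately per trial, treatment, and hours subset: **AH** (all
hours) and **GH** (only hours with observed grazing). Defaults are 500
trees and `mtry = floor(12/3) = 4` — the conventional regression-forest
settings, exposed as arguments. Every fit records its seed and is exactly
reproducible.

Performance is **out-of-bag**: each row is predicted only by trees whose
bootstrap resample excluded it. Bagging leaves each tree with ~63.2% of
rows in-bag, so OOB validation is effectively an internal ~2:1
calibration/validation split; `nCalibration`/`nValidation` report that
split's expected sizes (an explicit holdout mode is available). We report
`OOB R^2 = 1 - MSE_oob / var(y)` and OOB MSE.

**Importance significance** uses the Altmann target-permutation scheme:
permute the response B times (default 100), refit, recompute permutation
importance, and set `p = (1 + #{null >= observed}) / (1 + B)`. With
B = 100 the smallest attainable p is 1/101, just below the conventional
alpha = 0.01 reporting threshold. Rankings order predictors 1–12 by
importance with deterministic name-order tie-breaks and stars at
p < 0.01.

**Partial dependence** is the classical set-and-average computation: set
the predictor to each grid value in every training row, predict, and
average. The animal factor uses its levels as the grid.

## The simulator

`simConfig()` defaults encode the study design the package targets: a
~22.5 ha rectangular paddock, 15 collared animals, six-day trials, the
5-per-minute/4-minute-sleep collar schedule, a south-to-north elevation
trend (935–984 m), NDVI in [0.1, 0.4], and dawn/dusk grazing peaks.
Animals follow a biased correlated random walk at minute resolution: each
minute the heading mixes (i) the gradient of the current state's utility
surface — a weighted sum of *standardized* covariates (NDVI, elevation,
tree distance, water distance, and a shelter term that activates only when
the hour's chill index crosses a threshold), (ii) the previous heading,
(iii) mild attraction to the flock centroid, and (iv) noise; step length
comes from state-specific speeds (resting ~0.01, grazing ~0.08,
travelling ~0.3 m/s, lognormal spread). Standardized covariates keep
weights comparable across scenarios. Positions *reflect* off the boundary
rather than being clipped, preserving step lengths near fences while still
producing fence-adjacent residency. The observation model then emits the
burst schedule with GPS jitter, a configured probability (10%) of a slow
(> 16 s) fix and a 5% dropout rate, so cleaning has real work to do.

No quantitative movement parameters were available to estimate these
settings from; they are chosen once to reproduce the qualitative diurnal
speed/activity pattern of temperate sheep flocks and are labelled
synthetic throughout. The simulator deliberately omits rumination
structure, individual personalities, energetics and liveweight — passing
recovery tests therefore demonstrates that the *pipeline* identifies
planted drivers under a plausible movement model, not that real sheep
behave like the simulator.

`scenarioLibrary()` ships four designs: `ip-like` (NDVI-dominant),
`np-like` (elevation/tree-proximity dominant), `null` (all weights zero)
and `weather-driven` (shelter weights switched by chill). The
`recoverDrivers()` harness runs a scenario end to end, thins model rows to
one fix per 5-minute duty cycle (standard serial-autocorrelation
thinning), fits on a 750-row seeded subsample with 100 trees, and runs
the 100-permutation significance test. These problem sizes keep one
recovery run near ten seconds on a single CPU while leaving recovery rates
stable; they are the package's validation conditions, stated here so they
can be scaled up deliberately.

## What the null scenario teaches (a real limitation)

Under the `null` scenario animals ignore every covariate, yet the fitted
forest still attains a substantial OOB R^2 *without* EA/NO in the model,
and several zero-weight covariates earn small permutation p-values. This
is not a defect of the implementation — it is the spatial/temporal
pseudo-replication inherent in regressing a *positional* response on
*positional* covariates. The LRI of a cell-hour is shared by every row in
that cell-hour; smooth surfaces such as NDVI or elevation are effectively
coordinates in disguise, and hourly weather indexes time, so the forest
can memorise the realised occupancy map of a single trajectory realisation
even when the walk was unbiased. Target permutation destroys that
association, so observed importance beats the permuted null — the test
certifies *association*, not *causal driving*. The same mechanism is why
EA and NO rank at the top of residency models fitted to real collar data,
and why spatially explicit forests or cross-validation blocked by
cell/hour would be the next methodological step. A corollary worth knowing
before interpreting coordinate predictors: in this simulator, *adding* EA
and NO to a model that already has the smooth landscape surfaces changes
OOB R^2 by roughly nothing (slightly negative, since redundant predictors
dilute the `mtry` draw) — at 5 m resolution NDVI and elevation are
themselves injective coordinate proxies, so the coordinates carry no
additional information. Consumers of these
models should read importance ranks as descriptive of a single realised
spatial pattern, and rely on the simulator's *contrast* between scenarios
(planted drivers rank top-3 reproducibly; their ordering tracks the
planted weights) rather than on p-values alone to claim driver detection.

## Worked example

```{r example, eval = FALSE}
run <- recoverDrivers("ip-like", seed = 42)
run$fit                 # OOB R^2, split bookkeeping, top predictors
head(run$importance)    # ranks, permutation p-values, stars
pd <- partialDependence(run$fit, run$scenario$table, "NDVI", sampleRows = 500)
plot(pd$value, pd$yhat, type = "l", xlab = "NDVI", ylab = "predicted LRI")
```

## Known limitations

* Rectangular synthetic paddocks only (reflection assumes a convex
  boundary); real boundaries of any simple-polygon shape are supported in
  the analysis chain itself.
* IDW rather than kriging for NDVI surfaces; no variogram modelling.
* No spatially explicit forest; see the null-scenario discussion above.
* The chill formula is a conventional sheep chill index, not a claim about
  any particular study's exact formulation.
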
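---
title: "Methods: ecosystem services valuation and trend analysis in esvtrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecosystem services valuation and trend analysis in esvtrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esvtrend)
```

## Scope and assumptions

esvtrend implements the benefit-transfer approach to ecosystem services
valuation (ESV) on annual categorical land-use rasters, with three analysis
layers on top: socioeconomic dynamic adjustment, nonparametric trend
mapping, and segmented log-linear trend regression. The method assumes that

* each land-use class supplies a fixed bundle of nine services (gas
  regulation, climate regulation, water supply, soil formation and
  retention, waste treatment, biodiversity protection, food, raw material,
  recreation and culture) whose per-hectare value is a fixed multiple of a
  regional base unit value;
* value is linear in area — no saturation, spatial interaction or
  congestion effects;
* willingness to pay scales with social development, summarised by the
  Engel coefficient alone.

These are the standard working assumptions of equivalent-weight valuation;
they trade realism for transparency and comparability across years.

## Valuation

The base unit value is `D = yield × price / 7` (CNY/ha). The one-seventh
convention values one weight unit at a seventh of the mean grain production
value per hectare; the divisor is exposed as an argument of
`calibrate_unit_value()` but defaults to 7, which is the value forced by
the published calibration (4405 kg/ha × 3.05 CNY/kg / 7 = 1919.32 CNY/ha).

The 7 × 9 equivalent-weight table (`equivalent_weights()`) is the single
source of truth for coefficients; monetary tables are always rebuilt as
`weight × D` and never read from print, because published per-cell value
tables of this kind frequently carry row-shift typos. Two data notes:

* the Waterbody water-supply weight (20.97) is recovered from the printed
  row total (50.24) minus the eight printed cells — water bodies dominate
  the water-supply service, so a large weight in that cell is also the only
  physically plausible completion;
* the Grassland cells sum to 5.57 while their printed total is 5.49; cells
  are used as printed and row totals are always recomputed.

Built-up land carries negative weights for gas regulation, water supply and
waste treatment: impervious surfaces consume those services.

**Dynamic adjustment.** Static totals `ESV_s` are first deflated onto the
base year: `E_an(m) = E_m(m) / Π φ_i`, where `φ` is the yearly GDP index
and the product starts the year *after* the base year (an empty product at
the base year itself — deflating the base year by its own index would
contradict its role as the constant year). `E_m` is taken as GDP;
`deflate_series(measure =)` switches to per-capita net income where a
series provides it. `E_avg` is the arithmetic mean of `E_an` over the study
period. Comparable ESV is `ESV_c = ESV_s · E_an / E_avg`, and dynamic ESV
applies the Pearl logistic willingness-to-pay coefficient
`Ac = 1/(1 + e^{−t})` with development stage `t = 1/En − 3`:
`ESV_d = ESV_c · Ac`. `Ac` is strictly decreasing in the Engel coefficient
and confined to (0, 1); at `En = 1/3` the curve is at its midpoint
(`Ac = 0.5`). The Engel coefficient is supplied per year so `Ac` varies
annually; a constant value is the degenerate configuration.

Because valuation is linear in area, region totals can be computed either
from class-area tables or per pixel and aggregated — the two routes are
algebraically identical, and the per-pixel route (`esv_value_raster()`)
exists for mapping.

## Trend analysis

Per series (or per pixel of an annual stack), the Theil–Sen slope is the
median of all pairwise slopes, and the Mann–Kendall test supplies
significance: `S` counts concordant minus discordant pairs,
`Var(S) = n(n−1)(2n+5)/18`, and `Z` uses the standard continuity
correction — `(S−1)/√Var` for `S > 0` and `(S+1)/√Var` for `S < 0`. The
correction for negative `S` is required for antisymmetry (reversing a
series must negate `Z`). A tie-corrected variance is available
(`mk_test(tie_correction = TRUE)`) but off by default, matching the plain
formula; on continuous ESV data ties are rare.

Classification uses two thresholds: a slope band `|β| < 0.005` (value/yr)
below which a pixel is "no trend", and `|Z| ≥ 2.58` (the two-sided 1%
point) separating significant from slight trends. Positive slopes are
increases. Both thresholds are arguments; 2.58 is the default because the
classification scheme this package follows uses the 1% level even where
the accompanying prose quotes 5%. The Mann–Kendall normal approximation is
slightly conservative at these lengths: its exact size at `|Z| ≥ 2.58`
for n = 31 is 0.0090 rather than 0.0100 (computable from the exact null
distribution of `S` via the inversion-count recursion).

Per-pixel application (`trend_raster()`) drops any pixel with a missing
year by default (`pairwise_complete = TRUE` relaxes this), and the class
summary reports areas in km² plus improved (slight + significant increase)
and degraded (slight + significant decrease) aggregates.

## Joinpoint regression

`fit_segments()` fits `ln y_t = β₀ + β₁ t + Σ β_{i+1}(t − T_i)₊ + ε_t` by
ordinary least squares on the hinge design — continuous at every
breakpoint by construction. Segment slopes are
`b_s = β₁ + Σ_{j<s} β_{j+1}`; their standard errors come from the fitted
covariance through the corresponding linear contrasts.

* **APC** per segment is `(e^{b} − 1)·100` %/yr, with confidence limits
  from exponentiating the t-interval of the slope (residual degrees of
  freedom) and a t-test of the slope against zero.
* **AAPC** is `(exp(Σ wᵢbᵢ/Σ wᵢ) − 1)·100` with `wᵢ` the number of years
  each segment spans; its interval uses the delta method on the weighted
  slope combination. With a single segment AAPC equals APC. APC > 0 is an
  increase.

**Model selection.** `select_model()` searches breakpoint placements
exhaustively over observed (integer-year) time points, requiring at least
2 observations strictly between consecutive breakpoints and between a
breakpoint and either end of the series; for k ≤ 3 on series of ≤ 50
points this is at most a few thousand placements, so no heuristic search is
needed. The number of joinpoints is then chosen by an information
criterion:

* plain BIC, `n·ln(SSE/n) + p·ln(n)` with `p = 2(k+1)` effective
  parameters (each joinpoint contributes a slope change and an estimated
  location);
* the default *weighted BIC*, which adds one further penalty unit per
  joinpoint (`p = 3k + 2`). The reference implementation of joinpoint
  regression names a weighted-BIC criterion without publishing its
  formula; this package's operationalisation weights breakpoints more
  heavily on short series, which guards against spurious kinks at
  desk-scale sample sizes while leaving strong kinks detectable. Both
  criteria are selectable and the per-k criterion table is attached to the
  returned fit.

Two numerical choices matter. The SSE entering the criterion is floored at
`n · eps^{3/4}` (machine epsilon), so numerically perfect fits are ranked
purely by the penalty — on noiseless data extra breakpoints cannot win.
And confidence intervals are asymptotic (t-based); no permutation or
empirical-likelihood intervals are provided.

## Mining-impact comparison

`sample_points()` draws uniform points in the study polygon (seeded
rejection sampling) and labels them by containment in the concession
polygons, optionally dilated by an influence buffer (default 0 m: the
concession boundary itself, since no influence distance is established).
`buffer_extract()` averages raster values over pixel centres within a 1-km
disc; points at the study edge keep the mean of whatever valid pixels the
disc contains, and all-missing discs yield `NA` with a reported pixel
count. `grid_aggregate()` partitions the extent into 10-km cells anchored
at the raster origin; cell totals conserve the raster total exactly.

Group differences use the Mann–Whitney U test by default: `U` is computed
from midrank sums in-package, and the p-value comes from
`stats::wilcox.test` (exact for small tie-free samples, normal
approximation with tie correction otherwise). Welch's t-test is available
alongside (`compare_groups(method = "t_test")`) because both tests are
conventionally reported for this comparison; U is the default as the
distribution-free choice. Box summaries (median, IQR, Tukey fences) mirror
the usual graphical presentation.

## The synthetic landscape generator

`generate_landscape_series()` emulates the *inputs* the pipeline needs, not
any real geography. The default scenario:

* a 120 × 120 grid of 250-m pixels (900 km²), 31 annual rasters
  (1990–2020), grassland-dominated mosaic (76% grassland, the rest
  woodland/cropland/wetland/water/unused/built-up) built by seeded
  nearest-nucleus (Voronoi) patches — contiguous patches at the configured
  proportions, with no attempt at landscape-metric realism;
* two rectangular concessions of 10% of the area each; mining converts
  4% of the concession area per year (720 ha/yr at the default grid)
  inside them from the year 2000, growing outward from the
  concession centres, encoded as unused (disturbed bare) land with a 5%
  built-up fringe — the legend has no "mining" class, so disturbance is
  priced through these classes exactly as the valuation intends;
* restoration from 2016 returns 3% of the footprint per year to grassland;
* a 0.1%/yr background class-flip rate outside concessions emulates
  classification noise.

The expansion rate is set so mining reaches about 80% of the concession
area by the end of the period (within the concession capacity, so the
default scenario never trips the expansion cap), and the mix of
disturbance classes keeps regional dynamic ESV positive throughout — a
requirement of the log-linear trend model downstream. Under these defaults
the concession region's dynamic ESV is flat-to-rising before mining and
declines afterwards, while the control region rises steadily — the
qualitative mining/control contrast the comparison stage is designed to
detect. `generate_socioeconomic_series()` compounds GDP at 9%/yr (its
yearly index is the realised ratio, so deflation is exact) and interpolates
the Engel coefficient from 0.55 to 0.28 over the period — a typical
development trajectory for a Chinese resource region over 1990–2020.

What the generator does **not** emulate: real class-confusion structure,
spatially autocorrelated noise, mixed pixels, concession shapes beyond
rectangles, or any real region's geography. Passing tests therefore
demonstrate the correctness of the computational chain and the qualitative
detectability of a mining signal, not calibration to any real landscape.

## Problem sizes and test design

The test suite validates Sen/Mann–Kendall against brute-force oracles on
every series of length ≤ 6 over a three-value alphabet, checks the
Mann–Kendall type-I error on 10,000 null series of length 31, recovers
joinpoint parameters over 200 seeded one-kink replicates (breakpoints
within ±1 year, APCs within two CI half-widths of truth in ≥ 90% of
replicates), verifies the Mann–Whitney null rejection rate over 1,000
simulations, and runs the full pipeline end to end on reduced grids
(40 × 40 to 120 × 120). These sizes give stable Monte-Carlo estimates
while keeping the default suite under half a minute.

## Known limitations

* Coefficients are spatially uniform; no willingness-to-pay surveys or
  spatially varying tables.
* No pre-whitening of the Mann–Kendall test: autocorrelated series inflate
  its size.
* Joinpoint breakpoints are restricted to observed years (integer-year
  turning points); continuous-time breakpoints and jump models are out of
  scope, as is permutation-based model selection.
* The comparison treats sample points as independent; spatial-error or
  spatial-lag structures are not modelled.
* Rasters are exchanged as plain-text ASCII grids with a simple projected
  coordinate convention; reprojection and resampling are out of scope.
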
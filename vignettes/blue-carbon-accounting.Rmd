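---
title: "Blue-carbon accounting for tidal wetlands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blue-carbon accounting for tidal wetlands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalcarbon)
```

## The problem

Tidal marshes and mangroves bury organic carbon in their sediments at rates
one to two orders of magnitude above terrestrial soils, and — unlike upland
soils — they do not saturate, because the soil surface accretes vertically as
relative sea level rises. A national carbon budget for these systems needs
three ingredients:

1. **site-level carbon accumulation rates (CAR)** harmonized from
   heterogeneous sediment-core literature,
2. **a driver model** — here, the relationship between CAR and relative
   sea-level rise (RSLR) estimated from tide gauges, and
3. **an upscaling rule** that carries the site network onto a wetland polygon
   inventory with honest uncertainty, plus a forward projection under climate
   scenarios.

`tidalcarbon` implements this pipeline end to end, together with a synthetic
data generator calibrated to the published regional and vegetation summary
statistics, so that every stage can be exercised and tested without any
external download.

## Core derivations

**LOI conversions.** Where core studies report loss-on-ignition (LOI) rather
than carbon content, two conversions are used. Mangrove and tidal-freshwater
soils use the classical van Bemmelen divisor, `TOC = LOI / 1.724`. Brackish
and salt-marsh soils use a marsh-specific quadratic calibrated in percent
units, `TOC% = 0.04·LOI% + 0.0025·(LOI%)²`. The quadratic's linear
coefficient is configurable (`quad_a`) because the original salt-marsh
calibration in the wider literature is usually quoted with a linear term of
0.40 rather than 0.04; the default stays faithful to the compilation this
package reproduces, and users working with their own data can switch.

**Bulk density.** Missing bulk density is filled with the organic/mineral
self-packing mixing model, `BD = 1 / (LOI/k₁ + (1−LOI)/k₂)` with
k₁ = 0.085 g cm⁻³ (pure organic) and k₂ = 1.99 g cm⁻³ (pure mineral). The
model is bounded by the two self-packing densities and is strictly
decreasing in LOI; both endpoint values are asserted in the test suite.

```{r}
bd_from_loi(c(0, 0.5, 1))
```

**CAR.** Carbon density (g C cm⁻³) times the sediment accretion rate
(mm yr⁻¹) times 1000 gives CAR in g C m⁻² yr⁻¹, because each millimetre of
accretion adds 1000 cm³ of new sediment per square metre. Multi-layer cores
are averaged over the top 30 cm (thickness-weighted, partial overlaps
pro-rated), the window that records roughly the last century of burial.
Records dated by ¹⁴C are excluded from CAR statistics: their
centennial-to-millennial accretion rates are systematically lower than the
decadal ¹³⁷Cs/²¹⁰Pb rates and would skew the compilation. Sites with several
cores are averaged to one record per site — the simplest defensible
reduction where the underlying compilations do not state their own.

**Vegetation classes.** Salinity below 0.5 ‰ is tidal freshwater, 0.5–18 ‰
(inclusive on both ends) brackish, above 18 ‰ salt marsh; a mangrove flag
overrides salinity. The inclusive brackish interval follows the natural
reading of a "0.5 to 18" range.

## RSLR from tide gauges

Annual mean-sea-level series are reduced to a linear trend over the most
recent 60 years by ordinary least squares. Gauges must cover at least 80% of
the window (48 of 60 annual values); the threshold is a package choice, as
gap tolerance is rarely stated alongside "continuous records". Gauges with
only ~30 years are mapped onto the 60-year basis through an OLS bridge
`trend60 ~ trend30` (with intercept) trained on gauges supporting both
windows; bridged slopes are flagged, are never used when a direct 60-year
trend exists, and carry a standard error combining the mapped gauge SE with
the bridge's residual SE in quadrature. Sites take the slope of their
haversine-nearest gauge (sphere radius 6371 km — sub-km precision is
irrelevant at the 100-km scales involved), with distance ties broken toward
the smaller gauge id.

## Upscaling with error propagation

Each inventory polygon takes the unweighted mean CAR of all sites within a
100 km radius (boundary inclusive) with SE = SD/√n. The neighbor mean is
deliberately unweighted: the method is defined by membership in the radius,
not by distance decay. Polygons with no or only one neighbor fall back on
their region's mean CAR with the regional mean's SE (not the regional SD —
the fallback propagates the uncertainty of the regional estimate, not
site-to-site scatter). Exactly two neighbors interpolate.

Fluxes are `CAR × area × 10⁻⁶` Tg yr⁻¹, and sums propagate standard errors
in quadrature, `δ_sum = √(Σδᵢ²)`, with `CI95 = 1.96·δ_sum`. Quadrature
assumes independent polygon errors even though neighboring polygons share
sites; this is implemented as the method defines it, and the test suite
verifies the propagation against a Monte-Carlo oracle rather than against a
cluster-aware alternative. Two simpler estimators — one national mean over
the whole area, and stratified group means times group areas — bracket the
interpolated total; on a spatially homogeneous field all three provably
coincide, which the tests assert exactly.

```{r}
# the three headline totals reproduced from printed summary inputs
upscale_uniform(161.8, 25892)
veg <- default_vegetation_table()
upscale_stratified(
  setNames(c(166.2, 179.7, 154.3, 151.5), veg$vegetation),
  setNames(veg$area_km2, veg$vegetation))
underestimation_pct(271.9, 161.8, digits = 0)
```

## Statistical surface

Group contrasts use one-way ANOVA (`stats::aov`) with Tukey HSD pairwise
comparisons (`stats::TukeyHSD`, which applies the Tukey–Kramer harmonic
adjustment under unequal group sizes) and a compact letter display built by
the insert-and-absorb algorithm, so two groups share a letter exactly when
they are not significantly different. Within the CAR/SAR/C-density triangle
the reported associations are first-order partial correlations,
`r_xy·z = (r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²))`, with the remaining
drivers as plain Pearson correlations; no multiplicity correction is
applied to the correlation table, matching the apparent convention of such
summaries, and the tests check the partials against a
residual-on-residual regression oracle.

The driver model is the parsimonious final regression `CAR ~ RSLR`. Because
sites cluster by source of reference, the default fit keeps OLS coefficients
but uses source-clustered sandwich standard errors
(`sandwich::vcovCL`); a `random_intercept` mode fits per-source intercepts
by REML via `lme4`, and plain `ols` is available for comparison. A full
stepwise model search over regions, vegetation and climate covariates is
intentionally not performed: the final model is known, and fitting it
directly keeps the provenance of the slope unambiguous.

## Projection to 2100

Future CAR applies the fitted slope to the difference between future and
current RSLR, with both capped at a critical rate (default 10 mm yr⁻¹,
configurable to the 12 mm yr⁻¹ limit reported for southeast-US marshes):

`CAR_t = max(0, CAR₀ + slope × (min(RSLR_t, crit) − min(RSLR₀, crit)))`.

Capping both terms means a site already beyond the critical rate gains no
further CAR, and the response is continuous at the cap. National flux per
decade multiplies projected CAR by baseline segment area and the scenario's
area-change fraction. The 95% band comes from Monte-Carlo draws (default
10⁴, seed recorded in the output) perturbing each segment's baseline CAR
and the model slope by their standard errors, flooring CAR at zero; the
projected RSLR trajectories are treated as fixed mean paths, so the band
deliberately understates total future uncertainty — propagating sea-level
model spread is out of scope here.

## The synthetic study system

The generator emulates four data products with the statistical structure
the analysis assumes:

* **Sites** (default 50 per region, 7 regions): SAR is drawn per region and
  carbon density per vegetation class, with site-level SD = SE·√n so that
  regional sample means recover the configured summary values (the defaults
  are the published regional and vegetation tables). CAR is the exact
  identity `c_density × SAR × 1000` plus a stored noise term: within each
  region CAR is standardized to the configured mean and SD, then an extra
  calibration component (independent noise, or an RSLR-aligned component if
  the realized correlation falls short) iterates until the all-site
  CAR–RSLR Pearson correlation is within ~0.02 of the 0.40 target, flooring
  at zero and re-centering regional means after each pass. Salinity is drawn
  inside each class's interval; sites carry source groups of 5–10 and an
  optional shared source offset (`source_sd`, default 0 — within-source
  correlation is not documented for the real compilation, so the default
  assumes none).
* **Gauges**: a known linear trend near the regional RSLR plus i.i.d.
  Gaussian annual noise (default SD 20 mm). No AR(1) structure is simulated
  because the analysis fits plain linear trends. A configurable fraction
  has only the latest 30 years.
* **Inventory**: centroids cluster near the site clusters so radius queries
  find neighbors; raw areas are log-normal and rescaled so each region's
  total equals the configured regional area exactly, emulating a fixed
  inventory extraction rather than a random total.
* **Scenarios**: one segment per region; RSLR paths are monotone power
  curves adding 2/4/8 mm yr⁻¹ by 2100 for RCP 2.6/4.5/8.5, and area
  fractions run linearly from exactly 1 in 2020 to endpoints set by the
  accommodation-space population threshold (5 → 0.75, 20 → 0.90,
  150 → 1.20, 300 → 1.50), mirroring the reported range from a 25% loss to
  a <50% gain.

Geography is schematic — seven labeled coastal boxes with plausible
coordinates — because the analysis consumes distances and labels, not
shapes. What passing tests on this system demonstrate is that the
*machinery* is correct (conversions, trend fitting, interpolation, error
propagation, projection); they cannot certify the real compilation's data
quality, spatial autocorrelation structure, or the representativeness of
the literature sites, none of which the generator attempts to emulate.

All randomness flows from one root seed through named substreams
(sites/gauges/inventory/scenarios/projection), so partial pipelines are
reproducible and byte-identical under a fixed seed.

## Numerical choices and edge cases

* Haversine distances on a 6371-km sphere; radius membership is boundary
  inclusive.
* Nearest-gauge ties break toward the smaller gauge id; Tukey letters order
  groups by decreasing mean.
* Negative computed CAR is rejected at validation rather than clamped —
  accretion rates in a compilation are positive, and silently clamping
  would hide unit errors.
* Records lacking both bulk density and LOI are dropped with a logged
  count.
* Degenerate inputs fail loudly with classed conditions
  (`tidalcarbon_trend_unavailable`, `tidalcarbon_bridging_unavailable`,
  `tidalcarbon_empty_profile`) so callers can distinguish data
  insufficiency from numerical failure.
* Reported summary tables round to 2 decimals in Tg at the reporting layer
  only; all internal arithmetic is full precision.

## Problem sizes used in the test suite

The suite runs the generator at 15 sites / 10 polygons per region and 12
gauges for pipeline smoke tests, 50 sites per region for calibration
checks, 200 gauges for the trend-recovery rate, 200 synthetic seeds for
slope-recovery coverage, 10⁵ draws for the quadrature-vs-Monte-Carlo
propagation check, and 2×10⁴ permutations for the max-T Tukey oracle —
sizes chosen so each check has clear statistical resolution while the whole
suite completes in well under a minute.

## Known limitations

* The interpolation assumes independent polygon errors (shared neighbor
  sets are not down-weighted).
* The projection band propagates only baseline-CAR and slope uncertainty.
* The generator produces Gaussian site scatter (floored at zero) rather
  than the right-skewed CAR distributions common in real compilations.
* The 30→60-year gauge bridge is a single national regression; stations
  with idiosyncratic decadal variability may not be well served by it, and
  no station-level QC beyond coverage is attempted.
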
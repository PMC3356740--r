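---
title: "Methods: the S-shape radiation estimation family and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the S-shape radiation estimation family and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sshape)
```

## The estimation problem

Daily global solar radiation `Rs` (MJ m⁻² d⁻¹) drives crop-growth and
water-balance simulation, but pyranometer records are scarce and expensive
to maintain, while daily temperature extremes and precipitation are
measured almost everywhere. Temperature-based estimators exploit the fact
that clear days have large diurnal temperature ranges `ΔT` and overcast
days small ones. The classical families have two structural defects:
power-law (Hargreaves-type) models are unbounded above, so hot clear days
can be assigned radiation above the physical ceiling, and exponential
(Bristow–Campbell-type) models force the estimate to zero as `ΔT → 0`,
although a fully overcast day still receives a substantial fraction of
extraterrestrial radiation. The S-shape family repairs both defects by
modelling the *fraction of clear day* with a sigmoid borrowed from soil
water-retention theory.

## The model family

Every member estimates

```
Rs = Ra · τ(i) · Fcd(ΔT) · (1 + q·R)^[optional] · Fs(i)^[optional]
```

- `Ra` — daily extraterrestrial radiation from the standard astronomical
  formula (solar constant 0.0820 MJ m⁻² min⁻¹, solar declination,
  inverse relative Earth–Sun distance, sunset hour angle). The model
  family treats `Ra` as given; the package computes it from latitude and
  day of year, which is the de facto convention in this literature.
- `τ(i)` — clear-sky transmissivity, either a 2nd- or 1st-order Fourier
  series of the day of year `i` (period fixed at 365 days, leap days
  evaluating at `i = 366`), a constant, or a value derived from site
  metadata (below).
- `Fcd(ΔT)` — the S-shaped fraction of clear day, either the
  four-parameter van Genuchten form `1 − (1−f)/(1+(g·ΔT)^n)^m` or the
  three-parameter Brutsaert form (its `m = 1` special case). Both rise
  monotonically from `f` at `ΔT = 0` toward 1, so estimates stay positive
  on calm days and bounded above. `f` is dimensionless in [0, 1], `g` an
  inverse temperature scale (1/°C), `n` and `m` shape exponents. In the
  final 7-parameter variant `n` is frozen at 2.285, the cross-site
  average obtained when `n` is free.
- `(1 + q·R)` — a multiplicative wet-day term with occurrence flag
  `R ∈ {0, 1}` (wet when precipitation ≥ 0.1 mm by default).
- `Fs(i)` — a seasonal correction Fourier series with constant term fixed
  at 1, fitted in the second calibration stage.

Variants are named by the compact notation `τ-form / Fcd-form /
precip-term / Fs-order` (`parse_variant()`): the original scheme
`5-44-4S` fits the van Genuchten curve separately per season × wet/dry
group (5 + 8×4 = 37 parameters), `5-44-4` replaces the seasonal grouping
with a wet/dry split plus `Fs` (17), and the final `0-2-1-4` — metadata
τ, frozen-`n` Brutsaert curve, wet-day term, 2nd-order `Fs` — has 7 free
parameters. `n_free_parameters()` audits these counts. The parser also
accepts compositional strings such as `1-2-1-4` (identical to `0-2-1-4`
but with τ as a free constant), which the test-suite uses when τ itself
must be recovered from data.

### Diurnal range conventions

`ΔT` defaults to the smoothed convention
`Tmax_i − (Tmin_i + Tmin_{i+1})/2`, which discounts warm-air advection
nights; the last day of a series falls back to the raw range and slightly
negative smoothed values are floored at zero. The raw range is selectable
everywhere. The HKS reference model always uses the raw range, since its
formulation states no smoothing; the other models (S-shape, DC, DB, LS)
default to smoothed. The DB model additionally uses a centred 7-day
moving average of the raw range in its denominator; the window shrinks
symmetrically at the series edges so the output keeps its length.

## Double-step calibration

Stage 1 (`fit_stage_one()`) determines the τ coefficients, the `Fcd`
parameters per group and `q` by bounded least squares on observed
radiation. The solver is Levenberg–Marquardt (via minpack.lm) started
from a fixed grid of start points (`f ∈ {0.2, 0.4, 0.6}`,
`g ∈ {0.05, 0.15}`, `n ∈ {1.5, 2.5}`, `m ∈ {0.5, 1, 2}`, `τ₀ = 0.72`,
`q₀ = 0.1`, capped at 12 evenly chosen combinations), with a cost
tolerance of 1e−8, so the result is deterministic: the same series and
configuration reproduce the identical parameter set bit for bit. Bounds
keep every parameter in its meaningful domain (`f ∈ [0, 1]`, `g, n, m >
0`, `q > −1`). Parameters named in the variant's `frozen` set are held at
supplied values, reproducing the reduced forms in which `f` and `g` are
treated as constants.

A least-squares fit leaves a pronounced, site-specific seasonal pattern
in the residuals. Stage 2 therefore computes the mean observed/estimated
ratio for each day of year (`doy_bias_ratios()`; days with nonpositive
estimates are excluded and counted, empty days are `NA`, never a silent
zero) and fits the deviation of that curve from 1 on the `Fs` sine/cosine
basis with no intercept, weighted by the per-day counts (`fit_fs()`).
Because the basis is orthogonal over the year, a pure harmonic in the
ratios maps onto exactly one coefficient. A 1st-order series cannot
express a half-year harmonic — the structural reason the 2nd-order `Fs`
is the default. `calibrate()` chains the two stages and records error
indices before and after, so the pattern-index gain of stage 2 is always
visible in the result object.

Grouped calibration (wet/dry or season × wet/dry) requires at least 30
usable days per group and at least one full year of data overall; both
thresholds are configuration fields. Records missing any required field
are excluded from fitting.

## Reference models

Four published comparison models are implemented verbatim
(`estimate_reference()`): Donatelli–Campbell (DC, temperature only),
Donatelli–Bellocchi (DB, adds a day-of-year modulation using the
fractional part of its seasonality parameter `c`, legal in
(0, 0.5] ∪ (1, 1.5]), Hunt–Kuchar–Swanton (HKS, linear in `Ra·ΔT^0.5`,
`Tmax`, `P`, `P²` with intercept) and Liu–Scott (LS, exponential
association times an occurrence factor of the previous, current and next
day; edge days reuse the nearest available flag). In the DC formula the
parameter `c` enters as `exp(Tmin/c)`, a positive temperature scale.

Their calibrations follow their authors' pattern-minimizing scheme
(`calibrate_reference()`): DC chooses `c` by an outer one-dimensional
search minimizing the minimum-temperature pattern index with inner least
squares on (τ, b); DB chooses (b, c) by an outer grid-plus-refine search
minimizing the day-of-year pattern index with inner least squares on
(τ, d), keeping `c` inside its two legal intervals; HKS is an ordinary
linear regression; LS is bounded least squares from a small fixed start
list. HKS and LS are intentionally *not* clamped: negative estimates
(negative intercepts on cool calm days) and super-physical estimates are
the documented pathologies of these families, and
`apply_physical_bounds()` exists to count and optionally repair them.
The ceiling is a configurable fraction of `Ra` (default 0.8, a
conservative clear-sky transmissivity ceiling chosen because no exact
upper-limit formula is prescribed for this data set).

## Error indices

`evaluate()` reports the three indicator families: correlation (`R²`,
the squared product-moment correlation), accuracy (RMSE and the mean
absolute relative error in percent, records with nonpositive observations
excluded and counted) and pattern. The pattern index is the maximum
absolute difference between mean residuals of any two intervals:
calendar quarters of the day-of-year axis (boundaries 1–91, 92–182,
183–273, 274–end) for `PI_doy`, and four equal-width bins of observed
minimum temperature for `PI_Tmin` (bins with fewer than 5 days are left
out of the pairwise maximum; the boundaries of both groupings are package
choices, as the literature states none). A small pattern index means the
estimation error carries no systematic seasonal or temperature-dependent
component — the property crop models are most sensitive to, because they
integrate radiation bias but average out random scatter.

## Metadata-only regionalization

Across stations, the fitted constant clear-sky transmissivity correlates
with the long-term average diurnal range, `τ = 0.00591·ΔT_avg + 0.6758`
(r = 0.727). The shipped rule set for the central US plains
(`regional_rules_default()`) fixes the parameters whose cross-site
coefficient of variation was low at their means — `Fcd` floor a = 0.476,
scale b = 0.106, wet-day factor c = 2.25, leading `Fs` cosine
coefficient d = −0.259 — and derives the remaining `Fs` coefficients from
linear regressions on `ΔT_avg`. An alternative regression for the last
coefficient (slope −0.0036, intercept 0.0755, r = −0.905) is carried as
`g_alt` but unused by default: the published list names eight
regressions for seven parameters, and which of the two candidates feeds
the last `Fs` slot is ambiguous; the package adopts the weaker-labelled
one for the default slot and exposes the other as an option.
`regional_parameters()` therefore yields a complete 7-parameter model
from metadata alone — zero site-specific fitting — and
`build_regional_rules()` re-derives such a rule set from any collection
of ≥ 3 calibrated sites (CV ≤ 0.2 → mean rule, else the best
single-covariate regression by |r| among latitude, altitude, mean
temperature, mean diurnal range and annual precipitation).

One caveat is documented rather than silently repaired: with the shipped
constants, the wet-day factor (1 + 2.25·R) combined with `Fcd ≥ 0.476`
puts every wet-day estimate above 0.8·Ra, which is physically
implausible and inconsistent with the accuracy this rule set is known to
achieve; the value is nevertheless shipped verbatim because reproducing
the published arithmetic exactly is one of the package's contracts. Users
applying the regionalized model to real sites should inspect
`apply_physical_bounds()` counts, or refit the wet-day factor where any
radiation record exists.

## The synthetic weather generator

`generate_weather()` emulates the statistical structure that the model
family exploits, with known ground truth: a sinusoidal annual cycle of
minimum temperature with AR(1) day-to-day anomalies (default mean 8 °C,
amplitude 10 °C, autocorrelation 0.7, innovation s.d. 2 °C — a
mid-latitude continental station); first-order Markov precipitation
occurrence (wet-after-wet 0.45, wet-after-dry 0.25) with exponential
wet-day amounts (mean 6 mm); a seasonal diurnal range (mean 11 °C,
amplitude 3 °C, noise s.d. 1.5 °C) reduced by a factor 0.75 on wet days —
the wet/dry contrast the precipitation terms detect; and observed
radiation generated from a chosen variant with true parameters,
multiplied by lognormal noise (s.d. 0.05, i.e. roughly proportional 5 %
errors, appropriate for a positive quantity) and clipped to a
quality-control band (default [0.03, 0.8]·Ra). Years are 365 days long
by default to keep day-of-year bookkeeping trivial; a real leap-year
calendar is available. Everything derives from one integer seed.

The default generating truth is τ from the metadata regression at the
configured mean range, `f = 0.476`, `g = 0.106` 1/°C, `n = 2.285` and a
modest wet-day factor `q = 0.2`. The factor is deliberately *not* the
regionalized 2.25: a generating model that exceeds the clip ceiling on
every wet day would be erased by its own quality-control band, and the
whole point of a recovery experiment is that the truth is present in the
data.
For the same reason, the one experiment that does generate with
`q = 2.25` (to show the calibration machinery recovers even those
constants) releases the upper clip.

`inject_seasonal_bias()` multiplies a known `Fs`-type pattern into the
observed series, emulating the site-specific annual bias curve that
motivates stage 2. The bundled stage-2 experiment injects a *sine-led*
pattern (leading coefficient `e = 0.2`): a cosine-led pattern is nearly
collinear with the annual cycles of `ΔT` and `Ra`, so the stage-1
nonlinear fit absorbs much of it into distorted curve parameters and the
experiment would measure identifiability, not the stage-2 correction. A
sine-led pattern (spring/autumn asymmetry) is phase-orthogonal to those
cycles and can only be removed by `Fs`.

What the generator does *not* emulate: multi-day synoptic persistence of
cloudiness beyond the AR(1) anomaly, spatially correlated multi-site
weather, elevation effects on transmissivity, and instrument artefacts
other than multiplicative noise and clipping. Passing recovery tests on
synthetic data therefore demonstrates that the estimators and the
calibration machinery are correct and self-consistent, not that any
particular real station attains the same accuracy.

## Problem sizes and runtime choices

The bundled experiments use a 30-year virtual station (10 950 days) for
stochastic recovery checks — matching the length of the station records
this model family is usually calibrated on — and 2–3-year series for
structural unit checks. With the fixed multi-start list, a 7-parameter
calibration on 30 years completes in well under a second; the DB
reference calibration, the most expensive piece (an outer grid over its
two seasonality parameters with an inner fit each), takes a few tens of
seconds on a multi-year series.

## Worked example

```{r example}
cfg <- synthetic_config(n_years = 10, seed = 42)
sim <- generate_weather(cfg)
res <- calibrate(sim$ws, "1-2-1-4", sim$metadata)
res
res$params
```

```{r regional}
# a site with no radiation record at all
ps <- regional_parameters(site_metadata(latitude = 40, dt_avg = 11.3))
ps
```

## Known limitations

- The regionalized wet-day factor reproduces its published value even
  though it is physically implausible (see above); the clamp is the
  user-facing mitigation.
- Reference-model calibrations optimize the pattern index on the
  calibration sample itself, as their authors prescribe; no
  cross-validation machinery is provided.
- No uncertainty intervals on fitted parameters.
- Sunshine-duration and humidity-based predictors, hourly radiation and
  crop-model coupling are out of scope.
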
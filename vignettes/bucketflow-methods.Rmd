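---
title: "Methods: bucket-model streamflow simulation and flow-threshold scenario analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bucket-model streamflow simulation and flow-threshold scenario analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bucketflow)
```

## Scope and motivation

`bucketflow` estimates how often a Mediterranean headwater stream crosses
flow thresholds that matter for fully aquatic stream fauna — prolonged
low flows that dewater reaches, and abrupt day-over-day flow rises that
cause catastrophic downstream drift — and how those frequencies respond
to climate warming/drying and to vegetation-cover change. The package
covers the full chain: daily forcing and streamflow handling, a
semi-distributed bucket rainfall–runoff model, Monte-Carlo calibration,
parameter-sensitivity screening, threshold-event statistics, a
climate × vegetation scenario engine, and ANOVA variance partitioning of
the scenario outcomes. A seeded synthetic-data module generates
Mediterranean forcing and pseudo-observed records so every stage is
testable without external downloads.

## The rainfall–runoff model

The catchment is a mosaic of three landscape units — holm oak forest,
beech forest, heathland — sharing the same forcing but carrying their own
parameters. Each unit is a daily-explicit cascade of three linear
buckets, updated in a fixed within-day order:

1. **Snow.** While `T < snow_threshold`, precipitation accumulates in a
   snowpack; otherwise it falls as rain. Melt is degree-day:
   `melt = melt_rate * max(0, T - snow_threshold)`, capped by the pack.
   Snow is marginal in this climate (a few percent of precipitation) but
   kept as a minimal scheme; `snow = FALSE` disables it.
2. **Quick bucket.** Gains rain + melt and routes `V_q / tau_quick`
   entirely into the soil the same day. It represents near-surface
   routing delay, not a separate flow path to the stream.
3. **Evapotranspiration.** Demand is degree-day,
   `PET = et_rate * max(0, T - et_threshold)`; actual uptake is
   `AET = PET * min(1, V_s / field_capacity)^et_adjustment`, capped at
   the available soil water. The exponent (`et_adjustment`) limits
   transpiration from dry soils: at field capacity the limitation
   vanishes for any exponent, and below capacity AET is non-increasing
   in the exponent.
4. **Soil drainage.** Only storage above field capacity drains:
   `D = max(0, V_s - field_capacity) / tau_soil`, split `soil_to_gw` to
   groundwater and the rest directly to the stream (fast runoff).
5. **Groundwater.** A linear reservoir, `V_g / tau_gw`, providing base
   flow.

Catchment streamflow is the cover-fraction-weighted sum of unit runoff.
Residence times are constrained `>= 1` day so each outflow is at most the
available storage and the explicit update is unconditionally stable.
Nine unit parameters × 3 units + the shared snow threshold give 28
calibration parameters.

Two structural identities anchor the implementation and are enforced in
tests: with ET off and field capacity driven to zero the cascade reduces
to discrete linear reservoirs whose impulse response equals the analytic
convolution of geometric kernels (checked to 1e-9), and the water balance
`cumP = cumAET + cumQ + ΔS (+ Δsnowpack)` closes within 1e-6 mm per unit
and catchment-wide for arbitrary parameter sets.

## Calibration

`mc_calibrate()` scores candidates with a single composite objective so
that ranking is a total order:

```
NS + logNS - w_rvd |RVD|/100 - w_var |1 - VAR| - sum(w_soft * soft/norm)
```

with defaults `w_rvd = w_var = 1`, `w_soft = 0.5`, and soft event-count
penalties normalised by the observed counts (floored at 1). The four hard
metrics emphasise complementary aspects: NS high flows, log NS low flows
(offset 0.01 mm/day — below the mm/day equivalent of the 0.33 L/s
low-flow threshold on a ~2 km² catchment, yet strictly positive so zero
flows are admissible), RVD cumulative volume, VAR dispersion. All metrics
use pairwise-complete days, so gapped observation records need no
preprocessing.

Sampling is uniform within per-parameter ranges. After each iteration the
ranges shrink to the min–max envelope of the top 5% of all finite-scored
samples so far, inflated by 10% and clipped to the initial ranges; the
initial ranges play the role of expert-judged credible intervals and are
user-editable. One best set per iteration is retained: this elite
ensemble (not the top draws of a single pool) feeds the sensitivity
screen, and the global best parameterises predictions and scenarios.
Candidates that fail to simulate score `-Inf` and are counted, never
fatal. Everything is reproducible from the `seed` argument.

## Sensitivity screening

`parameter_sensitivity()` compares, per parameter, the elite-ensemble
values against the rectangular (uniform) distribution over the *initial*
sampling range with a one-sample Kolmogorov–Smirnov test
(`stats::ks.test`, exact p-values where available), Bonferroni-corrected
at `alpha / 28` with `alpha = 0.01`. Testing against the initial range is
deliberate: refinement makes the sampled distribution non-uniform by
construction, and that concentration is precisely the evidence that the
simulation responds to the parameter. Under a null of pure uniform
sampling, the family-wise false-alarm rate stays at the nominal level
(verified by simulation in the test suite, within binomial tolerance).

## Threshold-event statistics

All event statistics treat missing days explicitly:

- **Q_diff** is defined only where both consecutive days are observed, so
  a record with `k` maximal observed runs yields `n_obs - k` differences.
- A missing day **breaks** a consecutive-day low-flow run: an unobserved
  day cannot attest continuity. Event durations therefore always
  partition the below-threshold day count.
- Comparisons are strict (`<` below, `>` above), consistent with
  "below"/"above" threshold wording; ties are measure-zero on real data.
- Dry-season membership of a Q_diff value follows its *later* day (the
  rise manifests on day `t`); the dry season is April 1 – September 30.
- Percentile thresholds use linear interpolation at rank `1 + p(n-1)`
  (`stats::quantile` type 7). The convention is stated openly because
  several exist; it is the one under which the reference record's
  published 99th-percentile thresholds are reproducible.
- Flow-duration curves use Weibull plotting positions `100 i/(n+1)`.
- Event durations are binned `<7`, `7–30`, `31–90`, `>90` days, encoding
  "shorter than a week", "longer than a month", "longer than a quarter".

`record_report()` bundles the observation-record chain (completeness,
difference counts, percentile thresholds, event counts, best
precipitation-to-streamflow lag) for any local gauged record in the
canonical CSV layout; `xlsx_to_daily_csv()` is a one-shot converter for
spreadsheet-deposited records.

## Scenario engine and variance partitioning

Vegetation scenarios transform cover fractions exactly (total area is
conserved): (i) as present; (ii) holm oak takes half the beech area and
beech half the heathland; (iii) holm oak takes half the beech area,
heathland untouched; (iv) holm oak everywhere. The engine crosses
2 periods × 2 climate pathways × 4 covers with one fixed calibrated
parameter set, and — deliberately — one fixed threshold triple
(0.33/97/42 L/s): scenarios are judged against the same absolute habitat
criteria, never against thresholds recomputed from their own flows.
Percent-of-time figures use the actual calendar-day count of the
simulated window after spin-up exclusion.

`variance_partition()` fits main effects only:
`SS_factor = Σ_levels n(mean_level - grand mean)²`, fractions =
`100 SS / SS_total`. In a single-replicate 2×2×4 design a saturated model
would leave zero residual by construction; with main effects only, the
residual absorbs all interaction structure and remains informative. This
choice is corroborated by the package's acceptance checks: the published
variance shares of the reference scenario study are reproduced exactly
from its printed event-count table under this model. The test suite also
cross-checks the mean-decomposition sums of squares against a
`stats::aov` fit on random balanced designs.

Reporting rounds half away from zero (`round_half_up()`), matching table
conventions; values below 1% are shown to one decimal.

## Synthetic data

The generator emulates the study conditions of a subhumid-Mediterranean
headwater: mean annual temperature 11.5 °C (seasonal sinusoid of
amplitude 7.5 °C peaking in late July, plus AR(1) anomalies with lag-1
correlation 0.7 and stationary sd 1.6 °C) and expected annual
precipitation 983 mm. Precipitation occurrence is a two-state first-order
chain with monthly wet-day probabilities (0.10–0.30, driest in July) and
persistence r = 0.25 parameterised so the stationary wet-day probability
equals the monthly target; wet-day amounts are gamma (shape 0.7) with
monthly scales solved analytically from relative monthly totals — wet
springs and autumns, dry summers — so the expected annual total equals
the configured value by construction. These defaults are documented
choices representative of the region, not values fitted to any record,
and they are fixed: tests characterise the generator at these settings.

Delta-change presets perturb a baseline by monthly temperature offsets
and precipitation factors whose annual means equal projected regional
changes (+1.3/+1.3/+1.8/+3.9 °C and −11/−16/−17/−28% precipitation for
the near/far × moderate/high-pathway combinations), with the relative
precipitation reduction strongest in the already-dry summer and weakest
in winter. Monthly shapes beyond those annual means are approximate by
design. Temperature offsets are flat across months so the annual mean is
exact for any year length.

`generate_truth_run()` degrades a known-parameter simulation into a
pseudo-observed record: multiplicative lognormal noise (median 1 — flows
stay positive, errors scale with magnitude) and a configurable fraction
of days masked in a few contiguous blocks, mimicking instrument outages
rather than scattered dropouts (default emulation target: ~11% missing,
as in a typical multi-year pressure-sensor record).

What the generator does *not* emulate: spatial precipitation structure,
multi-day storm clustering beyond first-order persistence,
temperature–precipitation cross-correlation, and any specific downscaled
future series. Passing tests therefore demonstrate the correctness and
internal consistency of the pipeline under realistic Mediterranean
statistics, not predictive skill for any particular catchment.

## Numerical choices and degenerate inputs

- Time constants are validated `>= 1` day (stability); field capacity
  `> 0`; cover fractions must sum to 1 within 1e-9 and are re-normalised
  exactly after scenario transforms.
- Constant observed series make NS and the variance ratio undefined:
  explicit errors, not NaN.
- Zero total variation across scenario outcomes yields an all-zero
  partition with a warning rather than 0/0.
- Lag search ties break to the smallest lag; lags with insufficient
  overlap are skipped.
- Spin-up (default 365 days) is simulated and discarded everywhere, so
  event counts never see initial-storage artifacts; the water-balance
  ledger covers the full run including spin-up.

## Problem sizes used in the shipped checks

The test suite exercises: water-balance closure on 1,000 random
parameter sets over 10 years of synthetic forcing; 1,000 null ensembles
of 50 sets × 28 parameters for the family-wise error calibration of the
sensitivity screen; and parameter recovery by calibrating 100 iterations
× 200 runs against a noise-free truth run over 3 observation years
(reaching NS ≥ 0.95). These sizes characterise the methods sharply while
keeping the default check run in the minutes range; all are plain
arguments, so larger studies simply pass larger values.

## Known limitations

- No sub-daily routing or stream-network hydraulics: a day is the atomic
  time step, and drift risk is represented by day-over-day flow rises,
  not velocities.
- No aquifer exchange between landscape units; units interact only
  through area-weighted summation.
- The quick bucket has no direct path to the stream; all fast response
  passes through the soil layer.
- Calibration is Monte-Carlo only — no gradient, Bayesian or GLUE-style
  uncertainty ensembles; the elite ensemble supports sensitivity
  screening, not predictive intervals.
- The ANOVA reports variance fractions only, no F-tests: in a
  single-replicate design the main-effects residual conflates
  interactions with noise, so p-values would overreach.
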
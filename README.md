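# bucketflow

Ecohydrological streamflow simulation and flow-threshold analysis for
small Mediterranean forest headwater catchments.

Stream-dwelling amphibians such as the critically endangered Montseny
brook newt (*Calotriton arnoldi*) live entirely in running water, so their
habitat viability hinges on two hydrological extremes: prolonged low-flow
spells that dry out stream reaches, and sudden flow rises (spates) that
cause catastrophic downstream drift of eggs, larvae and adults. Assessing
those risks under changing climate and vegetation requires simulating
daily streamflow decades ahead, counting threshold events in the
simulated series, and attributing the variation across scenarios to its
drivers. `bucketflow` implements that whole chain for catchments split
into holm oak, beech and heathland landscape units.

## The model

Each landscape unit *u* is a cascade of three buckets updated daily.
With storages V_q, V_s, V_g (mm), forcing T (°C) and P (mm/day):

- snow: P accumulates as snowpack while T < T_snow; melt = m·max(0, T − T_snow)
- quick bucket: gains rain + melt, drains V_q/τ_quick entirely into the soil
- evapotranspiration: PET = e·max(0, T − T_et);
  AET = PET · min(1, V_s/FC)^γ, where γ is the evapotranspiration
  adjustment limiting water loss from dry soils
- soil: drains max(0, V_s − FC)/τ_soil, a fraction φ recharging
  groundwater and 1 − φ reaching the stream
- groundwater: drains V_g/τ_gw to the stream (base flow)

Catchment streamflow is the cover-fraction-weighted sum of unit runoff,
Q(t) = Σ_u f_u · q_u(t). Nine parameters per unit plus one global snow
threshold give 28 calibration parameters. Calibration is Monte-Carlo:
uniform sampling within ranges refined iteration-by-iteration toward the
elite, scored by NS + log NS − |RVD|/100 − |1 − VAR| minus soft
penalties for mismatched threshold-event counts. Parameter sensitivity is
screened by comparing the elite ensemble of each parameter against its
rectangular sampling distribution with a Bonferroni-corrected
Kolmogorov–Smirnov test.

Habitat statistics follow the threshold definitions used for the Montseny
reference catchment: days and consecutive-day events below
Q_low = 0.33 L/s, and single-day events where the day-over-day flow
increase Q_diff exceeds its observed 99th percentile over the whole year
(97 L/s) or the dry season, April–September (42 L/s). A scenario engine
crosses 2 future periods × 2 climate pathways × 4 vegetation-cover
scenarios, and a main-effects ANOVA partitions the resulting variation in
event counts among period, climate and vegetation.

## Worked example

Generate synthetic Mediterranean weather, fabricate a gauged record from
known parameters (10% noise, 11% of days missing), calibrate, screen
sensitivity, and run the scenario matrix:

```r
library(bucketflow)
forcing <- generate_weather(weather_config(), years = 4, seed = 101)
rc <- montseny_reference_catchment()
truth <- parameter_set(
  holm_oak  = unit_parameters(tau_soil = 6, tau_gw = 35, et_rate = 0.25,
                              et_adjustment = 1.5),
  beech     = unit_parameters(tau_soil = 8, tau_gw = 60, et_rate = 0.18),
  heathland = unit_parameters(tau_soil = 4, tau_gw = 20, et_rate = 0.10))
record <- generate_truth_run(forcing, rc, truth, noise_sd = 0.1,
                             missing_fraction = 0.11, seed = 7)

fit <- mc_calibrate(record$obs, forcing, rc, iterations = 20, runs = 200,
                    seed = 42, thresholds = threshold_spec(area_km2 = 2))
fit
#> <bucket_calibration> 20 iterations x 200 runs (seed 42)
#>   best: NS 0.916, logNS 0.901, RVD +3.8%, VAR 0.832, objective 1.511
#>   soft penalties (|count diff|): q_low_days=0, qdiff_all_events=1, qdiff_dry_events=0
```

NS and log NS near 0.9 mean both the high-flow dynamics and the low-flow
regime of the noisy pseudo-record are captured; the soft penalties show
the calibrated model reproduces its threshold-event counts almost
exactly. The sensitivity screen concentrates on the holm-oak soil and
groundwater residence times:

```r
head(as.data.frame(parameter_sensitivity(fit, min_sets = 20)), 2)
#>           parameter statistic      p_value sensitive
#> 1 holm_oak.tau_soil 0.6745277 1.591331e-09      TRUE
#> 2   holm_oak.tau_gw 0.5043852 3.094497e-05      TRUE
```

Scenario matrix (delta-change presets for two pathways and two periods,
four vegetation covers) and variance partitioning of the low-flow days:

```r
forcings <- list(reference = forcing)
for (p in c("near", "far")) for (cl in c("rcp45", "rcp85"))
  forcings[[paste(p, cl, sep = "_")]] <-
    apply_delta_change(forcing, delta_preset(paste0(cl, "_", p)))
sm <- run_scenario_matrix(fit$best_params, forcings, rc,
                          threshold_spec(area_km2 = 2))
fut <- sm$table[sm$table$period != "reference", ]
variance_partition(fut$qlow_days, fut$period, fut$climate, fut$vegetation)
#> <variance_partition> percent of total sum of squares
#>     period    climate vegetation      model   residual
#>         32         22         21         75         25
```

Every future scenario in `sm$table` is drier than the reference (its
`annual_q_change_pct` column is the percent decrease in annual flow), and
the whole-holm-oak cover rows show the most low-flow days — holm oak
transpires most, so its expansion amplifies habitat-critical droughts.

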
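# careplan

Small-area estimation of the demand for general practitioner (GP) care and
its confrontation with local GP supply — the computation behind decision
tools that show health-workforce planners where primary care is under- or
oversupplied.

Direct utilisation data exist only for the areas covered by sample-based GP
registration networks. `careplan` therefore estimates local demand by
**two-stage synthetic estimation**: a patient-level OLS regression of annual
GP consultation minutes (contacts × 10 min) on gender, age band, area
socioeconomic composition and urbanisation,

y_ia = β₀ + β_F·F_i + Σ_k β_k·A_ik + γ₁·p_a^nw + γ₂·p_a^1p + γ₃·p_a^li + Σ_u δ_u·U_au + ε_ia,

is projected onto the census composition of every area (each coefficient
times the number of inhabitants carrying its predictor), yielding expected
consultation minutes per area. Demand is then **confronted** with registered
FTE GP supply through two indicators:

* workload per FTE = demand minutes / FTE (a `No GP` sentinel where FTE = 0);
* FTE balance = FTE − demand/74,730, where 74,730 min/year = 2,350 patients
  per FTE × 31.8 min/patient is the norm workload of one FTE GP.

Because patients often see a GP just outside their own area, the
confrontation is repeated with each area **pooled with its surroundings**
within 3 km (inclusive), letting neighbouring oversupply compensate local
undersupply. A seeded synthetic-data module generates geography, census
profiles, patient records and supply, so the whole pipeline runs and is
validated without access to restricted registry data.

## Worked example

```r
library(careplan)

areas    <- generate_geography(geography_spec(n_areas = 60,
              population_range = c(800, 9000), extent = c(0, 25, 0, 25),
              seed = 42))
profiles <- generate_area_profiles(areas, seed = 43)
supply   <- generate_supply(profiles, supply_scenario(seed = 44))
patients <- generate_patients(profiles, noise = noise_spec(seed = 45),
                              sample_fraction = 0.5)

fit <- fit_demand_model(patients)
fit$fit_stats$r_squared
#> [1] 0.1283     # weak individual-level signal, as expected for GP visits

demand <- apply_population_filter(predict_area(fit, profiles))
head(demand, 3)
#>   area_id population total_minutes minutes_per_inhabitant included
#> 1   A0001       3725      117733.6               31.60635     TRUE
#> 2   A0002       4167      122326.8               29.35609     TRUE
#> 3   A0003       5503      162424.2               29.51557     TRUE

norm <- norm_workload()          # 2350 patients/FTE x 31.8 min = 74,730 min
own  <- confront(demand, supply, norm)
own[1, c("workload_per_fte", "fte_needed", "fte_balance", "workload_band")]
#>   workload_per_fte fte_needed fte_balance  workload_band
#> 1         75834.56   1.575454  -0.0229471 50,000-100,000

pooled <- pooled_confrontation(
  build_neighbourhood(euclidean_distances(profiles), radius_km = 3),
  demand, supply, norm)
compensation_report(own, pooled)
#> Compensation report over 60 areas
#>   shortage share: 63.3% own-area, 50.0% pooled (13.3% compensated)
#>   shortage >= 1 FTE: 36.7% own-area, 31.7% pooled
#>   total shortage: 54.7 FTE own-area, 61.4 FTE pooled
```

Area A0001 needs 1.58 FTE to carry its estimated demand at the norm
workload but has 1.55 FTE — a marginal shortage; 13.3% of areas see their
shortage cleared once supply within 3 km is taken into account.
`summarize_bands()` and `summarize_by_residents_class()` produce the
standard workload-band and area-size report tables, and `run_pipeline()`
drives everything (simulate/load → fit → predict → filter → confront →
surround → report) from one JSON-serialisable config, writing CSV artefacts
and a run manifest.

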
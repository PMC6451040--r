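# riverbod

Semi-distributed modelling of mean-annual **biochemical oxygen demand (BOD)**
fluxes in river networks.

BOD — the oxygen consumed by microorganisms degrading organic matter over a
fixed incubation (BOD₅ = 5 days) — is the standard indicator of organic
pollution in rivers. High loadings come from domestic and livestock waste,
industrial effluents, combined-sewer overflows and, to a lesser degree,
organic matter exported by natural land. `riverbod` is aimed at water-quality
modellers who need a parsimonious, calibratable source-apportionment model of
BOD at basin to continental scale: which sources dominate, how much is
degraded in transit, what reaches fail good status, and how much reaches
the sea.

## The model

The landscape is split into subbasins, each with one main reach, linked
upstream → outlet as a tree. Per subbasin, six+one source categories are
estimated as mean-annual loads (t/y):

* **domestic point** — sewered population at 60 g BOD/PE/day (1 inhabitant
  ≙ 1.23 PE), less 10% sewerage losses, less the treatment efficiency of its
  level (Eff.1/Eff.2/Eff.3 for primary/secondary/tertiary, 0 for connected
  untreated);
* **domestic diffuse** — scattered dwellings (septic tanks, Eff.SD) and
  Individual Appropriate Systems (≈ primary treatment);
* **industrial** — reported TOC releases scaled by an effective bod/toc ratio;
* **livestock** — 400 g BOD/LU/day; pig/chicken plus ruminants above
  25 LU/km² are *intensive* (treated at secondary level, point source),
  the rest *extensive* (diffuse);
* **urban wash-off** — `BOD_U = EMC_U · R_U · 3600·24·365.25/10⁶` from urban
  runoff `R_U`;
* **natural areas** — export-coefficient load `BOD_NAT = E_NAT · Area_NAT`.

Diffuse loads decay within the subbasin over a pathway-specific travel time
(basin lag `T_B = 0.43·A^0.418` h plus 7 days for domestic/livestock
pathways, plus 4 h of sewer time for urban wash-off, no extra delay for
natural land). All loads are then routed down the reach network with
first-order decay `BOD_OUT = BOD_IN · exp(−k_T · TT)`, where
`k_T = k₂₀ · 1.047^(T−20)` is the Arrhenius-corrected decay rate and `TT`
the reach travel time. Concentrations follow from mean annual discharge,
`C = load / (31.5576 · Q)`.

The ten free parameters (four efficiencies, two pathway delays, `k₂₀`,
`EMC_U`, `E_NAT`, `bod/toc`) are calibrated by uniform Latin Hypercube
sampling within literature ranges; each set is scored against monitored
mean-annual concentrations with the Kling–Gupta efficiency and R² on
log-transformed values; *behavioral* sets are the intersection of the upper
quartiles of both scores. Evaluation utilities classify concentrations into
the five water-quality classes (thresholds 2.5/5/10/15 mg O₂/L) and compute
confusion-matrix accuracies and sea-load apportionment (with coastal
catchments flagged as Shreve-order-1 outlets).

A synthetic-data module generates river networks with realistic subbasin
statistics (lognormal areas, mean ≈ 7 km²), mass-consistent discharge,
clustered population, patchy livestock and noisy observations, so the whole
pipeline — including parameter recovery — is testable without external data.

## Worked example

```r
library(riverbod)

cfg   <- synth_config(n_subbasins = 200, seed = 42)
synth <- generate_network(cfg)
synth$network
#> BOD river network: 200 subbasins, 2 outlet(s)
#>   total area 1263.9 km2, total reach length 476.8 km

em <- compute_emissions(synth$network, synth$demographics,
                        synth$livestock, synth$industrial)   # calibrated defaults
fl <- route_network(synth$network, em)
round(summarize_series(fl$concentration_mg_l), 2)
#>     p5   mean    p90    p95    max
#>   1.12  11.26  18.49  36.54 374.14

sl  <- sea_loads(synth$network, fl)
round(100 * attr(sl, "totals") / sum(sl$total_t_y), 1)   # % of sea load by source
#>      domestic_point          industrial livestock_intensive    domestic_diffuse
#>                26.3                35.3                18.1                 0.7
#> livestock_extensive       urban_washoff             natural
#>                 3.4                12.0                 4.2

network_quality_share(fl, synth$network)$failing_pct     # % length > 5 mg O2/L
#> 18.1

obs <- generate_observations(synth, bod_params(), cfg)   # sigma = 0.1 noise
run <- run_calibration(synth$network,
                       synth[c("demographics", "livestock", "industrial")],
                       obs, n = 200, seed = 1)
run
#> LHS calibration: 200 sets, 25 behavioral, 42 stations
#>   best KGE 0.986 (R2 0.985)
```

The flux summary says this synthetic basin is heavily polluted (mean
11.3 mg O₂/L; 18% of reach length fails good status), point sources carry
~80% of the sea load, and a 200-set calibration against the noisy stations
recovers a near-perfect fit (KGE 0.99) with 25 behavioral parameter sets.

## Command line

```sh
Rscript inst/cli/riverbod.R synth     --n 500 --seed 7 --out DIR
Rscript inst/cli/riverbod.R simulate  --network DIR/subbasins.csv --emissions-dir DIR --out fluxes.csv
Rscript inst/cli/riverbod.R calibrate --network DIR/subbasins.csv --emissions-dir DIR \
                                      --obs DIR/observations.csv --n 1500 --seed 42 --out run.csv
Rscript inst/cli/riverbod.R evaluate  --fluxes fluxes.csv --obs DIR/observations.csv --out report.json
```

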
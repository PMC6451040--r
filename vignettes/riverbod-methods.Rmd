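---
title: "Modelling mean-annual BOD fluxes in river networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mean-annual BOD fluxes in river networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverbod)
```

## The model and its assumptions

`riverbod` implements a conceptual, semi-distributed model of mean-annual
biochemical oxygen demand (BOD₅) in a river network. Its core assumptions
are:

1. **Steady state.** Everything is a mean-annual flux; there is no
   intra-annual dynamics, no storm-event simulation, no seasonal lake
   switching. Lakes are folded into the natural-area export term.
2. **Linearity in sources.** Every emission is linear in its driver
   (population, livestock units, TOC, urban runoff, natural area), and decay
   is linear in load. Routing each source category independently and summing
   therefore reproduces the joint result exactly — which is both how the
   source apportionment is computed and a property the test suite asserts to
   1e-9 relative.
3. **First-order decay over travel time.** Both within-basin attenuation and
   in-stream transport degrade BOD as `exp(−k_T · TT)`, with one
   temperature-corrected rate `k_T = k₂₀ · 1.047^(T−20)` per subbasin. The
   same `k_T` is used for the soil/interflow pathway and the reach; the
   alternative (a separate soil rate) would add a parameter the observation
   type used for calibration (in-stream concentrations) cannot identify.
4. **Tree topology.** Each subbasin drains to exactly one downstream
   subbasin or to the sea; braided networks are rejected at validation,
   because the routing recursion assumes a single downstream edge.

## Parameters

| Parameter | Meaning | Units | Range | Default |
|---|---|---|---|---|
| eff1 | primary-treatment efficiency | – | 0.35–0.75 | 0.50 |
| eff2 | secondary-treatment efficiency (also intensive livestock) | – | 0.80–0.95 | 0.94 |
| eff3 | tertiary-treatment efficiency | – | 0.92–0.98 | 0.96 |
| eff_sd | septic-tank efficiency | – | 0.35–0.40 | 0.40 |
| dd_days | disconnected-domestic pathway delay | days | 4–8 | 7 |
| lvst_days | extensive-livestock pathway delay | days | 4–8 | 7 |
| k20 | decay rate at 20 °C | 1/day | 0.35–0.60 | 0.56 |
| emc_u | urban wash-off mean concentration | mg O₂/L | 1–21 | 11 |
| e_nat | natural-area export coefficient | t/km²/y | 0–0.5 | 0.16 |
| bod_toc | industrial BOD/TOC ratio | – | 0.2–2.2 | 0.75 |

The defaults are the calibrated continental-scale values; the ranges are the
literature-based bounds used by `lhs_sample()`. Fixed constants
(60 g BOD/PE/day, 1.23 PE/inhabitant, 10% sewer losses, 400 g BOD/LU/day,
the 25 LU/km² intensive threshold, 4 h sewer time, a 365.25-day year, the
BOD₇/1.16 conversion) live in `bod_constants()` and are overridable.

At the calibrated parameters the model's structural numbers are easy to
read off: a diffuse load delayed 7 days at the low/high end of the realised
decay range (k_T = 0.29–0.49/day) is retained at 87–97% before it ever
reaches a reach, which is why basin attenuation — not in-stream decay — is
the dominant sink for diffuse sources.

## Design choices where the design was open

* **Fate of sewerage losses.** The 10% loss on connected loadings is removed
  from the system by default. A `reemit_sewer_loss` switch re-emits it as
  diffuse domestic load instead; we default to removal as the conservative
  reading of a loss "applied to loadings".
* **Intensive-livestock threshold.** Applied to the *combined* cattle +
  sheep/goat density per subbasin; `combined_density = FALSE` switches to a
  per-type rule. The combined rule treats the threshold as a property of the
  farming system of the subbasin, not of a species.
* **Treatment allocation ties.** Subbasins tied on population density share
  their treatment-level mix proportionally to population (then by id for
  determinism), so a uniform-density region reproduces the national shares
  everywhere rather than an arbitrary ordering artefact.
* **Local-load entry point.** Local point and diffuse deliveries enter at
  the reach head and experience the full reach travel time, same as upstream
  influx (`local_entry = "half"` documents the alternative). One consistent
  rule keeps the path-product oracle exact.
* **Log transform.** Natural log, with observations and predictions floored
  at 0.25 mg O₂/L — half the modal reported detection limit of
  0.5 mg O₂/L — before transforming. R² is the squared Pearson correlation
  of the logs (bounded in [0, 1]); a regression-R² variant is available via
  `gof_suite(..., r2 = "regression")`.
* **Behavioral rule.** Upper quartile of KGE *and* of R², inclusive at the
  boundary (ties at the quantile are kept). The `run_calibration()`
  recommendation (max-KGE behavioral set) is advisory; the package ships the
  calibrated column of the parameter table as the canonical default.
* **Class boundaries.** Quality-class intervals are lower-closed: a
  concentration exactly at 2.5/5/10/15 mg O₂/L falls in the worse class.
* **Percentile rule.** Linear interpolation between order statistics
  (R's type 7), fixed and documented.
* **Threshold tolerance.** `tolerant_accuracy()` counts a pair as agreeing
  when shifting the *predicted concentration* by ±0.5 mg O₂/L could place it
  in the observed class; a class-side variant (`rule = "class"`) is provided
  because the phrase "an error at the thresholds" admits both readings.
* **Undefined concentrations.** Zero discharge flags the concentration as
  `NA` (unclassified downstream) instead of erroring: water-scarce reaches
  are data, not bugs.
* **Velocity model.** The hydraulic velocity–discharge relation is not part
  of the model proper; `reach_travel_time()` accepts precomputed travel
  times (always preferred), per-subbasin velocities, or a user-supplied
  power law `v = a·Q^b` whose defaults are generic placeholders, clearly
  non-calibrated.
* **CLI configuration format.** JSON rather than YAML, because the
  deployment environment guarantees a JSON parser.

## What the synthetic generator emulates — and what it does not

`generate_network()` targets the *statistical* structure the model assumes,
not hydrological realism:

* lognormal subbasin areas with mean 7 km² and interquartile range ≈1–7 km²
  (sdlog 1.4 — chosen once to hit the mean and lower quartile; the upper
  quartile lands at ~7 rather than 8 km²);
* a random tree per outlet grown by preferential downstream attachment,
  giving a few large collectors and many headwaters;
* discharge accumulated downstream from a uniform 10 L/s/km² specific
  runoff, so discharge is mass-consistent and never decreases downstream;
* a 5–25 °C water-temperature spread, town-sized population clusters on top
  of a rural background with density-ranked treatment levels
  (60/25/10/5% tertiary/secondary/primary/untreated), and 5% + 5% of people
  on septic tanks and IAS;
* lognormal ruminant densities centred near 10 LU/km² so the field straddles
  the 25 LU/km² intensive threshold, with pig/chicken production in 20% of
  subbasins;
* observations as the true routed concentrations times multiplicative
  lognormal noise (σ = 0.1 by default — concentrations are positive and
  right-skewed), at 30% of subbasins, with yearly sample counts drawn from
  4–12 so that part of the records falls under the six-sample reliability
  filter.

It does **not** emulate geometry (no coordinates, no DEM), climate forcing,
flow seasonality, or the European monitoring network's spatial bias. A green
end-to-end test therefore establishes that the *machinery* — emissions,
attenuation, routing, scoring, behavioral selection — is internally
consistent and can recover a known parameter vector from noisy data; it does
not establish that the defaults reproduce any particular real basin.

## Numerical notes

* Routing visits subbasins in a cached topological order (Kahn's algorithm);
  a cycle or dangling reference fails validation with the offending id.
* Decay composes exactly: `attenuate(attenuate(L, k, t1), k, t2) ==
  attenuate(L, k, t1 + t2)` to 1e-12 relative, which the property tests
  assert; the routing itself is verified against a brute-force path-product
  enumeration on random small networks to 1e-9 relative.
* KGE is the 2009 formulation `1 − sqrt((r−1)² + (α−1)² + (β−1)²)`;
  degenerate inputs (constant series, zero observed mean) yield `NA` rather
  than a misleading number.
* The Latin Hypercube sampler permutes `n` equiprobable strata per dimension
  and draws uniformly within each; every margin of every design therefore
  contains exactly one point per stratum (asserted as a property test).
* All generators are deterministic under their seed; derived seeds stay
  small integers.

## Known limitations

* Mean-annual steady state: no storm events, no combined-sewer-overflow
  dynamics, no inter-annual streamflow variability.
* The behavioral selection is a quartile rule, not a likelihood: no
  posterior weights, no uncertainty propagation to the flux maps.
* Industrial emissions inherit whatever incompleteness the TOC inventory
  has; the single effective bod/toc ratio averages over industry types.
* The synthetic world is one stated configuration; conclusions about
  parameter identifiability (e.g. that eff2 dominates the KGE response) are
  demonstrated there, in line with domestic/livestock-dominated loading, and
  need not transfer to basins with a different source mix.
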
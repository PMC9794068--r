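---
title: "Modelling pesticide-policy mitigation measures for a carabid beetle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pesticide-policy mitigation measures for a carabid beetle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

`carabidscape` is an in-silico policy experiment: a spatially explicit,
daily time-step agent model of *Bembidion lampros* — a small, univoltine,
spring-breeding ground beetle of temperate arable land and a natural
pest-control agent — living in synthetic dynamic agricultural landscapes
and exposed to insecticide application scenarios. The question the
pipeline answers is comparative, not predictive: which mitigation
measures (substituting toxic insecticides with low-risk products,
reducing spray drift, adding grassy field margins) best support beetle
populations, and how does the landscape context modify that.

The pipeline has five stages, all exercised by the numbered scripts under
`analysis/`:

1. **Synthetic landscape** (`generate_landscape()`): a categorical raster
   of rectangular field parcels grouped into farm units of distinct types,
   with herbaceous and woodland patches, grassy boundary strips, built-up
   blocks and water ditches. Mitigation layers: crop-free buffers along
   water (`add_water_buffers()`) and 4-m grassy margins on a fraction of
   fields (`add_field_margins()`).
2. **Farm calendar** (`default_rotations()`, `schedule_year()`,
   `generate_weather()`): 100-entry crop rotations per farm type, per-crop
   management plans with probabilistic time windows, and a synthetic
   temperate-maritime weather series.
3. **Exposure** (`daily_mortality_prob()` to `exposure_mortality()`): the
   toxic-unit exposure mathematics (below).
4. **Beetle agents** (`step_day()` and its sub-operations): development,
   movement, reproduction, density dependence, farm-operation and
   overwinter mortality.
5. **Endpoints and statistics** (`measure_endpoints()`,
   `run_experiment()`, `stepwise_fit()`): density / Occupancy / Abundance,
   AOR changes against the worst-case baseline, and backward-stepwise AIC
   regression of endpoints on heterogeneity metrics.

## The exposure model

Insecticides are classed by **field lethality rate** over a 7-day test:
LR90, LR50, LR25 (90/50/25 % of exposed beetles die). The daily mortality
probability \(p\) while a beetle sits in a cell at or above the trigger
concentration solves

\[(1 - m) = (1 - p)^d,\]

with \(m\) the overall mortality and \(d = 7\) days, giving \(p = 0.28,
0.09, 0.04\) for the three classes. Above the trigger there is **no
dose–response**: 1.5 and 15 toxic units kill with the same daily
probability.

Concentrations are held in **toxic units** (trigger = 1). The application
rate is calibrated so the deposit stays above the trigger for the whole
effect period at the 20 °C reference temperature:

\[\text{rate} = 1 / 0.5^{\,d/\mathrm{DT}_{50}},\]

which gives 41.78 toxic units for the fast-degrading class
(DT50 = 1.3 d) and 1.21 for the persistent class (DT50 = 25 d). The
printed source value for the latter is 1.22; the formula evaluates to
1.2143, and we report the formula value and document the 0.01 gap rather
than asserting the printed rounding. Decay is first-order with the
half-life scaled by a Q10 rule (\(Q_{10} = 2.58\)): colder days slow
degradation, warm days accelerate it.

**Spray drift** deposits off-crop following the field-crop power law
\(\%\text{drift} = A\,\mathrm{dist}^{B}\) with \(A = 2.7705\),
\(B = -0.9787\), truncated at 12 m. Drift-reducing technology is a
multiplicative scaling of \(A\) by \((1-\text{reduction})\); the source
recalculated coefficients for 50 % and 90 % reduction without printing
them, and uniform scaling preserves the exponent while matching the
stated percentages exactly. Distance is measured from the receiving cell
centre to the nearest sprayed-cell edge (Euclidean).

## The beetle model

Agents are **super-individuals**: one agent represents 100 beetles and
lives or dies as a unit (binomial thinning of the 100 is a documented
alternative we did not adopt, to keep the density-dependence rule acting
on model entities). Four stages are followed — egg, larva, pupa, adult
female; males are not tracked. Development of the immature stages is
below the soil surface and degree-day driven (base 5 °C); juveniles are
therefore exempt from surface spray mortality but exposed to soil
cultivation. Daily juvenile background mortality is high, as is typical
for the group.

Movement (adults only, ≤ 14 m/day) has three modes: random foraging with
rejection of unsuitable cells (sub-optimal habitat accepted with a small
probability; water and built-up never), autumn migration from October 1
(daily onset probability, then biased steps towards the nearest
overwintering cell — margins, boundary strips, woodland), and spring
dispersal back to fields once the 5-day running mean temperature passes a
threshold (default 7 °C; the source only says "triggered by
temperature"). Reproduction happens in fields and their edges from late
spring to mid-summer (default window day 135–196), Poisson daily
fecundity. Density dependence caps 2 adults and 2 larvae per 3 m × 3 m
window around any agent; hibernating aggregations are exempt.

The daily sub-step order (the source is silent) is: farm events and
sprays → exposure decay and trigger mortality → development →
reproduction → movement → density dependence. Spraying before movement
matters: at spraying time the population is largely in-field, and this
ordering preserves that exposure.

None of the quantitative life-history values (degree-day requirements,
fecundity, operation and overwinter mortalities, the autumn onset and
spring threshold) are printed in the source; they ship in
`beetle_params()` / `default_mortality_table()` as clearly labelled,
overridable defaults at literature magnitudes, and no acceptance anchor
depends on them.

## Scenarios and endpoints

`build_matrix()` encodes the 16 scenarios: {LR90 × drift 50/90 % ×
margins on/off} ∪ {LR50, LR25} × drift 50 % × margins on/off, for each
half-life class; the per-class baseline ("worst case") is LR90 + 50 %
drift reduction + no margins. Replicates share landscape geometry and
weather but redraw beetle placement and rotation phases, each from an
independent RNG stream derived from the master seed, so runs are
bit-reproducible and order-independent.

Endpoints are censused on day 59 (March 1) of each year: overall density
(adult females / m²), Occupancy (share of 50 m × 50 m aggregation cells
with ≥ 100 adult females — one super-individual), and Abundance (mean
female density over occupied cells). The source's "grid cells of 50 m²"
is read as 50 m × 50 m squares (the 100-female threshold is implausible
on 50 m²); the reading is configurable. Partial aggregation cells at the
boundary are dropped. Replicate summaries use the sample-sd coefficient
of variation.

## The synthetic world, and what a green test establishes

The original study ran on ten real 10 × 10 km Dutch landscapes built from
topographic and land-parcel registers, with De Bilt weather. Those inputs
are not redistributable, so this package *emulates their statistical
structure*: rectangular-parcel rasters with controllable field counts,
farm-type mixes and semi-natural fractions; rotations and management
plans of plausible Dutch composition; sinusoid-plus-AR(1) weather with a
wet/dry Markov chain. The desk-scale default is 1 km² at 2-m cells, 5
years, 3 replicates (the full profile is supported but long-running).

Consequences: printed *absolute* outcomes that depend on the real
landscapes (baseline densities, the "up to 11 %" scenario deltas, the
FRAGSTATS metric ranges of the study areas) are **not** reproduction
targets here. What the tests do establish is (i) the exposure
mathematics and its printed calibration constants exactly, (ii) the
agent-model invariants (density cap, conservation, step limit,
determinism), and (iii) the *directions* of the headline findings at desk
scale: lower toxicity and added margins raise density and occupancy,
drift-reduction steps move endpoints by less than replicate noise, and
combined measures beat single ones on occupancy.

## Numerical and design choices

- **Eq-1 reading**: the printed relation is typographically garbled; the
  reading \((1-m) = (1-p)^d\) is forced by the printed \(p = 0.28\).
- **Landscape shape index**: FRAGSTATS raster convention
  \(0.25\,E/\sqrt{A}\) with boundary edge included (the source does not
  state the boundary convention; we fix and document one).
- **Rectangular parcels**: seeded recursive splits keep area/perimeter
  bookkeeping exact; the heterogeneity metrics depend only on areas and
  edges, not parcel-shape realism.
- **Margins/buffers**: margin placement is uniform without replacement
  over parcels large enough to hold the ring; both operations are
  idempotent; margin and buffer cells keep their parcel's id but are
  never cultivated or sprayed.
- **Density window at coarse cells**: at 2-m cells the 3-m window rounds
  to a single cell; at 1-m cells the exact 3 × 3 window with a
  sequential-acceptance algorithm whose output is verified against a
  brute-force window scan.
- **Movement rounding**: cell offsets are truncated towards zero, so a
  drawn step of ≤ 14 m can never exceed 14 m after rasterization.
- **Hibernating agents** are not exposed to sprays (no spraying occurs
  near the hibernation period under the default plans) and are exempt
  from the density cap (the species overwinters in aggregations).
- **Calendar**: 365-day years, no leap days, so day 59 is always
  March 1.

## Known limitations

Grazing disturbance, adult males, winged dispersal morphs, prey dynamics
and chemical-specific fate (sorption, metabolites, wind-directional
drift) are out of scope, as in the source. The desk-scale landscape is
two orders of magnitude smaller than the study areas, so between-scenario
contrasts are direction-valid but not magnitude-comparable. The
regression stage at n = 10 landscapes runs with a small-sample flag and
is illustrative of the pipeline rather than inferential.
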
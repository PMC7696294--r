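# dietopt

Multi-objective, distance-to-target design of sustainable diets in R.

## The problem

Dietary guidelines are usually judged on one dimension at a time: nutrient
adequacy, *or* greenhouse-gas emissions, *or* cost. `dietopt` implements a
compromise-programming framework that treats all three at once. Every diet
is scored on:

- **Nutrition** — the NRD9.3 nutrient-density index,
  `NRD9.3 = TNR9 − TNL3`, where
  `TNR9 = Σᵢ₌₁⁹ min(NRIᵢ, RVᵢ)/RVᵢ · 100` sums the percent coverage of the
  recommended daily values of 9 qualifying nutrients (protein, fiber, Ca,
  Fe, Mg, K, vitamins A, C, E; intakes capped at the recommendation so
  overconsumption earns nothing) and
  `TNL3 = Σᵢ₌₁³ LNIᵢ/MVᵢ · 100` penalizes 3 limiting nutrients (saturated
  fat, added sugar, sodium). The theoretical maximum is 900.
- **Environment** — cradle-to-consumption GHG emissions
  `GHG = Σᵢ Qᵢ·Eᵢ` (kg CO₂eq/day).
- **Economy** — daily cost `TC = Σᵢ Qᵢ·Cᵢ` (EUR/day).

The three indicators are normalized (`X_NUTR = NRD9.3/900`; emissions and
cost by the maxima over the diet set under comparison) and collapsed into a
single normalized weighted distance to the ideal target
(X_NUTR = 1, X_ENV = X_EC = 0):

```
Dn = sqrt( Σᵢ kᵢ (Fᵢ − Gᵢ)² / n ),   Σ kᵢ = n,  kᵢ ≥ V_L (= 0.2)
```

`Dn` lives in [0, 1]: 0 is a perfectly nutritious, free, zero-emission
diet. An optimizer then searches the daily gram quantities `Qᵢ` minimizing
`Dn` subject to an energy equality (isocaloric diets, 2228 kcal/day by
default), full adequacy (`NRIᵢ ≥ RVᵢ`), limiting-nutrient maxima
(`LNIᵢ ≤ MVᵢ`) and *acceptability* bounds keeping the result close to the
baseline pattern (a ±TV% band, or a `[10%, NV×]` band for baselines far
from target). The package also provides ε-constraint Pareto fronts,
Monte-Carlo sensitivity of the nutrient weighting, the floor-constrained
extremal weighting analysis, and a corrected-emissions metric
`c-GHG = GHG/(RIS·α·NS)` that expresses emissions per unit of affordable,
energy-adequate, nutritious diet.

It is aimed at researchers in nutrition, LCA and food-systems modelling who
want a reproducible, solver-backed implementation of these methods. The
food-level Spanish datasets behind the published benchmark are not
redistributable; the package ships the published aggregate tables (see
`predefined_diet_indices()`, `diet_comparison_factors()`) and a synthetic
food-database generator for method studies.

## Worked example

Distances of the six published Spanish dietary patterns (current
consumption CC, national guidelines NDG, Mediterranean MED,
ovo-lacto-vegetarian OLV, vegan VEG, planetary health PLH), recomputed from
their published normalized indices:

```r
library(dietopt)
distance_table(predefined_diet_indices())
#>   diet dn_uniform dn_max max_aspect dn_min min_aspect
#> 1   CC      0.826  0.968        ENV  0.508       NUTR
#> 2  NDG      0.707  0.839        ENV  0.385       NUTR
#> 3  MED      0.793  0.962         EC  0.426       NUTR
#> 4  OLV      0.543  0.625        ENV  0.357       NUTR
#> 5  VEG      0.389  0.495         EC  0.318       NUTR
#> 6  PLH      0.604  0.749         EC  0.347       NUTR
```

Reading: under equal weighting the vegan pattern is closest to the ideal
(0.389) and current consumption farthest (0.826). The maximal distance of
each diet arises when its least favorable aspect (label column) carries all
the slack weight; the minimal distance always overweights nutrition, each
diet's strongest aspect.

Optimizing a synthetic omnivorous baseline within a ±60% acceptability
band:

```r
db  <- generate_synthetic_database(63, seed = 1)
ref <- default_nutrient_reference()
baselines <- generate_baseline_diets(db, ref, seed = 1)
ctx <- build_normalization(score_table(baselines, db, ref))
optimize_diet(baselines$omnivorous, db, ref, ctx,
              acc = acceptability_spec("tv", tv = 60))
#> Optimized diet 'omnivorous-opt': Dn = 0.4853 (feasible, 7 starts, status 4)
#> NRD9.3 720.8 | TC 2.95 EUR/day | GHG 2.30 kgCO2e/day | X = (0.801, 0.551, 0.602)
```

The optimizer cut the baseline's distance from 0.82 to 0.49 — denser in
nutrients, 39% cheaper and 45% lower-emission — while every food stays
within ±60% of its baseline amount and energy is held at 2228 kcal/day.

A command-line wrapper over the same functions (subcommands `synth`,
`evaluate`, `optimize`, `pareto`, `montecarlo`, `compare`, YAML configs,
run manifests) is installed at `inst/cli/dietopt.R`.

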
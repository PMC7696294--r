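---
title: "Distance-to-target diet optimization: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-to-target diet optimization: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietopt)
```

## The model

A diet is a vector of daily gram quantities $Q_i \ge 0$ over a food
database of $n$ products, each described per gram by its energy density,
twelve nutrient densities, and per kilogram by its retail price $C_i$ and
cradle-to-consumption greenhouse-gas intensity $E_i$. Three indicators
summarize a diet:

* **NRD9.3** nutrient density:
  $\mathrm{NRD9.3} = \sum_{i=1}^{9}
  \frac{\min(\mathrm{NRI}_i,\mathrm{RV}_i)}{\mathrm{RV}_i}\cdot 100 -
  \sum_{i=1}^{3} \frac{\mathrm{LNI}_i}{\mathrm{MV}_i}\cdot 100.$
  Qualifying intakes are capped at the recommendation (surpluses earn
  nothing); limiting ratios are deliberately *not* capped, so a diet that
  doubles the sodium maximum pays the full penalty. Both choices follow the
  index's definition; the uncapped penalty is also what lets badly
  unbalanced diets score far below the 0–900 band that feasible optimized
  diets occupy.
* **GHG** $= \sum_i Q_i E_i$ and **TC** $= \sum_i Q_i C_i$, with the
  explicit gram-to-kilogram conversion inside the aggregation. Quantities
  are treated as consumed amounts feeding both the nutrition and the
  footprint side; an edible/gross split is out of scope.

The indicators are normalized: $X_{NUTR} = \mathrm{NRD9.3}/900$ (the
theoretical maximum), while $X_{ENV}$ and $X_{EC}$ divide by the largest
value *over the set of whole diets being compared*. Normalizing by single
products would be meaningless (no product is a diet), and the resulting
context is **frozen** before optimization: if the denominators moved with
the decision variables, the objective would chase its own scale. Diets
outside the normalization set may exceed 1; that is permitted.

The compromise indicator is the normalized weighted distance to the ideal
point $G = (1, 0, 0)$:

$$D_n = \sqrt{\tfrac{1}{3}\sum_i k_i (F_i - G_i)^2}, \qquad
\sum k_i = 3,\; k_i \ge V_L.$$

Since $F_i, G_i \in [0,1]$ and $\sum k_i (F_i-G_i)^2 \le \sum k_i = 3$,
$D_n \in [0,1]$. The floor $V_L$ (default 0.2) keeps every objective with a
non-negligible voice; without it the minimizer would simply silence the
objectives farthest from target.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| energy target | 2228 | kcal/day | weighted average recommended intake for an adult in the Spanish setting the method was developed for; all diets are compared isocalorically |
| $V_L$ | 0.2 | – | objective-weight floor; the extremal analysis puts $3-2V_L = 2.6$ on one objective |
| RV, MV | config file | per day | EU/EFSA-style adult values; satfat and added-sugar maxima are 10% of the energy target, Na the EFSA safe intake. The benchmark study never published its reference set, so these are clearly-labelled defaults and **no shipped benchmark number depends on them** |
| TV | 60 | % | symmetric acceptability band around the baseline; products absent from the baseline stay absent (TV% of zero is zero) |
| NV | ≥ 1 | × | fallback band $[0.1\,Q_{base},\, NV\,Q_{base}]$ for baselines too distant to fix within ±100% |
| nutrient weights $kr_i, km_i$ | 1 | – | $\sum kr = 9,\ kr \ge 0.5$; $\sum km = 3,\ km \ge 0.2$ |
| consumption income | 29.3 | EUR/day | back-derived: the interval (29.10, 29.52) is the set of incomes reproducing all twelve published residual-income scores at two decimals from the published prices; 29.3 sits inside it and matches the order of national consumption statistics. It is a calibration constant, not an official figure |

## Optimization

`optimize_diet()` minimizes $D_n$ over $Q$ subject to (i) the energy
equality, (ii) adequacy $\mathrm{NRI}_i \ge \mathrm{RV}_i$, (iii) limits
$\mathrm{LNI}_i \le \mathrm{MV}_i$ and (iv) the acceptability box. All
constraints are linear in $Q$; the objective is smooth except for the
capping kinks, and $D_n^2$ is convex. Numerical choices:

* **Solver.** SLSQP (`nloptr`), the standard sequential quadratic
  programming method for small dense NLPs, with analytic gradients.
  Internally the solver minimizes $3 D_n^2$ (same minimizer, no square-root
  singularity at $D_n = 0$).
* **Energy equality as two inequalities** with relative half-width
  $10^{-6}$, which SQP methods handle more gracefully than a hard equality;
  solutions are re-checked against the equality at the same tolerance.
* **Capping kinks.** Inside the feasible region every qualifying ratio is
  ≥ 1, so the capped sum is constant there and the objective is smooth
  where it matters; the kink is only met while iterates are still
  infeasible, where the subgradient (indicator of ratio < 1) is used. The
  exact capped score — not a smoothed surrogate — is evaluated at the
  returned point.
* **Multistart.** Baseline, box midpoint, and uniform draws from seeds
  1–5 by default; the best solution that an *independent* constraint
  re-check (`check_constraints()`) confirms feasible is returned, with the
  solver status and number of starts. On the toy fixtures the best
  objective varies by less than $10^{-4}$ across disjoint seed sets.
* **Scaling.** Adequacy/limit constraints are expressed on the ratio scale
  ($1 - r_q \le 0$, $r_l - 1 \le 0$) so all constraint rows are O(1).
* **Unrestricted mode** bounds each product by the quantity that would
  supply the whole energy target alone — not a restriction, just a finite
  box — and reports the support size, since such optima are typically
  sparse (a handful of products).

`minimal_acceptability_margin()` finds the smallest integer TV for which
the constraint set admits *any* feasible point. Feasibility is monotone in
TV (the boxes nest), so integer bisection is exact; each level is decided
by a phase-1 subproblem minimizing a smooth squared-hinge violation over
the box with L-BFGS-B (no LP formulation is needed, and the violation
profile at the last infeasible level names the binding nutrients). If
±100% does not suffice, the search switches to the NV band on a 0.5 grid —
mirroring how distant baselines (e.g. a vegan pattern short of calcium)
must scale single food groups several-fold rather than stretch everything
symmetrically.

`pareto_front()` implements the ε-constraint method: maximize NRD9.3 (or
minimize GHG) under a cost budget, per budget level, then filter to the
non-dominated set. Relaxing the budget enlarges the feasible set, so the
attainable score is monotone in ε — a property the tests assert.

## Extremal weighting and Monte-Carlo sensitivity

Both the weighted score NRD9.3w (in the nutrient weights) and $D_n^2$ (in
the objective weights) are *linear* in their weights at fixed intakes, so
their extremes over the floor-constrained simplices are attained at
vertices: all slack on one coordinate (weight 5 for a qualifying nutrient,
2.6 for a limiting nutrient or an objective at $V_L = 0.2$), floors
elsewhere. `extremal_weighted_scores()` and `extremal_distances()`
enumerate those vertices exactly; ties are broken by canonical order
(nutrient order; NUTR before ENV before EC).

The Monte-Carlo module samples weights as
$\mathrm{floor} + \mathrm{slack}\cdot\mathrm{Dirichlet}(\mathbf 1)$ — the
flat, maximum-entropy distribution on the shifted simplex. The sampling law
on the constrained simplex is otherwise unspecified in the benchmark
setting; flat-Dirichlet is this package's documented assumption. Draws are paired across diets (the same weight set scores both diets),
which is what a per-draw scatter requires, and no hypothesis tests are
attached to the distributions. Every draw satisfies the sum and floor
constraints to $10^{-12}$, and every sampled score must lie inside the
vertex-enumeration envelope — both are asserted in the tests.

## Corrected emissions

$c\text{-}GHG = GHG/(\mathrm{RIS}\cdot\alpha\cdot\mathrm{NS})$ expresses
emissions per unit of affordable, energy-adequate, nutritious diet. RIS is
$1 - \mathrm{cost}/\mathrm{income}$ (error if the diet is unaffordable);
$\alpha$ is the energy ratio capped at 1 — for energy at or above the
reference we read the score as exactly 1, consistent with the isocaloric
setting, rather than as an inverse ratio; NS is the NRD9.3 ratio to the
reference diet (the planetary health pattern in the shipped benchmark).
Scores at or below $10^{-6}$ raise an error rather than returning an
exploding correction.

## The synthetic generator

Real food-composition, price and footprint databases are licensed and not
redistributable, so the package generates synthetic baskets from
category-conditioned uniform ranges shipped as a versioned YAML config
(`inst/extdata/synthetic_ranges.yaml`). The ranges encode the gross
structure that drives the method: ruminant meat is an order of magnitude
more GHG-intensive than vegetables, legumes are fiber/K/Fe-rich, dairy and
fortified drinks carry calcium, oils are energy-dense and vitamin-E-rich.
Values are order-of-magnitude realistic for European retail foods (legumes
on a dry basis; added sugar is a database column like any nutrient, with no
disaggregation from total sugars).

Baseline diets allocate pattern-specific grams per category (omnivorous,
Mediterranean-like, fully plant-based), split within category by a seeded
Dirichlet draw, then pass through a deterministic *adequacy repair* loop:
scale to the energy target, shrink the top-contributing category of any
limiting-nutrient excess, boost the best per-kcal source category of the
worst deficit, repeat. This mirrors how guideline diets are formulated — by
construction they meet reference intakes — and gives baselines that are
feasible at TV = 0, so the improvement and band-monotonicity properties can
be exercised on the full TV grid. Real *current-consumption* patterns are
typically not adequate at baseline; that case is covered by the
minimal-margin search, tested on constructed fixtures with known
thresholds (a diet deficient only in calcium, fixable exactly at TV = 30).

What the generator does **not** emulate: correlations between nutrients
within a product beyond category structure, seasonal/regional price
variation, processed-food fortification, or the specific Spanish basket
behind the published tables. Passing tests on synthetic data therefore
demonstrate *method* properties (feasibility, monotonicity, improvement,
envelope bounds), not the published food-level results; the published
aggregate tables are shipped separately and reproduced exactly by the
distance, normalization and corrected-emissions modules.

## Problem sizes and determinism

The shipped tests run the full pipeline on a 63-product basket with three
baselines and the TV grid {10, 20, 40, 60} (about a dozen SLSQP solves, a
few seconds each), a 28-product basket for the unrestricted mode, 1000
Monte-Carlo draws (10⁵ for the symmetry check), and 1-gram grid oracles on
3-product toys. All randomness flows through explicit integer seeds via an
RNG-state-preserving wrapper, so every result in the package, the tests and
the acceptance script is bit-reproducible.

## Known limitations

* The NRD9.3 capping makes the score flat in covered nutrients, so
  optimized diets are indifferent between "just adequate" and "generous"
  qualifying intakes; other profiling indices (per-100-kcal variants) are
  out of scope.
* Acceptability bands never introduce products absent from the baseline;
  promoting genuinely new foods requires the unrestricted mode.
* SLSQP finds local optima; $D_n^2$ is convex over the polytope so
  multistart consistency is expected, but the epsilon-constraint fronts
  with the capped (piecewise-linear) score can have flat regions where the
  reported cost at a given budget is not unique.
* Single environmental dimension (GHG); land, water or pesticide footprints
  would need additional columns and objectives.
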
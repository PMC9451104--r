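---
title: "A coupled logistic–replicator model of human–plant coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled logistic–replicator model of human–plant coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevosim)
```

## The model

`coevosim` simulates two populations — humans $H$ and a plant species
$P$ — linked by mutualism. Each population grows by a discrete-time
Verhulst–Pearl logistic map,

$$H_{t+1} = H_t + r_H H_t - \frac{r_H H_t^2}{K_{H,t}}, \qquad
  P_{t+1} = P_t + r_P P_t - \frac{r_P P_t^2}{K_{P,t}},$$

whose carrying capacities are not constants but are built, at every
step, from what the *other* population currently provides plus a
baseline from other resources:

$$K_{H,t} = U_{PH,t} + U_{bH,t}, \qquad
  K_{P,t} = \min(U_{HP,t} + U_{bP,t},\ \mathrm{MaxArea}).$$

The `max_area` cap is the single asymmetry between the two populations:
plants must grow contiguously in a finite area, humans have no
predefined ceiling.

Each population is split into $n$ ordered *types*, from least (1) to
most ($n$) mutualistic, with shares $\mathrm{pop}_i$ summing to one.
Per-type quantities — the utility per capita one individual contributes
to the partner population, and the baseline utility a type can extract
from other resources — are linear interpolations between their type-1
and type-$n$ endpoint parameters (`type_values()`). Aggregate utilities
are share-weighted sums scaled by population size, e.g.
$U_{HP,t} = H_t \sum_i \mathrm{pop}_{H_i,t}\, \bar U_{H_iP}$.

Type shares evolve by replicator dynamics. Selection couples the two
populations: the fitness of type $i$ weighs the baseline (favouring the
wild end) against the partner's contribution (favouring the mutualistic
end),

$$\mathrm{fitness}_{H_i,t}
  = \frac{(n_H - i)\,U_{bH,t} + i\,U_{PH,t}}{U_{bH,t} + U_{PH,t}},$$

so that whichever income source dominates the carrying capacity also
decides which end of the type spectrum is favoured. Before selection, a
deterministic *undirected variation* step relaxes the shares towards
uniformity by a fraction $v$, standing in for mutation or innovation.
This produces a double positive feedback: more partners raise the
carrying capacity (mutualism), and a larger partner contribution tilts
selection towards stronger mutualism types (coevolution).

## Order of operations and determinism

One call to `coevo_step()` is a synchronous map. All diagnostics —
utilities, carrying capacities, fitness vectors, coefficients — are
computed from the time-$t$ state; then populations advance with the
time-$t$ capacities, and type shares undergo variation followed by the
replicator update with the time-$t$ fitness. We apply variation before
selection because that is the narrative order of the mechanism
(innovation seeds types, selection then amplifies them); both orders are
mathematically valid, and the choice is frozen here as the package's
definition of the map. Despite the word "undirected", variation is a
deterministic relaxation — no random number generator appears anywhere
in the dynamics, so every trajectory is exactly reproducible and the
run-level tests can be exact.

## Degenerate inputs

Three situations make the printed update rules undefined; the package
declares explicit continuations for each:

* **Zero carrying capacity.** The logistic density term divides by $K$.
  When $K = 0$ the update becomes geometric decay
  $\mathrm{pop}\,(1 - r)$ clipped at zero: a collapsed capacity drives
  extinction rather than a division error.
* **Zero mean fitness.** If $\sum_i \mathrm{fitness}_i\,
  \mathrm{pop}_i = 0$ the replicator ratio is undefined; the share
  vector is returned unchanged and the step is flagged (`stagnant`).
* **No selection signal.** If both utilities entering a fitness vector
  are zero, a vector of ones (pure neutrality) is returned.

Type shares are renormalized whenever accumulated floating-point drift
moves their sum away from one, keeping the unit-sum invariant to
1e-12 over arbitrarily long runs.

## Initial conditions

The type distributions at $t = 0$ default to all mass on type 1 for
both populations — a wild, pre-mutualistic baseline — and can be
overridden (`initial_type_proportions_*`). With $v > 0$, variation
seeds the other types in the first steps.

## Convergence, classification and timing

A run ends when both population levels *and* both type distributions
are stable: every absolute one-step change strictly below
$10^{-\epsilon}$ (default $\epsilon = 6$), or at `max_iterations`
(default 5,000) otherwise. The absolute form of the criterion is used
deliberately; one tolerance for levels and shares keeps the contract
simple.

The coevolution coefficient summarises a type distribution on
$[-1, 1]$:
$\mathrm{coevo} = 2 \sum_i \mathrm{pop}_i \frac{i - 1}{n - 1} - 1$,
with $-1$ all-type-1 and $+1$ all-type-$n$. The dependency coefficient
is the OLS slope of the fitness vector against the type index, computed
directly rather than through its closed form. Converged runs are
classified against the threshold `coevolution_threshold` (default 0.5):
both coefficients above it is `full_coevolution`, exactly one is
`partial_stationary`, neither is `no_coevolution`. The same printed
threshold is reused for the partial class rather than inventing a
second cutoff.

Runs interrupted at the cap are checked for oscillation: over the last
10% of recorded steps, a population oscillates if its variance exceeds
$10^{-2} \max(\text{mean}^2, 10^{-6})$ — i.e. a squared coefficient of
variation above 1%, with a floor that avoids dividing by a vanishing
mean. This operationalizes "enters an oscillatory state" without
spectral machinery; no printed cutoff exists for separating oscillation
from very slow drift, so interrupted non-oscillating runs fall back to
the stationary rules with a warning.

Timing (`timing_humans`, `timing_plants`) registers the first crossing
of the coevolution threshold that *persists* to the end of the run,
rather than the raw first crossing: oscillating coefficients cross
repeatedly, and the timing concept presumes a completed shift.

## Parameters

All parameters are validated at construction (`coevo_params()`).
Population units are deliberately abstract — organisms or any explicit
proxy — so utilities are expressed in carrying-capacity units per
individual. The defaults are a frozen reference setting chosen once so
that the dynamics display the canonical full-coevolution anatomy (see
the presets below): growth rates $r_H = 0.05$, $r_P = 0.1$ per step,
variation $v = 0.01$, ten types per population, plant baselines
declining from 100 (type 1) to 20 (type $n$), human baselines 10 to 2,
cross-utility endpoints $\bar U_{P1H} = 0.15$, $\bar U_{PnH} = 1.5$,
$\bar U_{H1P} = 0.5$, $\bar U_{HnP} = 5$, and `max_area` 1000.

```{r}
p <- coevo_params()
run <- run_coevo(p)
run
```

```{r, fig.width = 7, fig.height = 5}
ggplot2::autoplot(run)
```

## Shipped presets

`coevo_presets()` freezes four settings, one per qualitative regime.
Only fragments of the regimes' canonical parameterisations are fixed by
the model's description (the plant baselines 100/20; the flat
human-to-plant utility 0.5 of the partial regime); every other value is
a package fixture choice, frozen and never tuned thereafter.

* `full_coevolution` (the default): both populations transit; the
  population curve is a double sigmoid (a pseudo-stable plateau near
  the baseline capacities, then a boom to the coevolved equilibrium),
  and the plant carrying capacity shows a transient dip — the "bump"
  that appears when the stronger mutualism types are worse at
  exploiting other resources ($U_{bP1} > U_{bPn}$) and the plant
  baseline collapses before the human contribution has grown enough to
  compensate.
* `no_coevolution`: identical except the plants' type-1 utility to
  humans is lowered to 0.05, below its tipping point; both populations
  settle near their wild baselines.
* `partial_oscillatory`: humans contribute 0.5 regardless of type,
  weakening the plant-side feedback so only the human population
  transits.
* `decoupled`: all cross-utilities zero and $v = 0$; two independent
  logistic maps whose end-states are the type-1 baselines exactly —
  the analytic anchor used by the tests.

## Parameter-space exploration

`run_sweep()` executes one run per row of a parameter table and returns
a tidy tibble; `grid_points()` builds factorial designs.
`sample_lhs()` draws Latin hypercube designs: each marginal is
stratified into $n$ bins with one sample per bin, and among 20
candidate hypercubes the one with maximal minimum pairwise distance
(best-of-$k$ maximin) is kept. This space-filling criterion replaces a
point-process (Strauss) optimization of the design: the intent —
well-spread samples — is the same, and the maximin criterion needs no
point-process machinery; this is a documented deviation. Because no
canonical ranges exist for the 15 non-initial parameters, ranges are
mandatory inputs; `inst/extdata/lhs_ranges_example.yaml` documents an
example spanning weak-to-strong mutualism around the reference setting.

`rank_importance()` fits a random-forest regression of a run-level
output on the sweep's parameter columns (initial populations excluded
by default: they have virtually no effect on end-states), tunes tree
count and predictors-per-split by 10-fold cross-validation, and reports
the out-of-bag permutation importance (%IncMSE) — used for the ranking
— alongside the impurity decrease (IncNodePurity), which is reported
but never ranked on, being the less robust of the two measures.

`find_tipping_point()` bisects one parameter axis between two settings
with different end-state classes until the bracket is $10^{-3}$ of its
initial width. Near such thresholds the dynamics exhibit critical
slowing: `time_end` grows severalfold relative to settings far from the
boundary.

## What the tests do and do not show

The test suite verifies the machinery against independent oracles (a
straight-line transcription of the composed update, `lm()` for the
dependency slope, brute-force re-scoring of the maximin candidates),
the analytic limits (decoupled equilibria, fitness rank orders,
replicator fixed points), structural invariants (share conservation,
nonnegativity, the `max_area` cap, mirror symmetry under swapping the
two populations' parameter blocks), and the qualitative regimes of the
four presets. The sensitivity pipeline is exercised at a reduced,
desk-scale design — 500 Latin hypercube points over the 15 non-initial
parameters, repeated over five seeds with majority voting — rather
than a production-scale exploration (10,000 points), which remains
available as a documented long-running command:

```sh
coevosim lhs --ranges ranges.yaml --n 10000 --seed 1 --out sweep.csv
coevosim importance --sweep sweep.csv \
  --target coevolution_coefficient_humans --out ranking.csv
```

Passing these tests shows the simulator implements its stated map and
that the stated regimes exist and are robustly classified under the
frozen fixtures. It does not validate the model against empirical
population or archaeobotanical data: the model is a theory-building
instrument, populations are dimensionless proxies, types are an
artefact of discretizing a continuum, and deterministic variation
ignores finite-population drift.

## Known limitations

* No spatial structure; `max_area` is the only spatial abstraction.
* No stochastic drift: type shares are deterministic frequencies, so
  rare-type extinction cannot occur (shares decay but never hit zero
  unless they start there).
* The oscillation rule is a variance heuristic, not a limit-cycle
  characterization; borderline slow-drift cases at the iteration cap
  are classified with a warning rather than a dedicated class.
* Tipping-point bisection assumes a single class boundary inside the
  bracket, which holds along facilitator axes but is not guaranteed
  globally.
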
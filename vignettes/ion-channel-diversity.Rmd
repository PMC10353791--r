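---
title: "Ion-channel diversity and the geometry of valid parameter space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-channel diversity and the geometry of valid parameter space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelpop)
```

## The question

Neurons of a given type express many more ion-channel species than seem
necessary to produce their firing repertoire, and channels within a family
(delayed-rectifier potassium channels, high-voltage-activated calcium
channels, ...) overlap substantially in function. `channelpop` implements a
population-of-models pipeline for asking what this degeneracy buys a
neuron: how does the *number* of partially redundant channels affect the
density of valid models in conductance space, their stability under
parameter drift, and the connectedness of the valid region?

The package has two legs. The first is a compact surrogate family of
conductance-based dentate granule-cell models with 5-, 9- and 15-channel
rosters, a spike-feature fitness, a derivative-free search, and the
population protocols (random sampling, range sweeps, random walks,
knockouts, isoform expansion, hyperplanes). The second is a probabilistic
toy model that strips the biophysics away and reduces the phenomenon to the
law of large numbers, with exact analytic oracles.

## The surrogate model family

The original granule-cell model this family emulates is a detailed
multi-compartmental reconstruction with published channel kinetics; neither
the morphology nor the kinetics are reproduced here. Instead the surrogate
uses three coupled isopotential compartments — soma (2000 um^2), axon
initial segment (200 um^2) and a lumped dendrite (8000 um^2), specific
capacitance 1 uF/cm^2 — and gives every channel Boltzmann/Hill gating:

* voltage gates follow
  $x_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k})$, with a Gaussian-bell
  time constant
  $\tau(V) = \max(\tau_{min},\ \tau_{base} + \tau_{amp}
  e^{-(V - V_\tau)^2 / 2\sigma_\tau^2})$;
* calcium gates follow a Hill function of the compartmental calcium
  concentration, which is a first-order pool fed by the inward calcium
  currents (ohmic, fixed +120 mV reversal; no GHK flux, for simplicity and
  testability).

All kinetic constants are engineering defaults of this surrogate, chosen
once so that the baselines rest near −80 mV and fire a handful of spikes
(3–10) during a 200 ms, 90 pA somatic step. They are not fits to
measurements, and no quantitative agreement with the original cell's
parameter values is claimed.

Two design decisions matter for everything downstream:

* **Region-resolved parameters.** A conductance parameter is a (channel,
  region) pair: `na8st@AIS` is independent of `na8st@soma`. The rosters
  expose 9, 13 and 27 parameters for the 5-, 9- and 15-channel models. The
  passive backbone (`pas`, `Kir21`) is frozen everywhere: it sets input
  resistance and resting potential and is never sampled or searched.
* **Class-conserving densities, isoform-like kinetics.** Channels are
  organized in functional classes (one sodium channel; BK plus the Kv and
  SK channels as repolarizers; Cav22/Cav12/Cav13/Cav32 as calcium sources).
  Across rosters, a class's summed baseline density is approximately
  conserved and split over the members present; members of a class differ
  by modest shifts in midpoints and time constants, the way isoforms do.
  This is the structural assumption that makes the family express
  degeneracy: the reduced model concentrates the same machinery in fewer
  knobs. Channels with genuinely unique function in the roster (the slow
  M-type `Kv723`, the calcium-gated `SK`, the low-threshold `Cav32`) are
  kept at modest densities; their loss or doubling is exactly the kind of
  perturbation a diverse roster can absorb and a reduced one cannot.

### Integrator

The simulator is a fixed-step scheme in compiled code: exponential-Euler
updates for the gates (from tabulated $x_\infty$ and $\tau$ curves, table
step 0.05 mV) and an implicit (backward-Euler) voltage update over the
coupled compartments. The implicit update makes the discrete charge balance
$C\,\Delta V/\Delta t = -(I_{ion} + I_{axial}) + I_{inj}$ hold to machine
precision at every step, which the test suite checks directly. Gate time
constants are floored at $\tau_{min} = 0.05$ ms to bound stiffness. Each
simulation starts with an unstimulated settle-in that defines the resting
state.

Two solver settings are used, both validated by the same convergence tests:
dt = 0.025 ms (500 ms settle) for single-trace work and the quantitative
simulator checks, and a coarser dt = 0.1 ms (300 ms settle) for
population-scale experiments, where tens of thousands of evaluations are
needed. Feature targets are always generated with the same solver that
evaluates the candidates, so validity is internally consistent at either
setting. Because the integrator is first order, the sup-norm difference
between traces at successive dt halvings is dominated by small spike-time
shifts; it decreases monotonically under refinement (tested), but
pointwise-tight agreement across dt is only meaningful for subthreshold
responses (also tested).

## Features, fitness and validity

Nine spike features are extracted from the standard protocol (50 ms
prerun, 200 ms somatic step at 50 and 90 pA, 50 ms tail): spike count,
latency of the first spike, voltage threshold (where dV/dt first exceeds
15 mV/ms), mean spike amplitude, signed and absolute fast
after-hyperpolarisation (threshold minus the minimum within 5 ms after the
peak; positive when the trough undershoots the threshold), half-height
spike width, first interspike interval, and the adaptation index
$AI = 1 - ISI_1/ISI_{end}$.

Fitness is multi-objective: each feature's deviation from its target mean
is expressed in units of the target SD,
$F_i = |SF_i - \overline{SF}_i| / SD_i$, and the Pareto efficiency
$P = \max_i F_i$. A model is valid iff $P < 2$ (strict). Non-spiking
models (no spikes at either amplitude) receive the sentinel $P = 6$.
Features are computed at both amplitudes and the maximum runs over all
defined (feature, protocol) pairs; features undefined in the candidate or
the reference (e.g. no second ISI) are skipped, because the criterion is
only computable over defined features.

The original study compared models against experimental feature statistics
that are not public. The fixtures module emulates them: target means are
the reference model's own features, and SDs are `0.2 x |mean|` floored at
per-feature values (0.5 spikes, 1 ms, 1 mV, 0.05 for the unitless
adaptation index). The floors prevent division blow-ups where a mean is
near zero; the 0.2 fraction gives the baseline neighbourhood the expected
qualitative structure (high validity near the baseline, decaying with
range). In practice the binding features under random sampling are the
spike count and the adaptation index — the voltage-valued features get
proportionally wide SDs — which mirrors the role of discrete/ratio
features in the original cost.

## The search

`conjugate_direction_search()` is a Powell-style derivative-free method:
successive line minimizations along a maintained direction set, with the
direction of largest decrease periodically replaced by the sweep's
aggregate displacement. Line minimization uses multiplicative bracketing
(initial relative step 5%, golden-ratio expansion, golden-section
refinement, at most 20 evaluations). Two escape mechanisms handle the flat
plateaus that non-spiking models create: the step escalates in 5-point
increments to ±50%, and if the landscape is still flat the point is
randomized coordinate-wise over a range growing from ±10% to ±50%, after
which the direction set is reset to the coordinate axes. "Stalled" is
declared after two full escalation-plus-randomization cycles without an
improvement above 1e-6. Every evaluation is accounted in an event log,
which the tests reconcile against the evaluation counter exactly.

## Population protocols

* **Random populations**: free densities sampled independently and
  uniformly in 0–2x the baseline; validity classified at $P < 2$; the
  fraction reported with a Wilson 95% interval.
* **Range sweeps**: uniform sampling in $[1-w, 1+w]\times$ baseline.
* **Random walks**: every free parameter multiplied by an independent
  uniform factor in [0.95, 1.05] per step, halting at the first invalid
  state; ensembles report the survival histogram (bin width 4) and mean.
  The walked set is exactly the sampled (non-frozen) set.
* **Knockout refits**: a channel's densities are zeroed and frozen, and the
  remaining free parameters are reoptimized against the intact baseline's
  targets.
* **Isoform expansion**: the 5-channel model gains k artificial isoforms of
  BK and Cav22 (alternating), each with every gate time-constant parameter
  rescaled by an independent uniform factor in [0, 2); parent densities are
  split evenly over the copies; candidates are sampled in 0–2x, the best
  three refined by the search, and the best refined model becomes the new
  baseline.
* **Hyperplanes**: pairwise convex combinations at weights 0.1–0.9 (step
  0.1; connected iff all nine are valid) and triplet grids over weights
  −1.5–2.5 (step 0.04, 101 values per axis; third weight = 1 − w1 − w2;
  combinations with any negative parameter are masked). The regular grid
  does not contain the unit-weight vertices, so those three points are
  appended explicitly and flagged — this keeps both the published grid and
  exact vertex recovery.

## The toy model

Each conductance becomes a uniform random variable on [0, 2] around the
set point 1; a model is valid when its variables' mean deviates from 1 by
strictly less than 0.015. The valid fraction then follows the Irwin–Hall
distribution exactly, and `analytic_valid_fraction()` is the package's
oracle: the exact alternating-sum CDF up to n = 25 variables, and an
Edgeworth (kurtosis-corrected normal) approximation above, where the exact
sum loses too many digits to cancellation in double precision (the
skewness term vanishes for the symmetric interval, so the remaining error
is far below Monte Carlo resolution).

Variants: a Gaussian copula with equicorrelated latent structure imposes
positive correlations (feasible only for $\rho \ge -1/(n-1)$); a
"distributed" sampler places each new variable uniformly in the largest
gap of the existing ones (boundary gaps included, ties to the lowest left
endpoint), producing anti-correlated, evenly spread rows; and nonlinear
interaction orders pass the rows through left-stochastic random interaction
matrices and the sigmoid $S(x) = -1 + 2/(1+e^{-x})$. The validity rule for
the nonlinear orders is not prescribed anywhere, so the package defines the
reference output as the transform of the all-ones row under the same
matrices and keeps the same 0.015 tolerance on the mean output deviation —
preserving the "distance to a designated target" semantics.

Two estimator choices are worth stating. `toy_lln_curve()` defaults to
conditional Monte Carlo (each row's validity indicator replaced by its
exact conditional probability given all but the last variable) with common
random numbers across n. Both choices are standard variance-reduction
techniques; they change no estimand, but they make adjacent-n comparisons
(the strict monotonicity of the valid fraction in n) stable at 1e5 rows,
where the plain indicator estimator inverts adjacent values in a sizeable
fraction of seeds. The plain estimator remains available.

## Problem sizes and what the tests show

The test suite exercises the study protocols at reduced sizes chosen to
keep a full run modest on one CPU: populations of 500 per model (the
original used 20,000), 200 random walks capped at 200 steps (originally
2,000 uncapped), range sweeps of ~400 per width (originally 5,000), toy
experiments at 1e5–1e6 rows. These sizes resolve the qualitative claims
(orderings, signs, monotonicities) with comfortable margins; they do not
pin down the original study's percentage values, which depend on the
unpublished kinetics and experimental targets in any case.

What passing tests do show: the integrator is quantitatively correct where
closed forms exist; feature extraction is dt-exact on constructed ground
truth; the fitness and search behave per their definitions against
independent oracles; and the emergent claims — valid fraction, walk
survival and neighbourhood validity all increasing with channel diversity,
isoform expansion recovering robustness, knockout compensation succeeding
only in the diverse model — hold in this surrogate family. What they do
not show: anything about real granule cells beyond the structural
mechanism, since the surrogate's kinetics, targets and noise model are
synthetic. The toy-model results, by contrast, are exact claims about the
stated distributions and are verified against analytic oracles.

## Known limitations

* The surrogate's 9-channel model can compensate a BK knockout under the
  default budgets; in the original study neither reduced model could. The
  5-vs-15 contrast, which the acceptance checks assert, is robust.
* The fAHP sign convention ("threshold minus trough") is one of two
  defensible readings; both the signed value and its absolute value are
  reported as separate features.
* Hyperplane triplet grids are computed with the coarse evaluator only in
  the examples; at full dt they are the most expensive protocol in the
  package.
* No temperature dependence, no adaptive-step solver, no morphology import,
  and no HCN channel, by design.
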
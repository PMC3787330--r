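---
title: "Methods: executable statecharts for thymocyte dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: executable statecharts for thymocyte dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymostate)
```

## The formalism

Immunologists describe developing T cells in terms of state transitions:
a thymocyte differentiates (DN → DP → SP4/SP8) *while* cycling between
quiescence (G0) and division (S/M) *while* advancing through cell
generations. `thymostate` makes that description executable. A model is a
set of **orthogonal regions**, each an ordinary state machine; a cell
occupies one state per region simultaneously. Transitions live inside one
region and carry a rate (1/day in the shipped models), a kind (`flow`,
`division`, `export`, `death`), an optional **guard** (a conjunction of
state tests on the other regions, e.g. division only when
`cell_cycle == SM`) and an optional **reset** map applied on firing (so
daughters of a division re-enter G0). The reserved pseudo-state `EXIT`
absorbs deaths and thymic export as named cumulative outflow channels.

The same document drives two backends:

* **Population backend.** The parallel regions are flattened to their
  product states (minus declared *exclusions*, combinations that do not
  exist biologically, such as cycling late-DP cells). Each flat state
  `i` becomes one scalar equation of the conveyor-belt form

  $$\frac{dx_i}{dt} = 2\gamma p\, x_{i-1} - (p + d + u_i)\, x_i + \dots$$

  where division removes the parent at rate $p$ and injects $2\gamma p$
  into the next-generation state, $d$ collects death, and $u_i$ the
  generation-indexed differentiation rate.

* **Agent backend.** The same statechart is interpreted per cell in
  discrete time with competing-risks sampling (below), which is what
  licenses the mean-field comparison in `compare_mean_field()`.

## Rate expressions and linearity

Rates are written against the parameter table plus the reserved
generation index `i` (the cell's position in the region named
`generation`). Only affine forms (`u0 + s*(i-1)`) and per-generation
table lookups (`Us4[i]`) are accepted; the state vector can never appear
in a rate. Every compiled system is therefore **linear**,
$\dot x = A x + s$, which has two consequences we exploit deliberately:

1. **Exact integration.** `integrate_ode()` propagates the augmented
   vector (states, cumulative channels, constant source) with the matrix
   exponential of the augmented generator between time points. There is
   no step-size error and no stiffness concern; accuracy is machine
   precision, which more than meets the 1e-8/1e-10 tolerances a numerical
   solver would have been configured with. Negative round-off is clipped
   to zero only on output, never inside the propagated state, so
   bookkeeping identities survive. A piecewise-constant $\gamma(t)$
   schedule (ganciclovir windows) inserts its breakpoints into the
   propagation grid, so the discontinuity costs no accuracy either.
2. **Readable equations.** `export_equations()` writes one line per flat
   state using parameter names (with the generation index substituted),
   and each right-hand side is valid arithmetic that an independent
   evaluator can re-execute — the test suite does exactly that.

## The conveyor-belt model

`build_conveyor_model()` instantiates the generation-structured thymus
model: regions `differentiation` (DN, DP_early, DP_late, SP4, SP8),
`cell_cycle` (G0, SM) and `generation` (g1…g6). Progenitors flow in at
`Sn` cells/day into (DN, G0, g1); cells enter S/M at their stage's
proliferation rate (`Pn`, `Pp`, `Ps`) and, on completing division, move
to the next generation with the cycle reset to G0. Differentiation rates
increase affinely with generation, `u_i = u0 + s(i-1)`, which is what
makes the belt move: the more a cell has divided, the likelier it is to
progress. Late DP cells are quiescent-only (an exclusion removes every
DP_late × SM combination), which is also what shields them from
ganciclovir: setting $\gamma = 0$ kills any cell that completes S/M
(both would-be daughters are diverted to an apoptosis channel, keeping
mass accounted) and late DP has no S/M states to lose.

Structural choices that were genuinely open, and how we fixed them:

* **The 30-state split.** The flat system is known to have 30 equations
  but not its decomposition; we use DN 4 generations × {G0, SM},
  DP_early 6 × 2, DP_late 2 × {G0}, SP4 2 × 2, SP8 2 × 2 = 30. All
  counts are configurable (`conveyor_config()`), and non-default
  configurations are allowed with a warning.
* **Saturating generation cap.** Daughters at a stage's last generation
  divide back into that generation. The alternative (an absorbing
  non-dividing cap) changes the totals' growth law; saturation keeps the
  per-capita division outflow $p$ uniform across generations, matching
  the general flux law, and avoids unbounded state space.
* **Generation carry-over into late DP.** With a naive generation reset,
  late DP's second generation would be unreachable (it never divides), so
  entry from DP_early carries the generation over, capped at the late-DP
  count.
* **Selection semantics.** `a4`/`a8` act as DP_late → SP4/SP8 rates, with
  DP death `Dp` absorbing negative selection and neglect; the source
  material lists the selection rates without separating those channels.
* **Default rates are placeholders.** `Sn = 1e4`/day, `P* = 0.2`/day,
  `D* = 0.05`/day, `a4 = 0.08`, `a8 = 0.02`, `Us4 = Us8 = 0.5`/day,
  `u0 = 0.05`, `s = 0.05`/day per generation. They were chosen once for
  plausible magnitudes and a stable steady state (every compartment has
  positive outflow, so $x^\* = -A^{-1}s$ exists and is unique); the
  original models' fitted values live in their own publications and are
  deliberately not claimed here. Every value is overridable in
  `models/conveyor_belt.yaml`.

## The agent scheduler

`step_world()` advances every agent by `dt` (default 0.01 days):

* Per region, at most one enabled transition fires, chosen by competing
  risks: the region fires with probability $1 - e^{-R\,dt}$
  ($R$ = summed enabled rates) and the branch is drawn proportional to
  rate. This is exact for a single step of the embedded continuous-time
  chain; the $O(dt)$ error of treating regions independently within a
  step is the usual discrete-time embedding cost, and `new_world()` warns
  if any state's total rate times `dt` reaches 0.5.
* Agents are visited in a freshly shuffled order (relevant for the
  spatial model's occupancy conflicts; for non-spatial models the update
  is order-free and processed vectorized).
* Division resolves after the region transitions and is skipped if the
  agent also fired another region that step, so a cell cannot divide and
  differentiate simultaneously at coarse `dt`.
* All randomness flows from one seeded stream; replicate $r$ of a sweep
  uses `seed + r`. Fixed seeds reproduce runs bit for bit.

**Mean-field comparison.** `compare_mean_field()` runs the same model
through both backends from the same initial condition and reports, per
flat state and time, $z = (\bar x_{ABM} - x_{ODE})/\mathrm{se}$. The
standard error of the replicate mean is floored at the Poisson counting
noise $\sqrt{x_{ODE}/R}$: with 20 replicates the sample standard
deviation of a state holding a fraction of a cell is 0 (every replicate
sees none), which would make $z$ infinite, and small-count sample
standard deviations fluctuate low, which would inflate $|z|$ spuriously.
The floor is the irreducible noise of the counting process, not a tuned
constant. Note that $z$ is standardized, so it does *not* shrink with
more agents; the quantity with the $1/\sqrt{N}$ Monte-Carlo scaling is
the relative error, reported as `rel_mse`.

## The spatial model

`run_thymus_lattice()` implements the 2-D migration/selection model:
a rectangular lattice with banded anatomy (subcapsular rows on top,
cortex, medulla, and the bottom row as the egress edge), an epithelial
network placed uniformly at random at an exact site fraction, and static
chemokine gradients — concentration $\max(0, 1 - d/D)$ of the Chebyshev
distance to the attractor band. DN and DP follow CXCL12 (cortex),
immature SP follow CCL19/CCL21 (medulla), mature SP follow S1P (exit).
Movement is greedy along the stage's gradient with probability
`1 - noise` (strictly-better vacant Moore neighbor, ties uniform) and
uniformly random otherwise; at most one thymocyte per site, and bound
cells do not move.

While adjacent to epithelium a cell binds at `k_on` and unbinds at
`k_off`; its log accumulates the interaction count, cumulative bound
time and longest single interaction. Selection is evaluated in priority
order: cumulative bound time above `T_neg` → negative selection (even if
the positive threshold was also reached); interaction count at or above
`theta_pos` → positive selection; stage clock past `T_neglect` →
death by neglect. At DP positive selection the signal-duration rule
assigns CD4 if the longest single interaction reached `tau_lineage`
(boundary inclusive), else CD8. These semantics — count drives positive
selection, cumulative time drives negative selection, single-interaction
duration drives lineage — are one consistent reading of the qualitative
description; the original automaton's exact bookkeeping is not public.
All thresholds are placeholders in `models/thymus_lattice.yaml`. The
DN → DP step uses a fixed cortical dwell time (default 10 time units)
because thresholds are described only for DP and SP.

## What the tests do and do not establish

The synthetic fixture generator (`generate_fixture_model()`) produces
random valid statecharts: chain-connected regions, non-negative rates,
optional divisions, guards and sources. A green oracle sweep establishes
that the compiler implements the flux law exactly on that family — not
that any default rate matches a measured thymus. Likewise the mean-field
criterion establishes backend consistency (the agent interpreter and the
compiler execute the same model), not biological accuracy: the shipped
parameter values are documented placeholders, the gradients are static,
there is no TCR affinity model (interaction stochasticity stands in for
it), and the 2-D banded anatomy is a deliberate simplification of
thymic lobule geometry.

## Numerical and degenerate-input conventions

* Flat-state ordering is lexicographic by region order then state order;
  indices are 0-based and contiguous — no hash-order dependence.
* A division whose target combination is excluded saturates: the
  transition's own region keeps its source state (resets still apply).
  A *flow* into an excluded combination is a compile error instead.
* Zero-rate transitions are kept in the compiled flux table so channel
  names and exported equations are structurally stable.
* `rate_to_prob()` is $1 - e^{-r\,dt}$, exact for one transition.
* Ganciclovir windows are half-open $[t_{on}, t_{off})$ and must be
  disjoint; an empty schedule means $\gamma \equiv 1$.
* Empty models (exclusions eliminating every product state) and
  selectors matching no flat state are errors, not silent no-ops.
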
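---
title: "Model and methods behind cprsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind cprsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprsim)
```

## The modeled system

`cprsim` simulates small groups (four agents by default) that repeatedly
harvest a renewable common-pool resource over a short horizon (14 ticks,
mirroring a 14-round behavioral experiment). The scientific question is
when such groups manage the resource cooperatively and sustainably, and how
that depends on who holds accurate ecological knowledge, who communicates
it, how confidently it is communicated, and how much the group members
trust each other.

### Resource dynamics

The resource follows a stepwise discrete logistic growth rule. The stock
lives on `[0, 50]`. After harvesting, the stock regenerates by a per-tick
amount that is piecewise constant on 5-unit stock bins:

```{r}
default_regen_table()
```

The default table is `floor(0.72 * s * (1 - s / 50))` evaluated at the
lower edge of each bin: regeneration is zero below stock 5 (the
regeneration threshold), rises to a unique maximum of 9 units per tick on
the 25–29 bin, and falls back to zero at the carrying capacity 50. The
maximum sustainable yield (MSY) is therefore 9 per tick.

A tick's stock update is
`new_stock = clamp(stock - extraction + regen(stock - extraction), 0, 50)`
with extraction capped at the available stock (`resource_step()`).

### The optimal benchmark

`optimal_policy()` computes the harvest plan a perfectly informed sole
manager would follow, by value iteration over the integer stock space with
greedy tie-breaking toward larger extraction (200 sweeps, which converges
to the long-run-average-optimal stationary policy for this small chain; no
terminal liquidation value, so the policy does not strip the stock on the
last tick). On the default table the policy from the full stock is:
extract 25 in the first tick (dropping the stock to 25, which regrows by
the MSY to 34), then extract 9 every tick, holding the post-harvest stock
at 25 and the reported stock at 34. The lowest stock from which the
optimal manager harvests again — the recovery threshold — is 34, and the
reported stock band corresponding to MSY harvesting is 34–38
(`msy_stock_band()`).

### Agents

Each agent carries four state variables:

* **knowledge** — its perception of the optimal (maximum-regeneration)
  stock size, in `[5, 50]`;
* **confidence** — how certain it is of that perception, in `[0, 1]`;
* **trust** — how much it expects the others to honor agreements, in
  `[0, 1]`;
* plus two fixed traits: **social skills** (its probability of speaking
  each tick) and **social preferences** (whether it is willing to share
  equally).

A tick proceeds in a fixed order (`simulate_tick()`):

1. every agent decides independently whether to speak;
2. the speakers form the **group knowledge** — the confidence-weighted
   mean of their knowledge values (no speakers, no agreement that tick);
3. each agent may revise its knowledge toward the group knowledge: with
   probability `update_probability * (1 - confidence)` it moves a fraction
   `(1 - confidence)` of the way (confident agents neither reconsider
   often nor move far);
4. the **group extraction** is the surplus above the agreed optimal stock,
   `stock - group_knowledge`, shared equally; the **individual
   extraction** is the surplus above the agent's own perceived optimum,
   shared equally if the agent has social preferences and multiplied by
   `greed_factor` (capped at the surplus) otherwise;
5. each agent chooses between the group share and its individual level
   (see *Conditional cooperation* below); demand beyond the stock is
   rationed proportionally;
6. the resource is harvested and regenerates;
7. each agent compares the reported stock with the stock it expected —
   the true dynamics applied to its own chosen extraction plus the group
   share for everyone else — and updates confidence and trust: both rise
   by `reward_increment` on a match (within `match_tolerance`), confidence
   falls by `penalty_rate * |deviation| / capacity` on a mismatch, and
   trust falls too when the stock came in *below* expectation (someone
   took more than agreed). Without an agreement there is no expectation
   and no update.

All random draws are taken from R's global stream in this fixed order, so
a seeded run (`simulate_run()`) replays bit-identically.

### Conditional cooperation

When an agreement exists and an agent's individual extraction level
exceeds the group share by `gap > 0`, an agent with social preferences
honors the agreement with probability

```
p_coop = x ^ ((gap / defection_gap_scale) ^ defection_gap_exponent),
x = clamp((trust - trust_floor) / (trust_ceiling - trust_floor), 0, 1)
```

The form encodes three qualitative assumptions: honoring an agreement
that pays at least as much is costless (`p = 1` at `gap <= 0`), higher
trust means more cooperation, and a larger payoff advantage of defecting
means less cooperation. Agents whose trust has reached `trust_ceiling`
never break an agreement; agents without social preferences simply take
the larger amount.

## Parameters and calibration

The underlying behavioral theory fixes directions, not magnitudes. Every
behavioral constant is a named field of `behavior_params()` and can be
overridden per run; the defaults were calibrated so that the simulated
groups reproduce the qualitative outcome patterns of the behavioral
experiments (see *Validation targets*), not any single numeric series.

```{r}
behavior_params()
```

Calibration rationale for the non-obvious defaults:

* **`trust_ceiling = 0.8`.** The robustness experiments contrast initial
  trust drawn from `U(0.66, 0.94)` ("high trust") with `U(0.66, 0.80)`
  ("increased social uncertainty"), and the published finding is that the
  sparse-communication compositions (one informed speaker with silent or
  unconfident followers) lose their cooperative classification under the
  lower range while all other compositions keep it. For any smooth
  decreasing defection hazard the two trust distributions differ too
  little in mean hazard to reproduce that flip; the separation is maximal
  when the hazard is supported entirely below 0.8 — that is, when trust at
  or above 0.8 guarantees cooperation. 0.8 is exactly the boundary between
  the two experimental trust conditions, so the default has a direct
  experimental reading: agents in the upper "high trust" range are beyond
  temptation.
* **`defection_gap_scale` and `defection_gap_exponent`.** Chosen by a grid
  scan so that (i) all seven published group compositions classify as
  cooperative under the high-trust baseline, (ii) exactly the two
  sparse-communication compositions lose that classification under
  increased social uncertainty, and (iii) cooperative and non-cooperative
  runs, and all three exploitation classes, occur across the default
  factorial sweep. The scan maximized the margin of the binding
  classification quantities around the 0.9 config-level threshold.
* **`update_probability = 0.5`, `greed_factor = 2`,
  `reward_increment = 0.05`, `penalty_rate = 0.5`,
  `match_tolerance = 0.5`** follow the documented baseline magnitudes of
  the modeled experiments; scans confirmed they need no adjustment.

## Scenario generator

`scenario(1:7)` instantiates the seven published group compositions
(set I: scenarios 1–3 vary the number of informed, confident agents in a
fully communicating group; set II: scenarios 4–7 fix one informed and
three uninformed agents and vary who speaks and how confidently).
Informed agents draw their initial knowledge uniformly from the integers
25–29 (the MSY bin); uninformed agents from 10–24. The uninformed default
is the interpretation of "perceives the optimal stock size well below the
true optimum" that also keeps the all-uninformed scenario from being
degenerate; it is configurable (`uninformed_range`). Initial trust is
drawn from `U(0.66, 0.94)`, or `U(0.66, 0.80)` with `robustness = TRUE`.

`sweep_grid()` crosses five composition factors (knowledge, confidence,
speaking-skills profiles, trust level, social preferences) into 270
configurations used for pattern validation.

### Generator realism and limitations

* The generator reproduces the *design* of the behavioral experiments
  (group compositions, initialization ranges, horizon), not individual
  human trajectories; validation is pattern-oriented (classification
  frequencies, orderings of mean trajectories), not curve fitting.
* The resource is deterministic; all stochasticity is behavioral
  (speaking, knowledge-update timing, cooperation gambles) plus the
  initial draws.
* Expectation formation uses the true resource dynamics applied to the
  agreed plan. An alternative — expectations derived from the agent's own
  perceived optimum — is behaviorally plausible but is not implemented:
  none of the validation patterns exercise it, and it would be untested
  surface.
* Classification thresholds (config-level cooperation at 90% of runs,
  exploitation tolerance of ±2 stock units around the MSY bin) are
  documented stand-ins for unpublished analysis constants; both are
  arguments of `simulate_batch()`.
* The 14-tick horizon makes "learning" slopes noisy at the run level;
  they are meaningful in batch means.

## Validation targets

The test suite checks, at the published problem sizes:

1. the resource-model constants (MSY 9 on bin 25–29, optimal plan
   25, 9, 9, ..., recovery threshold 34, regeneration threshold 5) against
   brute-force oracles;
2. the 270-configuration sweep produces cooperative and non-cooperative
   runs and all three exploitation classes, also among cooperative runs;
3. scenarios 1→2→3 move monotonically closer to the optimal stock band,
   with near-universal overexploitation in the all-uninformed scenario;
4. the set-II exploitation gradient (scenario 4 closest to optimal, then
   5, 6, 7);
5. the robustness flip described under *Parameters and calibration*, with
   mean stock trajectories changing only minimally;
6. invariants: state bounds, contraction of knowledge updates, monotone
   trust/confidence under compliance, and bit-identical seeded replay.

## Reproducing a run

```{r}
cfg <- scenario(2, replications = 50, base_seed = 1)
batch <- simulate_batch(cfg)
batch
```

The command-line interface (`inst/cli/cprsim`) wraps the same entry
points: `run`, `sweep`, `classify`, `report`.
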
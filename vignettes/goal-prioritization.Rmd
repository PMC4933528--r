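---
title: "Modelling optimal and biased prioritization of two competing goals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling optimal and biased prioritization of two competing goals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalpursuit)
```

## The decision problem

`goalpursuit` models an agent pursuing two goals over a trial of `T`
discrete decision stages. At every stage exactly one goal is prioritized.
Each goal's position is summarized by a single non-negative integer, its
*distance to resolution* `d`:

* **Approach frame.** The goal is to reach a score threshold (by
  convention 10 points). `d` is the number of points still needed; the goal
  is *achieved*, permanently, when `d` reaches 0.
* **Avoidance frame.** The goal is to avoid falling to a score threshold
  (by convention 9 points). `d` is the number of points that can still be
  lost; the goal is *failed*, permanently, when `d` reaches 0.

Per stage and per goal, progress is an independent Bernoulli draw moving
the counter at most one unit. The prioritized goal enjoys the favourable
probability (default `p_prioritized = 0.8`): under approach, that is the
probability of gaining a point; under avoidance, the probability of *not*
losing one, so a point is lost with probability `1 - p`. The
non-prioritized goal gets `p_nonprioritized = 0.2`. Prioritizing an
avoidance goal therefore protects it, and the unified counter
representation makes the two frames mirror images: in both, `d` ticks down
toward an absorbing resolution, but resolution is success under approach
and failure under avoidance. Value is the number of attained goals at the
horizon — achieved goals under approach, *surviving* goals under avoidance
— so every value lies in `[0, 2]`.

### Assumptions worth stating

* At most one unit of progress or loss per goal per stage; scores never
  overshoot the threshold (resolution is absorbing).
* The two goals' outcomes are independent given the chosen action.
* Transition probabilities are known, fixed, and identical across stages;
  there is no learning and no time pressure beyond the finite horizon.
* Value depends only on the final attained-goal count, not on when goals
  resolve or on the money attached to them (the 3-pence-per-goal incentive
  is bookkeeping, linear in the count).

## Solving and evaluating the task

`backward_induction()` computes, for every joint state `(d1, d2)` and every
number of stages remaining `k`, the expected value of prioritizing each
goal and the state value `v = max(e1, e2)`, starting from the terminal
valuation and stepping backward. Tables are indexed by *stages remaining*
rather than calendar stage, so one table serves any trial with the same
state grid. The computation is vectorized over the whole `(d1, d2)` grid;
a trial with deficits up to 30 and 24 stages solves in milliseconds.

`attainment_probabilities()` transports the start-state probability mass
forward through the horizon under the recovered policy and reads off
`p_both`, `p_one`, `p_none`. The identity
`2 * p_both + p_one = v(start)` ties the forward and backward passes
together and is asserted in the tests.

### Numerical choices

* **Tie detection.** Expected values are compared with an absolute
  tolerance of `1e-12`. States with `d1 = d2` produce the two actions'
  expected values from mirrored floating-point expressions that agree to
  well below this tolerance, so symmetric states are always flagged as
  ties; the tolerance also catches near-ties arising elsewhere on the
  grid. Tie states are recorded as such (`action = 0`) rather than broken
  arbitrarily, because tied decisions are excluded from the behavioural
  analysis.
* **Ties in the forward pass** split their probability mass half-and-half
  between the two actions — the unique choice that introduces no
  directional bias.
* **Degenerate inputs.** A goal may start already resolved (`d = 0`); its
  row of the grid is frozen. When *both* goals are resolved no decision
  exists: `transition_distribution()` and the agents' choice functions
  refuse such states, while the value recursion simply carries the
  terminal value through (the state is absorbing).

## Reconstructing the experimental design

The experiment behind this package crossed goal frame (approach,
avoidance) with dual-goal difficulty (low, moderate, high) and relative
position (starting score differences 0, 1, 3, 5), 24 conditions, each
completed six times by each of 20 participants in trials of 11–24
decisions. Difficulty was defined by the probability of attaining *both*
goals at trial start: bands [.95, .96] (low), [.57, .58] (moderate) and
[.03, .06] (high). The exact per-condition starting scores and horizons
were not published, so `calibrate_condition()` reconstructs them by
searching integer horizons (11–24, ascending) and base deficits
(ascending) for a condition whose dual-attainment probability falls in the
band.

Three design choices here were genuinely open:

* **Which policy defines the band probability.** The published bands do
  not say under what decision policy the attainment probability was
  computed. We use the *optimal* policy, because it is the only
  participant-independent benchmark the model provides, and it is the same
  quantity the forward pass already computes.
* **Exact band attainability.** Integer deficits and horizons make the
  achievable probabilities a discrete set, and not every band contains a
  grid point. The search therefore proceeds in tiers: the strict band
  first; then the band widened by half a unit of its printed precision
  (±0.005), treating the published bounds as rounded; finally the grid
  point nearest the band midpoint, flagged `band_met = FALSE`. Under the
  default probabilities the low and high bands are always hit strictly;
  the moderate band is hit within printed precision except at relative
  position 5, where the nearest achievable probability is ≈ 0.561. Setting
  `fallback = FALSE` disables the tiers and turns an unattainable band
  into an error.
* **Orientation and counterbalancing.** In the canonical orientation goal
  1 starts in the better position (higher score). `build_schedule()`
  alternates which goal leads across repetitions (goal 1 on odd, goal 2 on
  even repetitions) — the original counterbalancing scheme is unpublished,
  and alternation is the simplest balanced choice.

## The synthetic-data generator

`generate_dataset()` emulates the experiment's data layer: 20 simulated
participants each work through a per-participant shuffled schedule of 144
trials (24 conditions × 6 repetitions), every decision logged with its
state, choice and per-goal outcome. Three agent families generate choices:

* **optimal** — argmax expected value, uniform at ties; the normative
  reference.
* **logistic_biased** — chooses the *worse-position* goal (the one with
  the lower score) with probability
  `plogis(inverse_temperature * (EV_worse - EV_better) + bias)`, with a
  separate additive bias per frame. This is the minimal stochastic rule
  that nests optimal play (large inverse temperature, zero bias) while
  exposing one interpretable risk-bias dial per frame: a negative approach
  bias yields risk aversion, a positive avoidance bias risk seeking. The
  pipeline default (`inverse_temperature = 5`, biases −0.5/+0.5) produces
  departures from optimality of the same qualitative shape as the human
  pattern the task was designed to detect.
* **diminishing_returns** — re-solves the task with concave terminal
  utility `u(0) = 0, u(1) = 1, u(2) = 1 + utility_second_goal` and plays
  its argmax; with `utility_second_goal = 1` it reproduces the optimal
  agent exactly (asserted in the tests).

Reproducibility is counter-based: the RNG seed of every
(participant, condition, orientation) simulation block is derived from the
master seed by a Lehmer-style integer hash, so datasets are identical
across runs and unaffected by block evaluation order, and all
block-internal draws use R's own RNG.

**What the generator does and does not emulate.** It reproduces the task's
probabilistic structure, trial bookkeeping (including the 0/±3/±6 pence
deltas), schedule layout and the directional risk biases. It does not
model learning or sequence effects, reaction times, fatigue, the
house-money effect, or individual differences beyond what a per-participant
agent list supplies. Passing tests therefore show that the *pipeline*
recovers what this generative family puts in — not that the logistic rule
is the true model of human choice.

## The analysis pipeline

`code_decisions()` recodes every decision onto the worse/better-position
scale: 1 if the prioritized goal had the lower score, 0 otherwise — and the
same coding for the normative model's choice in the same state. Note that
the lower score corresponds to the larger deficit under approach but the
smaller buffer under avoidance. Decisions are excluded when a goal had
already resolved, when scores were level, or when the two actions'
expected values tie; each kept decision then contributes two rows
(participant and model source, ±1 coded) to the modelling table.

The published analysis used a logistic mixed model with random effects of
participant and trial. We approximate it with fixed-effects logistic
regression (`stats::glm`, IRLS, deviance tolerance `1e-8`, max 100
iterations) and participant-clustered robust standard errors
(`sandwich::vcovCL`). This preserves the inferential target — the sign and
approximate magnitude of the frame × source interaction — at a fraction of
the machinery; coefficient magnitudes should be compared qualitatively,
not digit-for-digit. Whether "trial" in the original random-effects
structure means trial identity or condition is ambiguous; we cluster on
participant only. Separation is flagged when any |coefficient| exceeds 15.
No multiple-testing correction is applied: the analysis is one planned
interaction plus two follow-up contrasts.

## Test and simulation scales

The test suite verifies the dynamic program against an exhaustive
path-enumeration oracle (horizons ≤ 5, deficits ≤ 4, where the full
outcome tree is enumerable), re-derives calibrated attainment
probabilities with an independent state-mass forward pass, checks
Monte-Carlo attainment frequencies (4,000 trials) and empirical transition
rates (100,000 decisions) against their analytic targets at 3 standard
errors, and runs parameter recovery on 20 seeded datasets of 4
participants × the full 24-condition design with generating biases of
±1.5 logits — magnitudes chosen so the per-frame effect signs are
statistically identifiable at that sample size. The pipeline itself runs
the full 20-participant experiment in well under a minute.

## Known limitations

* Two goals only; no state-dependent or learned transition probabilities;
  no continuous-time reprioritization.
* The reconstructed design matches the published structure and difficulty
  bands, not the original (unpublished) per-condition scores and horizons,
  so decision counts differ from the original experiment's totals.
* The clustered fixed-effects approximation understates shrinkage relative
  to a full mixed model when participants are few.
* Bias parameters are inputs to the generator, not estimates from human
  data; the package fits population-level regression contrasts, not
  per-participant choice-model parameters.
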
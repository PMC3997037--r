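---
title: "Risk-sensitive reinforcement learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-sensitive reinforcement learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by **rsrl**, the behavioural
tasks it is evaluated on, the numerical choices made in the simulators, and
the design decisions and limitations a user should know about before
trusting the outputs.

## The model

The agent is a tabular reinforcement learner that tracks two quantities per
state–action pair: the expected reward (the *value* `Q`) and the running
variance of its own reward prediction errors (the *risk* `h`).

On every trial, after receiving reward `r` for action `a` in state `s`, it
computes the temporal-difference (TD) error — the model's dopamine
correlate — and updates both tables:

- immediate-reward tasks: `delta = r - Q(s, a)`
  (`td_error_immediate()`);
- delayed-reward tasks: `delta = r + gamma * Q(s') - Q(s)`
  (`td_error_discounted()`), with `Q(s') = 0` at terminal states;
- value: `Q <- Q + eta_q * delta` (`update_value()`);
- risk: `xi = delta^2 - h`, `h <- h + eta_h * xi` (`risk_error()`,
  `update_risk()`).  Since this is a convex combination of `h` and
  `delta^2`, `h >= 0` is an invariant, enforced and tested.

Actions are selected by softmax over the *sign-dependent mean–variance
utility* (`utility()`):

```
U(s, a) = Q(s, a) - alpha * sign(Q(s, a)) * sqrt(h(s, a))
```

The risk weight `alpha` is the model's serotonin correlate.  Because the
risk term flips sign with `Q`, a given `alpha > 0` produces risk *aversion*
when the expected outcome is a gain and risk *seeking* when it is a loss —
the asymmetry prospect theory describes.  Tryptophan depletion (lowered
serotonin) is modelled purely as a reduction of `alpha`.

Two presentational choices deserve a note:

- **`sqrt(h)` vs `h`.**  The utility uses the standard deviation
  `sqrt(h)`, which keeps the risk term on the same scale as `Q`.
  `utility(risk_transform = "identity")` exposes the raw-variance variant
  for sensitivity analyses; no headline behaviour in this package depends
  on the choice, but fitted `alpha` values do assume `sqrt`.
- **`sign(0) = 0`.**  At the neutral value the risk term vanishes, so a
  fresh agent starts risk-neutral.

## Tasks

### Foraging bandit (`run_bee_experiment()`)

Two flowers with equal mean nectar (1 unit): blue constant, yellow 3 units
with probability 1/3.  Contingencies swap at trial 15 of 40.  Fitted
parameters `eta_q = 0.001`, `eta_h = 0.051`, `alpha = 1.5`, `beta = 10`.
A risk-averse population prefers the constant flower, and after the
reversal the modal choice follows it within a few trials
(`reversal_switch_latency()`).

### Saccade gambling under tryptophan depletion (`run_rtd_experiment()`)

Six states pair a sure juice volume against a 50/50 gamble (`rtd_schedule()`);
states 1–4 have equal expected value (EEV), 5–6 unequal (UEV).  Choices are
driven by the *subjective* reward `r = juice - 193.2`
(`subjective_reward()`), which places the EEV sure options in a loss frame.
`beta = 0.044` reflects the shallow psychometric slope on this reward
scale.  The serotonin conditions are `alpha = 1.985` (baseline) and
`alpha = 1.658` (depleted).  Unstated details we fixed: each agent sees
every state in shuffled blocks (200 presentations per state by default),
and only the chosen option's tables update.

### Delayed-reward patch clearing (`run_delayed_experiment()`)

Two panels: white (18 ± 9 patches, reward 1) and yellow (72 ± 24 patches,
reward 4).  Each peck removes a trial-type-specific number of patches
(mean ± 2, integer uniform; `delayed_schedule()` crosses slow/fast rates in
an eight-trial block); clearing a panel delivers its reward and ends the
trial.  State is patches-remaining per panel; learning uses the discounted
TD rule.  At each peck the agent previews the state each panel would reach
and scores both prospects by utility, counting the panel reward when the
prospect is full clearance (see "Selection rule" below).

### Reward/punishment reversal learning (`run_reversal_experiment()`)

Two stimuli, two responses; the correct response on the rewarding stimulus
earns +1 and on the punishing stimulus avoids −1.  After a criterion of
5–9 correct responses the contingency reverses (up to 16 stages or 120
trials per block; four blocks).  The value table is constrained by the
complementarity identities `Q(s, a1) = -Q(s, a2)` and
`Q(s1, a) = -Q(s2, a)` (`enforce_complementarity()`), leaving one free
value; the risk tables are unconstrained.  Blocks alternate two probe
conditions differing in which stimulus is shown first after a reversal.
Errors on the first two post-reversal trials are not counted, an error
causes the same stimulus to repeat, and error counts are square-root
transformed for summaries.

## Numerical choices

- **Reproducibility and pairing.**  The bandit, saccade and reversal
  simulators give every agent its own RNG substream derived from the
  run-level seed, so (i) agent `i`'s trajectory is independent of the
  batch size, and (ii) runs that differ only in `alpha` are matched
  trial-for-trial (common random numbers), which is how the directional
  serotonin contrasts are tested.  The patch-clearing simulator advances
  all agents in lockstep from a single run-level stream: its step count is
  state-dependent, so per-agent streams would desynchronise anyway; its
  contrasts still share the seed across conditions.
- **Vectorisation.**  All engines advance agents in lockstep with matrix
  indexing; only the reversal task (whose trial count is itself random)
  loops per agent.
- **Softmax stability.**  `softmax_probs()` subtracts the maximum scaled
  utility before exponentiating, so large value scales (e.g. the saccade
  task's ±50-unit rewards) cannot overflow.
- **Risk non-negativity.** `update_risk()` clips at zero only to absorb
  floating-point dust and aborts if an update would be meaningfully
  negative, which can only happen if `xi` was not derived from the same
  `h`.

## Open design decisions

These points are underdetermined by the task descriptions; the package
picks one behaviour and documents it:

- **Measuring during learning (patch clearing).**  Choice frequencies are
  recorded while the agent learns from naive tables, over `n_passes = 4`
  blocks of the schedule by default.  If agents are instead trained to
  convergence and then probed, exploration collapses onto the white panel
  for all `gamma <= 0.7` (the yellow panel's discounted value
  `4 * gamma^(steps)` loses to white's at the horizons involved), and the
  large-reward preference disappears entirely.  The acquisition-phase
  measurement reproduces the rise of large-reward choice with `alpha`.
- **Selection rule (patch clearing).**  The prospective utility of a
  panel whose post-peck state is full clearance is the panel reward (its
  terminal-state tables are identically zero).  Without this term agents
  swerve away from panels they are about to clear, which contradicts the
  task's premise that clearing is the goal.
- **Reward coding (reversal learning).**  Rewards are correctness-coded
  (+1 correct, −1 error) on both trial types.  The alternative —
  outcome-valence coding (+1 obtained reward / −1 received punishment) —
  is pathological under the complementarity constraint: errors *reinforce*
  the erring response on punishing stimuli, locking agents into error
  loops and producing wildly asymmetric trial types even without the
  sign term, contrary to the intended no-sign control.

## Known limitations

Honest reds and non-reproductions, verified rather than patched:

- **EEV indifference is biased at `eta = 0.1`.**  A classical agent
  (`alpha = 0`) on an equal-expected-value state is often expected to
  settle at P(safe) = 0.5.  With chosen-arm-only updates at
  `eta_q = 0.1`, the risky option's value estimate fluctuates with sd
  ≈ 11.5 subjective units, and the feedback is asymmetric: underestimates
  suppress the very choices that would correct them.  Time-averaged choice
  tilts to ~0.53 safe; the bias vanishes as `eta -> 0` (0.503 at
  `eta = 0.01`) and grows with it (0.568 at 0.2).  The package keeps the
  model's stated learning rate and reports the biased value.
- **No `gamma` trend in the patch-clearing task.**  At `beta = 20` choice
  is saturated in the learned utility differences, and the measured
  preference arises during a `gamma`-insensitive acquisition transient;
  the rise of large-reward choice with `gamma` is not reproduced under
  any regime we found (training passes 1–16, measurement windows during
  or after learning).  The `alpha` trend is robust.
- **No trial-type × `alpha` interaction in reversal learning.**  Under
  complementarity, the error probability on both trial types is the same
  function `sigmoid(beta * (-2q + alpha * (sqrt(h1) + sqrt(h2))))` of the
  free value, so reducing `alpha` cuts reward- and punishment-prediction
  errors by statistically indistinguishable amounts (paired estimate
  −0.6 ± 0.5 errors at n = 4000).  The claim that punishment errors fall
  by *more* is therefore not reproduced; the main effect (fewer errors at
  lower `alpha`) and the condition equivalence are.
- **The saccade `alpha` contrast is a finite-session effect.**  At the
  true long-run tables the utility ordering would actually reverse;
  the observed baseline > depleted safe-choice gap arises from transient
  under-sampling dynamics in 200-presentation sessions, where it is
  robust across seeds under paired randomness.

## Reproducing the headline numbers

```{r}
library(rsrl)

# Foraging bandit: reversal latency
sim <- run_bee_experiment(n_agents = 1000, seed = 1)
reversal_switch_latency(sim)

# Serotonin contrast on the saccade task (paired seeds)
base <- run_rtd_experiment(alpha = 1.985, seed = 1)
depl <- run_rtd_experiment(alpha = 1.658, seed = 1)
glance(base)$p_safe - glance(depl)$p_safe

# Delayed reward: alpha x gamma sweep
run_delayed_sweep(n_agents = 2000, seed = 1)

# Reversal learning: serotonin main effect
hi <- run_reversal_experiment(alpha = 0.5, seed = 1)
lo <- run_reversal_experiment(alpha = 0.3, seed = 1)
glance(hi)$errors_total - glance(lo)$errors_total
```
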
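---
title: "Planning by policy rollouts in dynamic mazes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning by policy rollouts in dynamic mazes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`rollnav` implements a recurrent meta-reinforcement-learning agent for a
dynamic maze task, together with two companion analysis pipelines: a
Bayesian decomposition of human response times into thinking time plus a
perception–action delay, and a hippocampal replay pipeline (Poisson
position decoding, replay detection, and enrichment statistics with
permutation nulls) exercised on synthetic place-cell sessions.

## Task

Each episode lasts T = 20 s. A maze on a 4×4 lattice with periodic
boundaries is sampled, a hidden goal cell is drawn uniformly, and the agent
starts at a random non-goal cell. Reaching the goal yields reward 1; the
agent then observes the goal cell for one network iteration (its policy
output at that iteration is ignored) and is teleported to a random non-goal
cell. A physical action or a teleportation step consumes 400 ms, so a
purely reactive agent takes exactly 50 actions per episode; a rollout
consumes 120 ms (or l × 24 ms in the proportional-cost variant, where l is
the number of imagined actions).

Mazes are carved as a perfect maze (a spanning tree of the lattice) by
randomized depth-first search, after which 3 further walls are removed
(4 for bounded mazes, which approximately equates the shortest-path
distributions of the two boundary conditions — checked in the test suite).
Moving into a wall leaves the agent in place; this is the standard
gridworld convention and keeps the time accounting uniform.

## Agent

The agent is a GRU (default 100 hidden units; the scaled-down experiments
in this package use 60) receiving the current location (16 one-hot), the
previous action (5 one-hot), the previous reward, the wall layout (32
binary entries, one per potential edge of the periodic lattice; absent
wrap edges of bounded mazes are encoded as walls), the elapsed time t/T,
and a 33-entry rollout-feedback block. Three heads read out the hidden
state: a 5-way softmax policy (4 moves + "rollout"), a scalar value, and a
world model — a single 33-unit rectified-linear hidden layer mapping
(hidden state, action one-hot) to two 16-way softmax distributions over the
next state and the goal location.

Sampling the 5th action triggers a rollout: the imagined goal is the
argmax of the world model's goal distribution at the first imagined step
and is held fixed; imagined actions are drawn from the policy renormalized
over the four physical actions (a rollout inside a rollout is undefined);
the imagined next state is the argmax of the next-state distribution with
ties broken to the lowest cell index. Imagined observations reuse the real
input encoder with previous reward 0 and the elapsed time frozen at the
rollout start. The rollout stops after 8 imagined actions or as soon as
the imagined state reaches the imagined goal. The flattened action
sequence (8 slots × 4 indicators, unused slots zero) plus a success bit —
33 entries — is appended to the next network input. The caller's hidden
state and location are untouched, and no gradients flow through the
rollout: it is treated as part of the environment.

## Training

Training is on-policy actor–critic with Adam on batches of 40 episodes.
Per episode the surrogate loss is

    sum_k [ -adv_k log pi_k(a_k) + 0.5 beta_v (V_k - R_k)^2
            + beta_e sum_a pi log pi + beta_p CE_k ]

with `R_k` the undiscounted reward-to-go, `adv_k = R_k - V_k` treated as a
constant in the actor term, `beta_v = beta_e = 0.05`, `beta_p = 0.5`.
Policy, entropy and value terms are evaluated at iterations where an
action was sampled (physical or rollout); teleport iterations are ignored.
The world-model cross-entropy `CE_k` is evaluated at physical-action
iterations only, where a true next state exists; its targets are the
one-hot true next state and goal. The critic term in the printed update
rule, `beta_v * grad(V_k) * adv_k`, equals the gradient of
`0.5 beta_v (V_k - R_k)^2`, which is the form implemented. The entropy
term is computed over the full 5-way policy.

The learning rate is not a published constant; the default here is 1e-3
(Adam defaults otherwise), with 2e-3 used for the scaled-down runs in the
acceptance analyses where the training budget is small. Gradients were
verified against central finite differences on small instances to 1e-4
relative error (see `test-training.R`). Hidden states are reset to zero at
episode starts. Episodes are truncated exactly when t reaches T.

## Scale of the bundled experiments

The reference experiments behind this model train for 8 × 10^6 episodes.
The experiments run by this package's tests and acceptance script use
50,000 episodes with 60 hidden units (and 28,000 episodes with 48 units
for the cached test fixture) so that a full run completes on one CPU in
minutes. At this scale the world model and value function show clear
learning, but the policy is still far from converged: quantities that
depend on a competent goal-memory policy (trial-2 performance, effects of
forced rollouts on steps-to-goal) may not yet show the asymptotic pattern.
The analysis code paths themselves are exercised end to end regardless,
and every analysis invariant (pairing of environments across arms, rollout
count preservation under shuffling, renormalization to the 4-simplex) is
tested independently of training quality.

# Task-space estimation

`estimate_task_space()` follows the birthday-collision estimator: sample
n = 50,000 wall layouts, compute the fraction f of identical pairs among
the n(n−1)/2 comparisons by exact layout hashing, and report 16/f (16
goal positions per layout), repeated 10 times for a mean and s.e.m. The
estimator is validated against closed forms on degenerate and uniform toy
generators. Its value is conditional on the maze-generation algorithm;
with the DFS carving used here it converges near 3.0 × 10^8 tasks, and
markedly more uniform carvings (frontier-edge growth, unbiased
random-walk spanning trees) give effective supports an order of magnitude
larger — DFS is the reading most consistent with the reported task-space
scale.

# Thinking-time decomposition

Response times decompose as t_r = t_t + t_d with thinking time t_t ≥ 0
(uniform prior on [0, 7 s] — the task's response cap, so the upper bound
never binds and the closed form needs no upper truncation) and a shifted
log-normal perception–action delay t_d with density parameters (mu, sigma,
delta). On guided actions t_t = 0, so (mu, sigma, delta) are fitted to
guided response times by maximum likelihood: for fixed delta the ML (mu,
sigma) are the mean and ML standard deviation of log(t − delta); delta is
found by a 1-ms grid search over [0, min(t) − 1], which keeps every
observation at positive density (a grid point at min(t) would be
singular). Separate priors are fitted for the first action of each trial
(which carries an extra perceptual delay after the teleport) and for all
other actions.

The posterior mean thinking time is

    t_hat = t_r - delta - E[x | x < t_r - delta],

with the truncated log-normal conditional expectation computed via
log-space normal CDF ratios for numerical stability; responses shorter
than delta get t_hat = 0. The closed form is verified against adaptive
quadrature to 1e-6 relative error on a parameter grid, and against a
Monte-Carlo rejection oracle. Posterior-mode and constant-delay estimator
variants are available behind a `strategy` flag as robustness checks.

# Replay pipeline and the synthetic sessions

The decoder estimates per-neuron mean rates per state of a 5×5 grid from
movement epochs (speed > 2 cm/s), excludes neurons below 0.1 Hz, floors
rate maps at 0.01 Hz (so log-likelihoods stay finite; the data do not
constrain unvisited-state rates), and classifies each 5-ms step by the
maximum-likelihood state under a Poisson model over a centred 75-ms
window, ties to the lowest state index.

Forward replays are maximal sequences of lattice-adjacent decoded states
(4-connectivity, no wrap) originating at the animal's location, with at
least three states; excursions of ≤ 20 ms to a non-adjacent state are
bridged as "lapses" when the sequence afterwards continues from the chain
tail, and are excluded from the state list. We additionally require three
*distinct* states, which rejects single-state dither (A→B→A) produced by
decoder noise while accepting every scripted trajectory. Only trials
shorter than 40 s are analysed and the first home trial is dropped.

Statistics: wall-crossing fraction against the nonidentical rotations and
reflections of the session's walls (the dihedral group minus transforms
that fix the wall set); goal-passage fraction against the wells that are
neither the goal nor the current location; follow probability
P(a1 = a1_hat) split by replay success (reaching the goal without crossing
a wall), with the unsuccessful set defined via control locations and
disjoint from the goal-successful set (the non-disjoint variant is behind
a flag); and consecutive-replay over-representation with the success
indicator residualized against time-since-arrival and time-to-departure
(capped at 15 s) and normalized by a control-location baseline with its
own time correction. Permutation tests flip true/control labels per
session (10,000 draws), one-sided in the direction of each hypothesis; the
consecutive-replay test permutes replay order within trials.

The synthetic sessions emulate the rodent task: a walled 5×5 arena
(6 walls, connectivity enforced), nine wells in the inner 3×3, home/away
alternation with 5–15 s stationary periods at the previously rewarded
well, an initial roaming epoch covering the whole arena (so the decoder
sees movement in every state, as real foraging sessions do), and Gaussian
place cells (default 300 cells — within the 187–333 neurons of real
sessions — sigma 6 cm, peak 30 Hz, baseline 0.05 Hz) with centres on a
jittered lattice so every location has coverage. Scripted replays play
the field rates along a path at 40 ms per state (5 m/s, within the
measured range of replay propagation speeds; at much faster compressions a
state's dwell occupies too little of the fixed 75-ms decoding window for
any decoder to recover the sequence) with a 5× rate gain mimicking the
strong firing during sharp-wave ripples. What these simulations do not
emulate: theta modulation, reverse or remote replays, behavioural
variability in stationary position, and non-Poisson spike statistics —
so passing tests validate the pipeline's correctness, not its performance
on real tetrode data.

# Numerical choices and degenerate inputs

* Softmax columns are exponentiated directly (logits are bounded in this
  model); the max-subtraction path engages only for large values.
* Policy probabilities are floored at 1e-12 inside logs.
* The optimal-exploration search is exact branch-and-bound with an
  admissible distinct-times bound and nearest-unvisited expansion order; a
  node budget guards against pathological instances.
* Rollout sampling uses inverse-CDF draws; ties in argmax next states go
  to the lowest cell index.
* Paired analyses (ablation, shuffled timings) re-seed the environment
  stream identically across arms so comparisons are paired draw-by-draw.
* `fit_delay_prior` refuses fewer than 2 observations, non-positive
  response times and zero-variance data.

# Known limitations

* Policy competence at the bundled training scale is far below the
  asymptotic behaviour of fully trained agents; see "Scale" above.
* The replay detector's three-distinct-states rule is a deliberate
  noise-robust strengthening of "three or more states".
* The wall-input block is fixed to the periodic 4×4 edge enumeration
  (32 entries) regardless of boundary condition.
* The task-space estimate is a property of this package's maze generator;
  a different reading of the carving step would shift it.
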
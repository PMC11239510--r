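Package: rollnav
Title: Recurrent Meta-Reinforcement Learning with Policy Rollouts in Dynamic Mazes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a recurrent (GRU) meta-reinforcement learning agent for
    a dynamic maze navigation task in which the agent can either act or 'think'
    by sampling imagined policy rollouts through a learned world model.
    Provides the maze environment with wall-clock time accounting, on-policy
    actor-critic training with auxiliary world-model and entropy objectives,
    and the analyses that characterise planning behaviour: forced-rollout
    performance curves, rollout ablations, rollout-success effects on the
    policy, and task-space estimation. Also implements two companion
    data-analysis procedures: a Bayesian decomposition of human response times
    into thinking time plus a shifted log-normal perception-action delay, and a
    hippocampal replay pipeline (Poisson position decoding, replay detection,
    wall-avoidance / goal-enrichment / follow-probability / consecutive-replay
    statistics with permutation tests) exercised on synthetic place-cell
    sessions with scripted replays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
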
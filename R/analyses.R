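# Analyses of trained agents: forced-rollout performance curves, policy
# entropy, rollout ablations, rollout-success effects on the policy,
# task-space estimation, trajectory clamping, value-function quality and
# cross-validated consecutive-rollout over-representation.

# one network iteration "peek": compute h' and heads for the pending
# observation of every alive column without advancing the environment
peek_step <- function(par, config, sim) {
  idx <- which(sim$alive)
  m <- length(idx)
  n <- config$side^2
  D <- obs_length(config)
  cells <- integer(m); tfrac <- numeric(m)
  for (i in seq_len(m)) {
    st <- sim$states[[idx[i]]]
    cells[i] <- if (!is.na(st$teleport_obs_cell)) st$teleport_obs_cell else st$agent
    tfrac[i] <- st$t / st$T
  }
  X <- matrix(0, D, m)
  X[cbind(cells, seq_len(m))] <- 1
  pa <- sim$prev_action[idx]
  has_pa <- which(!is.na(pa))
  X[cbind(n + pa[has_pa], has_pa)] <- 1
  X[n + 6L, ] <- sim$prev_reward[idx]
  X[(n + 7L):(3L * n + 6L), ] <- sim$wallmat[, idx]
  X[3L * n + 7L, ] <- tfrac
  X[(3L * n + 8L):D, ] <- sim$feedback[, idx]
  g <- gru_forward(par, X, sim$h[, idx, drop = FALSE])
  hd <- heads_forward(par, g$h)
  list(idx = idx, h = g$h, policy = hd$policy, value = hd$value, X = X)
}

# run fresh episodes up to (and including) the first teleportation step,
# returning the frozen simulation snapshot; episodes that never find the
# goal within max_iters are marked dead and should be dropped by the caller
run_to_trial2 <- function(agent, n_mazes, greedy = TRUE, max_iters = 300) {
  config <- agent$config
  states <- lapply(seq_len(n_mazes), function(i) init_episode(config))
  sim <- sim_init(agent$params, config, states)
  res <- simulate_batch(agent$params, config, sim,
                        sim_control(greedy = greedy,
                                    stop_after_teleport = TRUE,
                                    ignore_T = TRUE, max_iters = max_iters))
  sim <- res$sim
  ok <- sim$goal_reached &
    vapply(sim$states, function(s) s$trial == 2L, logical(1))
  sim$alive <- ok
  sim
}

#' Trial-2 performance as a function of forced rollouts
#'
#' Simulates fresh episodes until the goal is first found, then enforces
#' \code{n} rollouts at the start of trial 2 and releases the agent with
#' rollouts prohibited (policy renormalized over the physical actions),
#' counting physical steps to the goal. The feedback-zeroed control repeats
#' this with the rollout input channels set to zero while the recurrent
#' dynamics still run. The optimal reference is the mean shortest path from
#' the trial-2 start locations.
#'
#' @param agent a trained \code{maze_agent}
#' @param n_list numbers of forced rollouts (default 0:15)
#' @param n_mazes episodes (default 1000)
#' @param max_steps cap on steps to goal in the release phase
#' @return data.frame(n_forced, variant, mean_steps, sem_steps,
#'   mean_entropy) plus attribute \code{"optimal"}
#' @export
forced_rollout_curve <- function(agent, n_list = 0:15, n_mazes = 1000,
                                 max_steps = 60) {
  config <- agent$config
  par <- agent$params
  base <- run_to_trial2(agent, n_mazes)
  keep <- which(base$alive)
  if (!length(keep)) stop("agent never reached the goal; is it trained?")
  opt <- mean(vapply(keep, function(b)
    shortest_path_length(base$states[[b]]$maze, base$states[[b]]$agent,
                         base$states[[b]]$goal), integer(1)))
  out <- NULL
  for (variant in c("intact", "zero_feedback")) {
    for (nf in n_list) {
      sim <- base
      sim$iter <- integer(length(sim$states))
      if (nf > 0) {
        resB <- simulate_batch(par, config, sim,
          sim_control(force_rollout = TRUE, ignore_T = TRUE, max_iters = nf,
                      zero_feedback = (variant == "zero_feedback")))
        sim <- resB$sim
      }
      sim$alive[keep] <- TRUE
      sim$iter <- integer(length(sim$states))
      sim$n_physical <- integer(length(sim$states))
      sim$goal2 <- FALSE
      # release: greedy physical actions, no rollouts, count steps
      pk <- peek_step(par, config, sim)
      pphys <- pk$policy[1:4, , drop = FALSE]
      pphys <- pphys / rep(colSums(pphys), each = 4L)
      ent <- -colSums(pphys * log(pphys))
      resC <- simulate_batch(par, config, sim,
        sim_control(greedy = TRUE, forbid_rollout = TRUE, ignore_T = TRUE,
                    stop_on_goal = TRUE, max_iters = max_steps))
      steps <- pmin(resC$sim$n_physical[keep], max_steps)
      out <- rbind(out, data.frame(
        n_forced = nf, variant = variant, mean_steps = mean(steps),
        sem_steps = sd(steps) / sqrt(length(steps)),
        mean_entropy = mean(ent)))
    }
  }
  attr(out, "optimal") <- opt
  out
}

#' Mean policy entropy over the physical actions after forced rollouts
#'
#' Convenience accessor over \code{\link{forced_rollout_curve}}: entropy of
#' the policy renormalized over the four physical actions, in nats
#' (uniform = log 4).
#'
#' @param curve output of \code{forced_rollout_curve}
#' @return data.frame(n_forced, mean_entropy) for the intact variant
#' @export
entropy_after_rollouts <- function(curve) {
  cv <- curve[curve$variant == "intact", ]
  cv[, c("n_forced", "mean_entropy")]
}

#' Rollout ablation: mean reward with the rollout action disabled
#'
#' Runs paired episodes (identical maze, goal and start) with the default
#' policy and with the policy renormalized over physical actions.
#'
#' @param agent a \code{maze_agent}
#' @param n_episodes number of paired episodes
#' @param greedy greedy action selection
#' @return data.frame(default, ablated) of per-episode rewards
#' @export
ablate_rollouts <- function(agent, n_episodes = 500, greedy = TRUE) {
  config <- agent$config
  states <- lapply(seq_len(n_episodes), function(i) init_episode(config))
  arm_seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(arm_seed)  # identical environment randomness across arms
  r1 <- simulate_batch(agent$params, config,
                       sim_init(agent$params, config, states),
                       sim_control(greedy = greedy))
  set.seed(arm_seed)
  r2 <- simulate_batch(agent$params, config,
                       sim_init(agent$params, config, states),
                       sim_control(greedy = greedy, forbid_rollout = TRUE))
  data.frame(default = r1$sim$reward_total, ablated = r2$sim$reward_total)
}

#' Shuffled rollout times: mean reward with randomized rollout iterations
#'
#' Counts the rollouts the default agent performs in each environment, then
#' re-runs the same environments enforcing the same number of rollouts at
#' uniformly resampled network iterations (and forbidding them elsewhere).
#' A scheduled rollout that collides with a teleportation iteration is
#' deferred to the next free iteration, preserving the count.
#'
#' @param agent a \code{maze_agent}
#' @param n_episodes number of paired episodes
#' @param greedy greedy action selection
#' @return data.frame(default, shuffled, n_rollouts)
#' @export
shuffle_rollout_times <- function(agent, n_episodes = 500, greedy = TRUE) {
  config <- agent$config
  states <- lapply(seq_len(n_episodes), function(i) init_episode(config))
  arm_seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(arm_seed)
  r1 <- simulate_batch(agent$params, config,
                       sim_init(agent$params, config, states),
                       sim_control(greedy = greedy))
  n_roll <- r1$sim$n_rollouts
  n_iter <- r1$sim$iter
  forced <- lapply(seq_len(n_episodes), function(b) {
    if (n_roll[b] == 0) integer(0)
    else sort(sample.int(n_iter[b], min(n_roll[b], n_iter[b])))
  })
  set.seed(arm_seed)
  r2 <- simulate_batch(agent$params, config,
                       sim_init(agent$params, config, states),
                       sim_control(greedy = greedy, forced_iters = forced))
  data.frame(default = r1$sim$reward_total, shuffled = r2$sim$reward_total,
             n_rollouts = n_roll, n_rollouts_shuffled = r2$sim$n_rollouts)
}

#' Effect of rollout success on the policy
#'
#' At the first iteration of trial 2, repeatedly samples rollouts from the
#' identical (maze, location, hidden state) until both a successful and an
#' unsuccessful rollout are obtained (episodes where 100 samples do not
#' produce both are discarded). For each arm the rollout feedback is fed
#' back and the probability of the first imagined action, renormalized over
#' physical actions, is compared before and after.
#'
#' @param agent a \code{maze_agent}
#' @param n_mazes episodes (default 1000)
#' @param max_attempts rejection-sampling cap per episode (default 100)
#' @return data.frame(episode, success, a1, pi_pre, pi_post)
#' @export
success_effect <- function(agent, n_mazes = 1000, max_attempts = 100) {
  config <- agent$config
  par <- agent$params
  sim <- run_to_trial2(agent, n_mazes)
  keep <- which(sim$alive)
  if (!length(keep)) stop("agent never reached the goal; is it trained?")
  pk <- peek_step(par, config, sim)   # first iteration of trial 2
  # pk$idx == keep; h after observing the new location
  h1 <- pk$h
  pol1 <- pk$policy
  m <- length(keep)
  got <- vector("list", m)
  need <- rep(TRUE, m)
  for (att in seq_len(max_attempts)) {
    todo <- which(need)
    if (!length(todo)) break
    rb <- rollout_batch(par, h1[, todo, drop = FALSE], sim$states[keep[todo]],
                        config)
    for (i in seq_along(todo)) {
      ii <- todo[i]
      arm <- if (rb$success[i]) "success" else "failure"
      if (is.null(got[[ii]][[arm]]))
        got[[ii]][[arm]] <- list(a1 = rb$actions[1, i],
                                 fb = rb$feedback[, i])
      if (!is.null(got[[ii]][["success"]]) &&
          !is.null(got[[ii]][["failure"]])) need[ii] <- FALSE
    }
  }
  done <- which(!need)
  if (!length(done)) stop("no episode produced both rollout outcomes")
  out <- NULL
  D <- obs_length(config)
  n <- config$side^2
  for (arm in c("success", "failure")) {
    X2 <- matrix(0, D, length(done))
    for (j in seq_along(done)) {
      b <- keep[done[j]]
      st <- sim$states[[b]]
      X2[st$agent, j] <- 1
      X2[n + 5L, j] <- 1  # previous action: rollout
      X2[(n + 7L):(3L * n + 6L), j] <- sim$wallmat[, b]
      X2[3L * n + 7L, j] <- st$t / st$T
      X2[(3L * n + 8L):D, j] <- got[[done[j]]][[arm]]$fb
    }
    g2 <- gru_forward(par, X2, h1[, done, drop = FALSE])
    pol2 <- heads_forward(par, g2$h)$policy
    for (j in seq_along(done)) {
      a1 <- got[[done[j]]][[arm]]$a1
      p_pre <- physical_policy(pol1[, done[j]])[a1]
      p_post <- physical_policy(pol2[, j])[a1]
      out <- rbind(out, data.frame(episode = keep[done[j]],
                                   success = (arm == "success"),
                                   a1 = a1, pi_pre = p_pre,
                                   pi_post = p_post))
    }
  }
  out
}

#' Estimate the size of the task space
#'
#' Samples \code{n} wall configurations, computes the fraction of identical
#' pairs among all n(n-1)/2 pairwise comparisons via exact layout hashing,
#' and returns \code{16 / fraction} (16 possible goals per layout). Repeats
#' \code{reps} times for a mean and s.e.m.
#'
#' @param n wall configurations per repetition (default 50,000)
#' @param reps repetitions (default 10)
#' @param side,periodic maze generator settings
#' @param sampler optional function() returning a hashable layout key;
#'   defaults to the package maze generator (used to validate the estimator
#'   on toy generators with known support)
#' @return list(mean, sem, estimates)
#' @export
estimate_task_space <- function(n = 50000, reps = 10, side = 4L,
                                periodic = TRUE, sampler = NULL) {
  if (is.null(sampler))
    sampler <- function() paste(sort(carve_wall_ids(side, periodic)),
                                collapse = ",")
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    keys <- character(n)
    for (i in seq_len(n)) {
      keys[i] <- sampler()
    }
    cnt <- table(keys)
    same <- sum(choose(as.numeric(cnt), 2))
    if (same == 0) {
      warning("no identical pairs observed; reporting a lower bound")
      same <- 1
    }
    frac <- same / choose(n, 2)
    est[r] <- side^2 / frac
  }
  list(mean = mean(est), sem = sd(est) / sqrt(reps), estimates = est)
}

#' Clamp the agent to a given physical trajectory
#'
#' Forces the physical actions to a prescribed sequence (e.g. a human
#' participant's) while still letting the agent sample rollouts with
#' probability pi(rollout). Records pi(rollout) at the first iteration in
#' each new state, averaged over \code{n_reps} repetitions.
#'
#' @param agent a \code{maze_agent}
#' @param maze the participant's maze
#' @param goal the goal cell
#' @param start start cell
#' @param actions integer vector of physical actions (1..4) taken from
#'   \code{start}
#' @param n_reps repetitions to average over (default 20)
#' @return numeric vector: mean pi(rollout) at each step (one per action)
#' @export
clamped_pi_rollout <- function(agent, maze, goal, start, actions,
                               n_reps = 20) {
  config <- agent$config
  par <- agent$params
  # validate the trajectory
  cell <- start
  for (a in actions) {
    if (!maze$open[cell, a])
      stop("clamped action ", a, " from cell ", cell,
           " is illegal under the maze walls")
    cell <- maze$trans[cell, a]
  }
  acc <- matrix(0, n_reps, length(actions))
  for (rep_i in seq_len(n_reps)) {
    st <- list(maze = maze, goal = goal, agent = start, t = 0, trial = 2L,
               T = config$episode_ms, pending_teleport = FALSE,
               teleport_obs_cell = NA_integer_,
               wallvec = wall_indicator(maze))
    h <- numeric(config$hidden_units)
    prev_a <- NULL; prev_r <- 0; fb <- NULL
    for (k in seq_along(actions)) {
      # first iteration in the new state: record pi(rollout)
      x <- observe(st, prev_a, prev_r, fb, config)
      as <- agent_step(par, h, x)
      h <- as$h
      acc[rep_i, k] <- as$policy[5]
      # keep sampling rollouts until the physical action is taken
      while (runif(1) < as$policy[5] && st$t < st$T) {
        ro <- run_rollout(par, h, st, config)
        st$t <- st$t + advance_clock("rollout", length(ro$actions), config)
        x <- observe(st, 5L, 0, ro$feedback, config)
        as <- agent_step(par, h, x)
        h <- as$h
      }
      res <- env_step(st, actions[k], config)
      st <- res$state
      st$pending_teleport <- FALSE  # clamped walk, no teleports
      st$teleport_obs_cell <- NA_integer_
      prev_a <- actions[k]; prev_r <- res$reward; fb <- NULL
    }
  }
  colMeans(acc)
}

#' Raw, distance and residual correlations with thinking time
#'
#' Pearson correlations between thinking times and (1) pi(rollout), (2) the
#' momentary distance to goal, and (3) pi(rollout) after subtracting the
#' per-distance means from both variables (the residual correlation).
#'
#' @param thinking_times numeric vector
#' @param pi_rollout numeric vector (same length)
#' @param distance_to_goal integer vector (same length)
#' @return named numeric vector (r_raw, r_distance, r_residual)
#' @export
residual_correlation <- function(thinking_times, pi_rollout,
                                 distance_to_goal) {
  stopifnot(length(thinking_times) == length(pi_rollout),
            length(thinking_times) == length(distance_to_goal))
  if (length(unique(distance_to_goal)) < 2)
    stop("residual correlation undefined with fewer than 2 distinct distances")
  r_raw <- cor(thinking_times, pi_rollout)
  r_dist <- cor(thinking_times, distance_to_goal)
  mt <- ave(thinking_times, distance_to_goal)
  mp <- ave(pi_rollout, distance_to_goal)
  r_res <- cor(thinking_times - mt, pi_rollout - mp)
  c(r_raw = r_raw, r_distance = r_dist, r_residual = r_res)
}

#' Value-function error against the true reward-to-go
#'
#' Compares V_k to the empirical reward-to-go R_k across episodes, and
#' against a constant control that predicts the global mean reward-to-go.
#'
#' @param agent a \code{maze_agent}
#' @param n_episodes episodes (default 200)
#' @return list(err = V_k - R_k, ctrl = Rbar - R_k)
#' @export
value_error <- function(agent, n_episodes = 200) {
  config <- agent$config
  states <- lapply(seq_len(n_episodes), function(i) init_episode(config))
  res <- simulate_batch(agent$params, config,
                        sim_init(agent$params, config, states),
                        sim_control(greedy = TRUE, record = "iters"))
  err <- c(); Rall <- c(); Vall <- c()
  for (lg in res$logs) {
    R <- compute_returns(lg$reward)
    keep <- lg$kind != "teleport"
    Vall <- c(Vall, lg$value[keep])
    Rall <- c(Rall, R[keep])
  }
  list(err = Vall - Rall, ctrl = mean(Rall) - Rall)
}

#' Cross-validated over-representation of successful rollouts by index
#'
#' Considers runs of consecutive rollouts during exploitation trials. Each
#' time the agent chooses to roll out, two independent samples are drawn
#' from the rollout process: the first drives the agent as usual, the
#' second is only scored. Success is the true goal appearing in the scored
#' imagined trajectory; the control is the mean analogous frequency over
#' the 14 cells that are neither the current location nor the goal.
#'
#' @param agent a \code{maze_agent}
#' @param n_episodes episodes (default 200)
#' @param max_index highest rollout index reported (default 3)
#' @return list(overrep, n (counts per index), succ_by_index, ctrl_base)
#' @export
agent_consecutive_overrepresentation <- function(agent, n_episodes = 200,
                                                 max_index = 3L) {
  config <- agent$config
  par <- agent$params
  succ <- lapply(seq_len(max_index), function(i) logical(0))
  ctrl <- c()
  for (ep in seq_len(n_episodes)) {
    st <- init_episode(config)
    h <- numeric(config$hidden_units)
    prev_a <- NULL; prev_r <- 0; fb <- NULL
    run_len <- 0L
    while (st$t < st$T) {
      x <- observe(st, prev_a, prev_r, fb, config)
      as <- agent_step(par, h, x)
      h <- as$h
      if (st$pending_teleport) {
        st <- env_teleport(st, config)
        prev_a <- NULL; prev_r <- 0; fb <- NULL
        run_len <- 0L
        next
      }
      a <- sample_action(as$policy, greedy = TRUE)
      if (a == 5L) {
        ro <- run_rollout(par, h, st, config)      # drives the agent
        ro2 <- run_rollout(par, h, st, config)     # scored only
        if (st$trial >= 2L) {
          run_len <- run_len + 1L
          if (run_len <= max_index) {
            hit <- st$goal %in% ro2$imagined_states
            succ[[run_len]] <- c(succ[[run_len]], hit)
            others <- setdiff(seq_len(config$side^2), c(st$agent, st$goal))
            ctrl <- c(ctrl, mean(others %in% ro2$imagined_states))
          }
        }
        st$t <- st$t + advance_clock("rollout", length(ro$actions), config)
        prev_a <- 5L; prev_r <- 0; fb <- ro$feedback
      } else {
        res <- env_step(st, a, config)
        st <- res$state
        prev_a <- a; prev_r <- res$reward; fb <- NULL
        run_len <- 0L
      }
    }
  }
  ctrl_base <- mean(ctrl)
  overrep <- vapply(seq_len(max_index), function(j)
    mean(succ[[j]]) / ctrl_base, numeric(1))
  list(overrep = overrep,
       n = vapply(succ, length, integer(1)),
       succ_by_index = vapply(succ, function(s) mean(s), numeric(1)),
       ctrl_base = ctrl_base)
}
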
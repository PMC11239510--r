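# Batched, resumable episode simulation.
#
# One call advances B episodes in lock-step, each column owning its own
# environment state, hidden state, previous-input fields and wall clock.
# Controls cover the analysis modes: greedy action selection, forbidding
# rollouts (policy renormalized over physical actions), forcing rollouts,
# forcing rollouts at a prescribed set of per-column iteration indices,
# zeroing the rollout feedback channel, stopping after the first
# teleportation, and ignoring the episode clock (used when measuring steps
# to goal in the release phase of the forced-rollout analysis).

sim_control <- function(greedy = FALSE, forbid_rollout = FALSE,
                        force_rollout = FALSE, forced_iters = NULL,
                        zero_feedback = FALSE, stop_after_teleport = FALSE,
                        stop_on_goal = FALSE, ignore_T = FALSE,
                        max_iters = Inf, record = "eval") {
  list(greedy = greedy, forbid_rollout = forbid_rollout,
       force_rollout = force_rollout, forced_iters = forced_iters,
       zero_feedback = zero_feedback,
       stop_after_teleport = stop_after_teleport,
       stop_on_goal = stop_on_goal, ignore_T = ignore_T,
       max_iters = max_iters, record = record)
}

# fresh per-column bookkeeping for B episodes
sim_init <- function(par, config, states) {
  B <- length(states)
  H <- nrow(par$Ur)
  n <- config$side^2
  wallmat <- vapply(states, function(s)
    if (is.null(s$wallvec)) wall_indicator(s$maze) else s$wallvec,
    numeric(2L * n))
  list(states = states,
       wallmat = matrix(wallmat, nrow = 2L * n),
       h = matrix(0, H, B),
       prev_action = rep(NA_integer_, B),
       prev_reward = numeric(B),
       feedback = matrix(0, 4L * config$planning_horizon + 1L, B),
       alive = rep(TRUE, B),
       iter = integer(B),          # per-column network iteration count
       reward_total = numeric(B),
       n_rollouts = integer(B),
       n_physical = integer(B),
       goal_reached = rep(FALSE, B))
}

# Advance a simulation snapshot until every column stops.
# Returns the updated snapshot plus records.
simulate_batch <- function(par, config, sim, control = sim_control()) {
  B <- length(sim$states)
  D <- obs_length(config)
  record_train <- identical(control$record, "train")
  record_iters <- identical(control$record, "iters")
  caches <- if (record_train) list() else NULL
  # per-column per-iteration logs (grown as lists, bound at the end)
  logs <- if (record_iters) lapply(seq_len(B), function(b)
    list(kind = character(0), action = integer(0), reward = numeric(0),
         value = numeric(0), trial = integer(0), cell = integer(0),
         policy = list())) else NULL
  k <- 0L
  while (any(sim$alive)) {
    k <- k + 1L
    idx <- which(sim$alive)
    m <- length(idx)
    n <- config$side^2
    # ---- observations (assembled in place; layout documented in env.R) ----
    cells <- integer(m); tfrac <- numeric(m); pend <- logical(m)
    for (i in seq_len(m)) {
      st <- sim$states[[idx[i]]]
      cells[i] <- if (!is.na(st$teleport_obs_cell)) st$teleport_obs_cell else st$agent
      tfrac[i] <- min(st$t / st$T, 1)
      pend[i] <- st$pending_teleport
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
    sim$h[, idx] <- g$h
    hd <- heads_forward(par, g$h)
    # ---- decide iteration kind per column ----
    kind <- rep("physical", m)
    action <- rep(NA_integer_, m)
    kind[pend] <- "teleport"
    free <- which(!pend)
    if (length(free)) {
      if (isTRUE(control$force_rollout)) {
        action[free] <- 5L
      } else {
        pol5 <- hd$policy[, free, drop = FALSE]
        restrict <- rep(isTRUE(control$forbid_rollout), length(free))
        if (!is.null(control$forced_iters)) {
          # deferral semantics: a scheduled rollout that collides with a
          # teleportation iteration is taken at the next free iteration, so
          # the per-episode rollout count is preserved
          forced <- vapply(seq_along(free), function(i) {
            b <- idx[free[i]]
            sum(control$forced_iters[[b]] <= sim$iter[b] + 1L) > sim$n_rollouts[b]
          }, logical(1))
          action[free[forced]] <- 5L
          restrict <- !forced  # non-forced iterations may not roll out
        }
        todo <- which(is.na(action[free]))
        if (length(todo)) {
          pol <- pol5[, todo, drop = FALSE]
          res_todo <- restrict[todo]
          pol[5L, res_todo] <- 0
          pol <- pol / rep(colSums(pol), each = 5L)
          if (control$greedy) {
            action[free[todo]] <- max.col(t(pol), ties.method = "first")
          } else {
            cum <- cumsum_cols(pol)
            action[free[todo]] <- pmin(colSums(cum <
              rep(runif(length(todo)), each = 5L)) + 1L, 5L)
          }
        }
      }
      kind[free] <- ifelse(action[free] == 5L, "rollout", "physical")
    }
    # ---- rollouts (batched over the rollout columns) ----
    roll_i <- which(kind == "rollout")
    new_fb <- matrix(0, nrow(sim$feedback), m)
    roll_len <- integer(m)
    if (length(roll_i)) {
      rb_cols <- idx[roll_i]
      if (isTRUE(control$zero_feedback)) {
        roll_len[roll_i] <- config$planning_horizon  # cost accounting only
      } else {
        rb <- rollout_batch(par, sim$h[, rb_cols, drop = FALSE],
                            sim$states[rb_cols], config,
                            wallcols = sim$wallmat[, rb_cols, drop = FALSE],
                            tfrac = tfrac[roll_i])
        new_fb[, roll_i] <- rb$feedback
        roll_len[roll_i] <- rb$lengths
      }
    }
    # ---- environment updates ----
    wm_s <- rep(NA_integer_, m); wm_g <- rep(NA_integer_, m)
    rew <- numeric(m)
    for (i in seq_len(m)) {
      b <- idx[i]
      st <- sim$states[[b]]
      cell_before <- if (!is.na(st$teleport_obs_cell)) st$teleport_obs_cell else st$agent
      if (record_iters) {
        lg <- logs[[b]]
        lg$kind <- c(lg$kind, kind[i]); lg$action <- c(lg$action, action[i])
        lg$value <- c(lg$value, hd$value[i]); lg$trial <- c(lg$trial, st$trial)
        lg$cell <- c(lg$cell, cell_before)
        lg$policy <- c(lg$policy, list(hd$policy[, i]))
        logs[[b]] <- lg
      }
      if (kind[i] == "teleport") {
        sim$states[[b]] <- env_teleport(st, config)
        sim$prev_action[b] <- NA_integer_
        sim$prev_reward[b] <- 0
        sim$feedback[, b] <- 0
      } else if (kind[i] == "rollout") {
        st$t <- st$t + advance_clock("rollout", roll_len[i], config)
        sim$states[[b]] <- st
        sim$prev_action[b] <- 5L
        sim$prev_reward[b] <- 0
        sim$feedback[, b] <- new_fb[, i]
        sim$n_rollouts[b] <- sim$n_rollouts[b] + 1L
      } else {
        res <- env_step(st, action[i], config,
                        enforce_time = !control$ignore_T)
        sim$states[[b]] <- res$state
        rew[i] <- res$reward
        sim$reward_total[b] <- sim$reward_total[b] + res$reward
        sim$prev_action[b] <- action[i]
        sim$prev_reward[b] <- res$reward
        sim$feedback[, b] <- 0
        sim$n_physical[b] <- sim$n_physical[b] + 1L
        wm_s[i] <- res$state$agent
        wm_g[i] <- res$state$goal
        if (res$goal_reached) sim$goal_reached[b] <- TRUE
      }
      if (record_iters) {
        lg <- logs[[b]]
        lg$reward <- c(lg$reward, rew[i])
        logs[[b]] <- lg
      }
      sim$iter[b] <- sim$iter[b] + 1L
      # ---- stopping ----
      stop_b <- FALSE
      if (!control$ignore_T && sim$states[[b]]$t >= sim$states[[b]]$T) stop_b <- TRUE
      if (control$stop_after_teleport && kind[i] == "teleport") stop_b <- TRUE
      if (control$stop_on_goal && kind[i] == "physical" && rew[i] > 0) stop_b <- TRUE
      if (sim$iter[b] >= control$max_iters) stop_b <- TRUE
      if (stop_b) sim$alive[b] <- FALSE
    }
    if (record_train)
      caches[[k]] <- list(idx = idx, X = X, action = action, kind = kind,
                          wm_s = wm_s, wm_g = wm_g, reward = rew)
  }
  out <- list(sim = sim)
  if (record_train) out$caches <- caches
  if (record_iters) out$logs <- logs
  out
}

#' Run a single episode with a trained agent
#'
#' @param agent a \code{maze_agent}
#' @param maze optional \code{maze}; generated if NULL
#' @param greedy greedy action selection (default TRUE, as at test time)
#' @param record \code{"eval"} or \code{"iters"} for a per-iteration trace
#' @return a list with total reward, counts, and (optionally) the trace
#' @export
run_episode <- function(agent, maze = NULL, greedy = TRUE, record = "iters") {
  config <- agent$config
  sim <- sim_init(agent$params, config, list(init_episode(config, maze)))
  res <- simulate_batch(agent$params, config, sim,
                        sim_control(greedy = greedy, record = record))
  trace <- if (!is.null(res$logs)) res$logs[[1]] else NULL
  list(reward = res$sim$reward_total[1],
       n_rollouts = res$sim$n_rollouts[1],
       n_physical = res$sim$n_physical[1],
       n_iters = res$sim$iter[1],
       trace = trace,
       final = res$sim)
}

#' Evaluate an agent over many episodes
#'
#' @param agent a \code{maze_agent}
#' @param n_episodes number of fresh episodes
#' @param greedy greedy action selection
#' @param forbid_rollout renormalize the policy over physical actions
#'   (rollout ablation)
#' @return data.frame with one row per episode: reward, rollouts, physical
#'   steps, iterations and rollout fraction
#' @export
evaluate_agent <- function(agent, n_episodes = 100, greedy = TRUE,
                           forbid_rollout = FALSE) {
  config <- agent$config
  states <- lapply(seq_len(n_episodes), function(i) init_episode(config))
  sim <- sim_init(agent$params, config, states)
  res <- simulate_batch(agent$params, config, sim,
                        sim_control(greedy = greedy,
                                    forbid_rollout = forbid_rollout))
  s <- res$sim
  data.frame(reward = s$reward_total, n_rollouts = s$n_rollouts,
             n_physical = s$n_physical, n_iters = s$iter,
             rollout_fraction = ifelse(s$iter > 0, s$n_rollouts / s$iter, NA))
}

#' @export
simulate.maze_agent <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  evaluate_agent(object, n_episodes = nsim, ...)
}
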
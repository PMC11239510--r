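# Episode state and dynamics.
#
# Wall-clock accounting: a physical action or a teleportation step advances
# the clock by `action_ms` (400 ms); a rollout advances it by `rollout_ms`
# (120 ms) or, in the proportional-cost variant, by l * 24 ms for a rollout
# of l imagined actions. An episode ends once t >= T.

#' Default timing / architecture configuration
#'
#' @param hidden_units GRU hidden units
#' @param planning_horizon maximum imagined actions per rollout
#' @param action_ms wall-clock cost of a physical action or teleport (ms)
#' @param rollout_ms wall-clock cost of a rollout in fixed-cost mode (ms)
#' @param per_step_rollout_ms per-imagined-action cost in proportional mode
#' @param episode_ms episode duration T (ms)
#' @param side maze side length
#' @param periodic periodic boundaries?
#' @param rollout_cost \code{"fixed"} or \code{"proportional"}
#' @return a list of class \code{agent_config}
#' @export
agent_config <- function(hidden_units = 100L, planning_horizon = 8L,
                         action_ms = 400, rollout_ms = 120,
                         per_step_rollout_ms = 24, episode_ms = 20000,
                         side = 4L, periodic = TRUE, rollout_cost = "fixed") {
  stopifnot(hidden_units > 0, planning_horizon >= 1, action_ms > 0,
            rollout_ms > 0, episode_ms > 0,
            rollout_cost %in% c("fixed", "proportional"))
  structure(list(hidden_units = as.integer(hidden_units),
                 planning_horizon = as.integer(planning_horizon),
                 action_ms = action_ms, rollout_ms = rollout_ms,
                 per_step_rollout_ms = per_step_rollout_ms,
                 episode_ms = episode_ms, side = as.integer(side),
                 periodic = isTRUE(periodic), rollout_cost = rollout_cost),
            class = "agent_config")
}

#' Clock increment for one network iteration
#'
#' @param kind \code{"physical"} (also used for teleport steps) or
#'   \code{"rollout"}
#' @param rollout_length number of imagined actions (proportional mode only)
#' @param config an \code{agent_config}
#' @return milliseconds
#' @export
advance_clock <- function(kind, rollout_length = 0L, config = agent_config()) {
  if (kind == "physical") return(config$action_ms)
  if (kind == "rollout") {
    if (config$rollout_cost == "proportional")
      return(rollout_length * config$per_step_rollout_ms)
    return(config$rollout_ms)
  }
  stop("unknown iteration kind: ", kind)
}

#' Initialise an episode
#'
#' Samples a maze (unless given), a hidden goal uniformly at random, and a
#' start location uniformly among the non-goal cells.
#'
#' @param config an \code{agent_config}
#' @param maze optional pre-built \code{maze}
#' @return an environment state (list)
#' @export
init_episode <- function(config = agent_config(), maze = NULL) {
  if (is.null(maze)) maze <- generate_maze(config$side, config$periodic)
  n <- maze$side^2
  goal <- sample.int(n, 1L)
  agent <- sample(setdiff(seq_len(n), goal), 1L)
  list(maze = maze, goal = goal, agent = agent, t = 0, trial = 1L,
       T = config$episode_ms, pending_teleport = FALSE,
       teleport_obs_cell = NA_integer_,
       wallvec = wall_indicator(maze))
}

#' Advance the environment by one physical action
#'
#' A move into a wall leaves the agent in place (reward 0). A move onto the
#' goal yields reward 1; the agent transitions to the goal cell and a
#' teleportation step is scheduled: on the next network iteration the agent
#' observes the goal cell with the reward, its policy output is ignored, and
#' \code{env_teleport} relocates it uniformly at random among non-goal cells.
#'
#' @param state environment state from \code{init_episode}
#' @param action integer in 1..4 (up, down, left, right)
#' @param config an \code{agent_config}
#' @param enforce_time error when the episode clock is exhausted (TRUE for
#'   normal episodes; analyses that measure steps-to-goal outside the
#'   episode clock disable it)
#' @return list(state, reward, goal_reached)
#' @export
env_step <- function(state, action, config = agent_config(),
                     enforce_time = TRUE) {
  action <- as.integer(action)
  if (is.na(action) || action < 1L || action > 4L)
    stop("invalid physical action index: ", action)
  if (enforce_time && state$t >= state$T) stop("episode is over (t >= T)")
  if (state$pending_teleport)
    stop("cannot act on a teleportation iteration; call env_teleport()")
  reward <- 0
  state$agent <- state$maze$trans[state$agent, action]
  state$t <- state$t + advance_clock("physical", config = config)
  goal_reached <- state$agent == state$goal
  if (goal_reached) {
    reward <- 1
    state$pending_teleport <- TRUE
    state$teleport_obs_cell <- state$goal
  }
  list(state = state, reward = reward, goal_reached = goal_reached)
}

#' Execute a scheduled teleportation step
#'
#' Relocates the agent uniformly at random among the non-goal cells, advances
#' the clock by one action duration and increments the trial counter.
#'
#' @param state environment state with a pending teleport
#' @param config an \code{agent_config}
#' @return updated state
#' @export
env_teleport <- function(state, config = agent_config()) {
  stopifnot(state$pending_teleport)
  n <- state$maze$side^2
  state$agent <- sample(setdiff(seq_len(n), state$goal), 1L)
  state$trial <- state$trial + 1L
  state$t <- state$t + advance_clock("physical", config = config)
  state$pending_teleport <- FALSE
  state$teleport_obs_cell <- NA_integer_
  state
}

# Observation layout (side = 4): total length 88
#  1:16  agent location (one-hot)
# 17:21  previous action (one-hot over 5 actions; all-zero at episode start)
#    22  previous reward
# 23:54  wall layout (32 slots, canonical edge order; absent wrap edges of
#        bounded mazes are encoded as walls)
#    55  elapsed time t / T
# 56:88  rollout feedback (8 slots x 4 action indicators + success bit;
#        all-zero when the previous iteration was not a rollout)
obs_length <- function(config) {
  n <- config$side^2
  n + 5L + 1L + 2L * n + 1L + (4L * config$planning_horizon + 1L)
}

wall_indicator <- function(maze) {
  # canonical 2n-slot edge indicator on the periodic lattice of same side;
  # the absent wrap edges of a bounded maze are encoded as walls
  lat <- lattice(maze$side, maze$periodic)
  w <- numeric(2L * lat$n)
  w[lat$wrap_missing] <- 1
  w[maze$wall_ids] <- 1
  w
}

#' Encode the network input for one iteration
#'
#' @param state environment state (the observed cell is the goal cell on a
#'   teleportation iteration, otherwise the agent's location)
#' @param prev_action previous action index (1..5) or NULL at episode start
#' @param prev_reward previous reward (0/1)
#' @param feedback rollout feedback vector (length 4 * horizon + 1) or NULL
#' @param config an \code{agent_config}
#' @param cell optional explicit cell override (used for imagined inputs)
#' @param t_override optional elapsed-time override (ms)
#' @return numeric observation vector
#' @export
observe <- function(state, prev_action = NULL, prev_reward = 0,
                    feedback = NULL, config = agent_config(), cell = NULL,
                    t_override = NULL) {
  n <- state$maze$side^2
  fb_len <- 4L * config$planning_horizon + 1L
  if (is.null(feedback)) feedback <- numeric(fb_len)
  if (length(feedback) != fb_len)
    stop("rollout feedback must have length ", fb_len)
  if (is.null(cell)) {
    cell <- if (!is.na(state$teleport_obs_cell)) state$teleport_obs_cell else state$agent
  }
  loc <- numeric(n); loc[cell] <- 1
  act <- numeric(5)
  if (!is.null(prev_action) && !is.na(prev_action)) act[prev_action] <- 1
  tt <- if (is.null(t_override)) state$t else t_override
  wv <- if (is.null(state$wallvec)) wall_indicator(state$maze) else state$wallvec
  c(loc, act, prev_reward, wv, tt / state$T, feedback)
}

# decode helper used in tests and validation
decode_observation <- function(x, config = agent_config()) {
  n <- config$side^2
  i <- 0L
  loc <- which(x[(i + 1):(i + n)] == 1); i <- i + n
  act <- which(x[(i + 1):(i + 5)] == 1); i <- i + 5L
  rew <- x[i + 1]; i <- i + 1L
  walls <- x[(i + 1):(i + 2 * n)]; i <- i + 2L * n
  tfrac <- x[i + 1]; i <- i + 1L
  fb <- x[(i + 1):length(x)]
  list(cell = if (length(loc)) loc else NA_integer_,
       prev_action = if (length(act)) act else NA_integer_,
       prev_reward = rew, walls = walls, t_frac = tfrac, feedback = fb)
}
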
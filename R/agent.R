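# GRU agent with policy / value / world-model heads.
#
# Parameters (H = hidden units, D = observation length, n = side^2):
#   Wr, Wz, Wn : H x D input weights;  Ur, Uz, Un : H x H recurrent weights
#   br, bz, bn, cn : H biases (cn is the recurrent bias inside the candidate)
#   Wp : 5 x H policy head, bp;  wv : 1 x H value head, bv
#   W1 : 33 x (H + 5) world-model hidden layer, b1; W2 : 2n x 33 output, b2
# The world-model output splits into a next-state 16-simplex and a goal
# 16-simplex (softmax over each half).

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(z) {
  # logits are bounded in this model (tanh hidden states, moderate weights),
  # so the max-subtraction stabilisation is only engaged for large values
  if (max(z) > 60) {
    cmax <- z[1, ]
    for (r in seq_len(nrow(z))[-1]) {
      zr <- z[r, ]; w <- zr > cmax; cmax[w] <- zr[w]
    }
    z <- z - rep(cmax, each = nrow(z))
  }
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# column-wise cumulative sums of a small matrix (rows accumulate downward)
cumsum_cols <- function(m) {
  for (r in seq_len(nrow(m))[-1]) m[r, ] <- m[r, ] + m[r - 1, ]
  m
}

#' Initialise agent parameters
#'
#' @param config an \code{agent_config}
#' @param init_scale multiplier on the Glorot-style initialisation
#' @return list of parameter matrices
#' @export
init_params <- function(config = agent_config(), init_scale = 1) {
  H <- config$hidden_units
  D <- obs_length(config)
  n <- config$side^2
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = init_scale * sqrt(2 / (nr + nc))), nr, nc)
  list(Wr = g(H, D), Wz = g(H, D), Wn = g(H, D),
       Ur = g(H, H), Uz = g(H, H), Un = g(H, H),
       br = numeric(H), bz = numeric(H), bn = numeric(H), cn = numeric(H),
       Wp = g(5L, H), bp = numeric(5),
       wv = g(1L, H), bv = numeric(1),
       W1 = g(33L, H + 5L), b1 = numeric(33),
       W2 = g(2L * n, 33L), b2 = numeric(2L * n))
}

# Batched GRU step: X is D x B, H_prev is H x B. Returns caches for BPTT.
gru_forward <- function(par, X, H_prev) {
  r <- sigmoid(par$Wr %*% X + par$Ur %*% H_prev + par$br)
  z <- sigmoid(par$Wz %*% X + par$Uz %*% H_prev + par$bz)
  un <- par$Un %*% H_prev + par$cn
  nn <- tanh(par$Wn %*% X + par$bn + r * un)
  h <- (1 - z) * nn + z * H_prev
  list(h = h, r = r, z = z, nn = nn, un = un)
}

# Policy / value heads on a batch of hidden states (H x B)
heads_forward <- function(par, h) {
  logits <- par$Wp %*% h + par$bp
  list(logits = logits, policy = softmax_cols(logits),
       value = drop(par$wv %*% h) + par$bv)
}

# World model on a batch: h is H x B, a_onehot is 5 x B
wm_forward <- function(par, h, a_onehot) {
  inp <- rbind(h, a_onehot)
  z1 <- par$W1 %*% inp + par$b1
  a1 <- z1 * (z1 > 0)
  logits <- par$W2 %*% a1 + par$b2
  n <- nrow(logits) / 2L
  list(inp = inp, z1 = z1, a1 = a1, logits = logits,
       s_dist = softmax_cols(logits[seq_len(n), , drop = FALSE]),
       g_dist = softmax_cols(logits[n + seq_len(n), , drop = FALSE]))
}

#' One iteration of the recurrent network
#'
#' @param par agent parameters
#' @param h hidden state vector (length \code{hidden_units})
#' @param x observation vector
#' @return list with updated hidden state \code{h}, the 5-way \code{policy},
#'   the scalar \code{value} and the forward caches
#' @export
agent_step <- function(par, h, x) {
  if (length(h) != nrow(par$Ur)) stop("hidden state has wrong length")
  if (length(x) != ncol(par$Wr)) stop("observation has wrong length")
  g <- gru_forward(par, matrix(x, ncol = 1), matrix(h, ncol = 1))
  hd <- heads_forward(par, g$h)
  list(h = drop(g$h), policy = drop(hd$policy), value = hd$value,
       cache = g)
}

#' Predict next state and goal distributions with the world model
#'
#' @param par agent parameters
#' @param h hidden state vector
#' @param a action index (1..5)
#' @return list(next_state_dist, goal_dist), each on the simplex over cells
#' @export
predict_world <- function(par, h, a) {
  stopifnot(a >= 1, a <= 5)
  ao <- numeric(5); ao[a] <- 1
  wm <- wm_forward(par, matrix(h, ncol = 1), matrix(ao, ncol = 1))
  list(next_state_dist = drop(wm$s_dist), goal_dist = drop(wm$g_dist))
}

#' Sample (or select greedily) an action from a policy
#'
#' @param policy probability vector on the simplex
#' @param greedy if TRUE, take the argmax (ties broken to the lowest index)
#' @return integer action index
#' @export
sample_action <- function(policy, greedy = FALSE) {
  if (any(policy < -1e-9) || abs(sum(policy) - 1) > 1e-6)
    stop("policy is not a probability vector")
  if (greedy) return(which.max(policy))
  sample.int(length(policy), 1L, prob = pmax(policy, 0))
}

# renormalize a 5-way policy over the 4 physical actions
physical_policy <- function(policy) {
  p <- policy[1:4]
  p / sum(p)
}

#' Encode / decode the rollout feedback vector
#'
#' Layout: \code{horizon} slots of 4 physical-action indicators (unused slots
#' zero), followed by a single success bit; total length 4 * horizon + 1.
#'
#' @param actions integer vector of imagined actions (1..4)
#' @param success logical
#' @param horizon planning horizon
#' @return numeric feedback vector
#' @export
feedback_encode <- function(actions, success, horizon = 8L) {
  fb <- numeric(4L * horizon + 1L)
  for (j in seq_along(actions)) fb[4L * (j - 1L) + actions[j]] <- 1
  fb[4L * horizon + 1L] <- as.numeric(success)
  fb
}

#' @rdname feedback_encode
#' @param feedback numeric feedback vector
#' @export
feedback_decode <- function(feedback, horizon = 8L) {
  acts <- integer(0)
  for (j in seq_len(horizon)) {
    slot <- feedback[4L * (j - 1L) + 1:4]
    if (!any(slot == 1)) break
    acts <- c(acts, which(slot == 1))
  }
  list(actions = acts, success = feedback[4L * horizon + 1L] == 1)
}

# Batched rollout for a subset of episodes.
#   par     : parameters
#   h       : H x B hidden states at the rollout decision
#   states  : list of B environment states (for walls / location / time)
#   config  : agent_config
# Imagined actions are sampled from the policy renormalized over the four
# physical actions; the imagined next state is the argmax of the world
# model's next-state distribution; the imagined goal is the argmax of the
# goal distribution at the first imagined step and is held fixed. The loop
# stops at the horizon or when the imagined state reaches the imagined goal.
# The caller's hidden state and environment are never modified.
rollout_batch <- function(par, h, states, config, wallcols = NULL,
                          tfrac = NULL) {
  B <- ncol(h)
  n <- config$side^2
  D <- obs_length(config)
  horizon <- config$planning_horizon
  if (is.null(wallcols))
    wallcols <- vapply(states, function(s)
      if (is.null(s$wallvec)) wall_indicator(s$maze) else s$wallvec,
      numeric(2L * n))
  wallcols <- matrix(wallcols, nrow = 2L * n)
  if (is.null(tfrac))
    tfrac <- vapply(states, function(s) s$t / s$T, numeric(1))
  h_im <- h
  cells <- vapply(states, function(s) s$agent, integer(1))
  goals_im <- rep(NA_integer_, B)
  actions <- matrix(0L, horizon, B)
  imagined <- matrix(NA_integer_, horizon, B)
  success <- rep(FALSE, B)
  lens <- integer(B)
  active <- rep(TRUE, B)
  s_im <- cells
  for (j in seq_len(horizon)) {
    if (!any(active)) break
    idx <- which(active)
    m <- length(idx)
    hd <- heads_forward(par, h_im[, idx, drop = FALSE])
    pphys <- hd$policy[1:4, , drop = FALSE]
    pphys <- pphys / rep(colSums(pphys), each = 4L)
    # inverse-CDF sampling, vectorized over columns
    cum <- cumsum_cols(pphys)
    a_j <- pmin(colSums(cum < rep(runif(m), each = 4L)) + 1L, 4L)
    ao <- matrix(0, 5, m)
    ao[cbind(a_j, seq_len(m))] <- 1
    wm <- wm_forward(par, h_im[, idx, drop = FALSE], ao)
    s_next <- max.col(t(wm$s_dist), ties.method = "first")
    if (j == 1L) goals_im[idx] <- max.col(t(wm$g_dist), ties.method = "first")
    actions[j, idx] <- a_j
    imagined[j, idx] <- s_next
    lens[idx] <- j
    s_im[idx] <- s_next
    reached <- s_next == goals_im[idx]
    success[idx[reached]] <- TRUE
    # imagined observation and hidden-state update for states that continue
    cont_i <- which(!reached)
    if (j == horizon) cont_i <- integer(0)
    if (length(cont_i)) {
      cont <- idx[cont_i]
      mc <- length(cont)
      Xim <- matrix(0, D, mc)
      Xim[cbind(s_im[cont], seq_len(mc))] <- 1
      Xim[cbind(n + a_j[cont_i], seq_len(mc))] <- 1
      Xim[(n + 7L):(3L * n + 6L), ] <- wallcols[, cont]
      Xim[3L * n + 7L, ] <- tfrac[cont]
      g <- gru_forward(par, Xim, h_im[, cont, drop = FALSE])
      h_im[, cont] <- g$h
    }
    active[idx[reached]] <- FALSE
    if (j == horizon) active[] <- FALSE
  }
  fb <- matrix(0, 4L * horizon + 1L, B)
  nz <- which(actions > 0L, arr.ind = TRUE)
  if (nrow(nz))
    fb[cbind(4L * (nz[, 1] - 1L) + actions[nz], nz[, 2])] <- 1
  fb[4L * horizon + 1L, success] <- 1
  list(actions = actions, lengths = lens, success = success,
       imagined_goal = goals_im, imagined_states = imagined,
       final_state = s_im, feedback = fb)
}

#' Sample a policy rollout
#'
#' Simulates up to \code{planning_horizon} imagined actions from the agent's
#' own policy through its learned world model, starting from the current
#' hidden state and location. Returns the imagined trajectory and the
#' feedback vector that is appended to the next network input. The caller's
#' hidden state and environment state are not modified, and no gradients are
#' ever propagated through this process during training.
#'
#' @param par agent parameters
#' @param h hidden state vector
#' @param state environment state
#' @param config an \code{agent_config}
#' @return list of class \code{rollout} with fields \code{actions},
#'   \code{imagined_states}, \code{imagined_goal}, \code{success},
#'   \code{feedback}
#' @export
run_rollout <- function(par, h, state, config = agent_config()) {
  if (state$pending_teleport)
    stop("rollouts are not possible on a teleportation iteration")
  rb <- rollout_batch(par, matrix(h, ncol = 1), list(state), config)
  len <- rb$lengths[1]
  structure(list(actions = rb$actions[seq_len(len), 1],
                 imagined_states = rb$imagined_states[seq_len(len), 1],
                 imagined_goal = rb$imagined_goal[1],
                 success = rb$success[1],
                 final_state = rb$final_state[1],
                 feedback = rb$feedback[, 1]),
            class = "rollout")
}

#' @export
print.rollout <- function(x, ...) {
  cat(sprintf("rollout: %s (%s), imagined goal %d\n",
              paste(ACTIONS[x$actions], collapse = " "),
              if (x$success) "successful" else "unsuccessful",
              x$imagined_goal))
  invisible(x)
}

# ---- parameter (un)flattening, used by Adam and finite differences ----

flatten_params <- function(par) unlist(par, use.names = FALSE)

unflatten_params <- function(theta, template) {
  out <- template
  i <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    v <- theta[(i + 1):(i + len)]
    if (is.matrix(template[[nm]]))
      out[[nm]] <- matrix(v, nrow(template[[nm]]), ncol(template[[nm]]))
    else out[[nm]] <- v
    i <- i + len
  }
  out
}

# ---- checkpoints ----

#' Save / load an agent checkpoint (portable JSON)
#'
#' @param agent a \code{maze_agent}
#' @param path file path
#' @export
save_agent <- function(agent, path) {
  stopifnot(inherits(agent, "maze_agent"))
  obj <- list(format_version = 1L,
              config = unclass(agent$config),
              n_episodes_trained = agent$n_episodes_trained,
              learning_curve = agent$learning_curve,
              params = lapply(agent$params, function(m) {
                if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
                else list(dim = NULL, data = as.numeric(m))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  cfg <- do.call(agent_config, obj$config[names(obj$config) %in%
                   names(formals(agent_config))])
  new_maze_agent(par, cfg, obj$learning_curve, obj$n_episodes_trained)
}

new_maze_agent <- function(params, config, learning_curve = NULL,
                           n_episodes_trained = 0L) {
  structure(list(params = params, config = config,
                 learning_curve = learning_curve,
                 n_episodes_trained = n_episodes_trained),
            class = "maze_agent")
}

#' @export
print.maze_agent <- function(x, ...) {
  cat(sprintf("maze_agent: %d GRU units, horizon %d, trained on %d episodes\n",
              x$config$hidden_units, x$config$planning_horizon,
              x$n_episodes_trained))
  if (!is.null(x$learning_curve) && length(x$learning_curve$mean_reward))
    cat(sprintf("  final mean reward/episode: %.2f\n",
                tail(x$learning_curve$mean_reward, 1)))
  invisible(x)
}

#' @export
summary.maze_agent <- function(object, n_episodes = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- evaluate_agent(object, n_episodes = n_episodes)
  out <- list(config = object$config,
              n_episodes_trained = object$n_episodes_trained,
              mean_reward = mean(res$reward),
              sem_reward = sd(res$reward) / sqrt(length(res$reward)),
              rollout_fraction = mean(res$rollout_fraction, na.rm = TRUE))
  class(out) <- "summary.maze_agent"
  out
}

#' @export
print.summary.maze_agent <- function(x, ...) {
  cat(sprintf("maze_agent (%d units), %d training episodes\n",
              x$config$hidden_units, x$n_episodes_trained))
  cat(sprintf("  evaluation reward/episode: %.2f +- %.2f (s.e.m.)\n",
              x$mean_reward, x$sem_reward))
  cat(sprintf("  fraction of iterations that are rollouts: %.3f\n",
              x$rollout_fraction))
  invisible(x)
}
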
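# On-policy actor-critic training with auxiliary world-model and entropy
# objectives. The surrogate loss minimised by Adam is, per episode,
#   sum_k [ -adv_k * log pi_k(a_k)            (actor; adv treated constant)
#           + 0.5 * beta_v * (V_k - R_k)^2    (critic)
#           + beta_e * sum_a pi log pi        (negative entropy)
#           + beta_p * CE(world model) ]      (next state + goal)
# averaged over the episodes of a batch. Policy, entropy and value terms are
# evaluated at iterations where an action was sampled (physical or rollout);
# teleportation iterations are ignored. The world-model cross-entropy is
# evaluated at physical-action iterations, where a true next state exists.
# Gradients never flow through the rollout process: rollout feedback enters
# the next observation as data.

#' Training configuration
#'
#' @param n_batches number of Adam updates
#' @param episodes_per_batch episodes per batch (default 40)
#' @param lr Adam learning rate
#' @param beta_v,beta_e,beta_p auxiliary loss weights
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters
#' @param grad_clip global gradient-norm clip (Inf = none)
#' @param log_every record the learning curve every this many batches
#' @return list of class \code{train_config}
#' @export
train_config <- function(n_batches = 200000L, episodes_per_batch = 40L,
                         lr = 1e-3, beta_v = 0.05, beta_e = 0.05,
                         beta_p = 0.5, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, grad_clip = Inf, log_every = 10L) {
  stopifnot(beta_v >= 0, beta_e >= 0, beta_p >= 0, lr >= 0)
  structure(as.list(environment()), class = "train_config")
}

#' Reward-to-go of an episode
#'
#' \code{R_k = sum_{k' >= k} r_{k'}}: the empirical cumulative future reward
#' from iteration k onward.
#'
#' @param rewards numeric vector of per-iteration rewards
#' @return numeric vector of the same length
#' @export
compute_returns <- function(rewards) {
  rev(cumsum(rev(rewards)))
}

# per-column own-iteration returns for a training batch
batch_returns <- function(caches, B) {
  rew <- lapply(seq_len(B), function(b) numeric(0))
  for (ck in caches) {
    for (i in seq_along(ck$idx)) {
      b <- ck$idx[i]
      rew[[b]] <- c(rew[[b]], ck$reward[i])
    }
  }
  lapply(rew, compute_returns)
}

# Forward (and optionally backward) pass over a recorded batch.
# caches: list over iterations with idx, X, action, kind, wm_s, wm_g, reward.
# advantages: optional list per column of fixed advantage values; when NULL,
# advantages are computed as R_k - V_k from this parameter set (and treated
# as constants in the actor term, exactly as in the update rule).
batch_pass <- function(par, caches, B, config, tc, advantages = NULL,
                       grads = FALSE) {
  H <- nrow(par$Ur)
  n <- config$side^2
  Rs <- batch_returns(caches, B)
  Rflat <- unlist(Rs)
  offs <- c(0L, cumsum(vapply(Rs, length, integer(1))))[seq_len(B)]
  advflat <- if (!is.null(advantages)) unlist(advantages) else NULL
  K <- length(caches)
  h <- matrix(0, H, B)
  pos <- integer(B)  # own-iteration counter per column
  fw <- vector("list", K)
  loss_pol <- 0; loss_v <- 0; loss_h <- 0; loss_p <- 0
  adv_store <- if (is.null(advantages)) numeric(length(Rflat)) else NULL
  for (k in seq_len(K)) {
    ck <- caches[[k]]
    idx <- ck$idx
    Hprev <- h[, idx, drop = FALSE]
    g <- gru_forward(par, ck$X, Hprev)
    h[, idx] <- g$h
    hd <- heads_forward(par, g$h)
    m <- length(idx)
    act_mask <- ck$kind != "teleport"
    wm_mask <- !is.na(ck$wm_s)
    # advantages and returns aligned to each column's own iteration index
    pos[idx] <- pos[idx] + 1L
    slot <- offs[idx] + pos[idx]
    Rk <- Rflat[slot]
    if (is.null(advantages)) {
      adv <- Rk - hd$value
      adv_store[slot] <- adv
    } else {
      adv <- advflat[slot]
    }
    pol <- hd$policy
    logpol <- log(pmax(pol, 1e-12))
    ai <- ck$action
    am <- which(act_mask)
    if (length(am)) {
      loss_pol <- loss_pol - sum(adv[am] * logpol[cbind(ai[am], am)])
      loss_v <- loss_v + 0.5 * sum((hd$value[am] - Rk[am])^2)
      loss_h <- loss_h + sum(pol[, am] * logpol[, am])
    }
    wmc <- NULL
    if (any(wm_mask)) {
      wi <- which(wm_mask)
      ao <- matrix(0, 5, length(wi))
      ao[cbind(ai[wi], seq_along(wi))] <- 1
      wmc <- wm_forward(par, g$h[, wi, drop = FALSE], ao)
      jj <- seq_along(wi)
      loss_p <- loss_p -
        sum(log(pmax(wmc$s_dist[cbind(ck$wm_s[wi], jj)], 1e-12))) -
        sum(log(pmax(wmc$g_dist[cbind(ck$wm_g[wi], jj)], 1e-12)))
    }
    fw[[k]] <- list(g = g, Hprev = Hprev, hd = hd, wmc = wmc,
                    adv = adv, Rk = Rk, act_mask = act_mask,
                    wm_mask = wm_mask)
  }
  total <- (loss_pol + tc$beta_v * loss_v + tc$beta_e * loss_h +
              tc$beta_p * loss_p) / B
  adv_list <- if (is.null(advantages)) {
    lens <- vapply(Rs, length, integer(1))
    split(adv_store, rep(seq_len(B), lens))
  } else advantages
  out <- list(loss = total,
              terms = c(actor = loss_pol / B, value = loss_v / B,
                        entropy = loss_h / B, predictive = loss_p / B),
              advantages = adv_list)
  if (!grads) return(out)

  # ---- backward ----
  gr <- lapply(par, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
               else numeric(length(p)))
  dH <- matrix(0, H, B)
  for (k in rev(seq_len(K))) {
    ck <- caches[[k]]
    f <- fw[[k]]
    idx <- ck$idx
    m <- length(idx)
    pol <- f$hd$policy
    logpol <- log(pmax(pol, 1e-12))
    dlogits <- matrix(0, 5, m)
    dV <- numeric(m)
    am <- which(f$act_mask)
    if (length(am)) {
      E <- matrix(0, 5, length(am))
      E[cbind(ck$action[am], seq_along(am))] <- 1
      ent_sum <- colSums(pol[, am, drop = FALSE] * logpol[, am, drop = FALSE])
      dlogits[, am] <- -rep(f$adv[am], each = 5L) *
        (E - pol[, am, drop = FALSE]) +
        tc$beta_e * pol[, am, drop = FALSE] *
          (logpol[, am, drop = FALSE] - rep(ent_sum, each = 5L))
      dV[am] <- tc$beta_v * (f$hd$value[am] - f$Rk[am])
    }
    dh <- crossprod(par$Wp, dlogits) + crossprod(par$wv, matrix(dV, 1)) +
      dH[, idx, drop = FALSE]
    gr$Wp <- gr$Wp + tcrossprod(dlogits, f$g$h)
    gr$bp <- gr$bp + rowSums(dlogits)
    gr$wv <- gr$wv + matrix(dV, 1) %*% t(f$g$h)
    gr$bv <- gr$bv + sum(dV)
    if (!is.null(f$wmc)) {
      wi <- which(f$wm_mask)
      mw <- length(wi)
      Es <- matrix(0, n, mw); Es[cbind(ck$wm_s[wi], seq_len(mw))] <- 1
      Eg <- matrix(0, n, mw); Eg[cbind(ck$wm_g[wi], seq_len(mw))] <- 1
      dwl <- rbind(tc$beta_p * (f$wmc$s_dist - Es),
                   tc$beta_p * (f$wmc$g_dist - Eg))
      da1 <- crossprod(par$W2, dwl)
      dz1 <- da1 * (f$wmc$z1 > 0)
      dinp <- crossprod(par$W1, dz1)
      gr$W2 <- gr$W2 + tcrossprod(dwl, f$wmc$a1)
      gr$b2 <- gr$b2 + rowSums(dwl)
      gr$W1 <- gr$W1 + tcrossprod(dz1, f$wmc$inp)
      gr$b1 <- gr$b1 + rowSums(dz1)
      dh[, wi] <- dh[, wi, drop = FALSE] + dinp[seq_len(H), , drop = FALSE]
    }
    # GRU backward
    g <- f$g
    Hprev <- f$Hprev
    dz <- dh * (Hprev - g$nn)
    dnn <- dh * (1 - g$z)
    dhp <- dh * g$z
    dan <- dnn * (1 - g$nn^2)
    dr <- dan * g$un
    dun <- dan * g$r
    dar <- dr * g$r * (1 - g$r)
    daz <- dz * g$z * (1 - g$z)
    gr$Wn <- gr$Wn + tcrossprod(dan, ck$X)
    gr$bn <- gr$bn + rowSums(dan)
    gr$Un <- gr$Un + tcrossprod(dun, Hprev)
    gr$cn <- gr$cn + rowSums(dun)
    gr$Wr <- gr$Wr + tcrossprod(dar, ck$X)
    gr$br <- gr$br + rowSums(dar)
    gr$Ur <- gr$Ur + tcrossprod(dar, Hprev)
    gr$Wz <- gr$Wz + tcrossprod(daz, ck$X)
    gr$bz <- gr$bz + rowSums(daz)
    gr$Uz <- gr$Uz + tcrossprod(daz, Hprev)
    dhp <- dhp + crossprod(par$Un, dun) + crossprod(par$Ur, dar) +
      crossprod(par$Uz, daz)
    dH[, idx] <- dhp
  }
  out$grads <- lapply(gr, function(x) x / B)
  out
}

adam_init <- function(par) {
  theta <- flatten_params(par)
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(par, grads, state, tc) {
  theta <- flatten_params(par)
  gvec <- flatten_params(grads)
  if (is.finite(tc$grad_clip)) {
    nrm <- sqrt(sum(gvec^2))
    if (nrm > tc$grad_clip) gvec <- gvec * (tc$grad_clip / nrm)
  }
  state$t <- state$t + 1L
  state$m <- tc$adam_beta1 * state$m + (1 - tc$adam_beta1) * gvec
  state$v <- tc$adam_beta2 * state$v + (1 - tc$adam_beta2) * gvec^2
  mhat <- state$m / (1 - tc$adam_beta1^state$t)
  vhat <- state$v / (1 - tc$adam_beta2^state$t)
  theta <- theta - tc$lr * mhat / (sqrt(vhat) + tc$adam_eps)
  list(par = unflatten_params(theta, par), state = state)
}

#' One policy-gradient update on a batch of fresh episodes
#'
#' @param par agent parameters
#' @param config an \code{agent_config}
#' @param tc a \code{train_config}
#' @param adam Adam state from \code{adam_init} (or NULL for plain SGD-free
#'   gradient inspection)
#' @return list(par, adam, mean_reward, loss_terms)
#' @export
gradient_step <- function(par, config, tc, adam = NULL) {
  B <- tc$episodes_per_batch
  states <- lapply(seq_len(B), function(i) init_episode(config))
  sim <- sim_init(par, config, states)
  res <- simulate_batch(par, config, sim, sim_control(record = "train"))
  bp <- batch_pass(par, res$caches, B, config, tc, grads = TRUE)
  gvec <- flatten_params(bp$grads)
  if (any(!is.finite(gvec)))
    stop("non-finite gradient encountered (", sum(!is.finite(gvec)),
         " entries); aborting")
  if (is.null(adam)) adam <- adam_init(par)
  upd <- adam_step(par, bp$grads, adam, tc)
  list(par = upd$par, adam = upd$state,
       mean_reward = mean(res$sim$reward_total),
       mean_rollout_frac = mean(ifelse(res$sim$iter > 0,
                                       res$sim$n_rollouts / res$sim$iter, NA)),
       loss_terms = bp$terms)
}

#' Train a maze-planning agent
#'
#' On-policy actor-critic training over randomly sampled mazes. Reproducible
#' given \code{set.seed} before the call.
#'
#' @param config an \code{agent_config}
#' @param tc a \code{train_config}
#' @param verbose print progress every \code{log_every} batches
#' @return a \code{maze_agent} with a learning curve (batch index, mean
#'   reward, rollout fraction and loss terms at logged batches)
#' @export
train_agent <- function(config = agent_config(), tc = train_config(),
                        verbose = FALSE) {
  par <- init_params(config)
  adam <- adam_init(par)
  curve <- list(batch = integer(0), mean_reward = numeric(0),
                rollout_fraction = numeric(0),
                actor = numeric(0), value = numeric(0),
                entropy = numeric(0), predictive = numeric(0))
  last_good <- par
  for (b in seq_len(tc$n_batches)) {
    step <- tryCatch(gradient_step(par, config, tc, adam),
                     error = function(e) e)
    if (inherits(step, "error")) {
      warning("training aborted at batch ", b, ": ", conditionMessage(step),
              "; returning last good checkpoint")
      par <- last_good
      break
    }
    last_good <- par
    par <- step$par
    adam <- step$adam
    if (b %% tc$log_every == 0L || b == tc$n_batches || b == 1L) {
      curve$batch <- c(curve$batch, b)
      curve$mean_reward <- c(curve$mean_reward, step$mean_reward)
      curve$rollout_fraction <- c(curve$rollout_fraction,
                                  step$mean_rollout_frac)
      curve$actor <- c(curve$actor, step$loss_terms["actor"])
      curve$value <- c(curve$value, step$loss_terms["value"])
      curve$entropy <- c(curve$entropy, step$loss_terms["entropy"])
      curve$predictive <- c(curve$predictive, step$loss_terms["predictive"])
      if (verbose)
        message(sprintf("batch %d: reward %.2f, rollout frac %.2f", b,
                        step$mean_reward, step$mean_rollout_frac))
    }
  }
  new_maze_agent(par, config, curve,
                 n_episodes_trained = tc$n_batches * tc$episodes_per_batch)
}

#' Loss terms of a single recorded episode
#'
#' Runs one episode on-policy and evaluates the objective terms: the episode
#' return J, the value loss, the negative-entropy term and the world-model
#' cross-entropy.
#'
#' @param agent a \code{maze_agent}
#' @param maze optional maze
#' @param tc a \code{train_config} (weights used for the total)
#' @return named numeric vector (J, value, entropy, predictive, total)
#' @export
episode_losses <- function(agent, maze = NULL, tc = train_config()) {
  config <- agent$config
  sim <- sim_init(agent$params, config, list(init_episode(config, maze)))
  res <- simulate_batch(agent$params, config, sim,
                        sim_control(record = "train"))
  bp <- batch_pass(agent$params, res$caches, 1L, config, tc)
  c(J = res$sim$reward_total[1], bp$terms, total = bp$loss)
}
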
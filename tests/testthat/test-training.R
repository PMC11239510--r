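test_that("reward-to-go matches brute force", {
  expect_equal(compute_returns(c(0, 0, 1, 0, 1)), c(2, 2, 2, 1, 1))
  expect_equal(compute_returns(numeric(5)), numeric(5))
  set.seed(1)
  for (i in 1:20) {
    r <- rbinom(sample(3:30, 1), 1, 0.3)
    brute <- vapply(seq_along(r), function(k) sum(r[k:length(r)]), numeric(1))
    expect_equal(compute_returns(r), brute)
  }
})

test_that("loss terms hit their closed-form anchors", {
  # value loss is zero when V == R; entropy of the uniform 5-way policy is
  # log(1/5); a point-mass world model has zero cross-entropy
  V <- c(2, 1, 1, 0); R <- V
  expect_equal(sum(0.5 * (V - R)^2), 0)
  p <- rep(0.2, 5)
  expect_equal(sum(p * log(p)), log(1 / 5), tolerance = 1e-12)
  s_hat <- numeric(16); s_hat[7] <- 1
  expect_equal(-log(s_hat[7]), 0)
})

test_that("an all-zero agent produces the uniform-policy loss profile", {
  cfg <- agent_config(hidden_units = 5, episode_ms = 4000)
  set.seed(2)
  par <- init_params(cfg)
  for (nm in names(par)) par[[nm]][] <- 0
  ag <- rollnav:::new_maze_agent(par, cfg)
  tc <- train_config()
  l <- episode_losses(ag, tc = tc)
  # entropy term: log(1/5) per action iteration
  states <- l[["entropy"]] / log(1 / 5)
  expect_gt(states, 0)
  expect_equal(states, round(states), tolerance = 1e-9)
})

test_that("BPTT gradients match central finite differences", {
  set.seed(42)
  cfg <- agent_config(hidden_units = 4, episode_ms = 4000)
  par <- init_params(cfg)
  tc <- train_config(episodes_per_batch = 2)
  states <- lapply(1:2, function(i) init_episode(cfg))
  sim <- rollnav:::sim_init(par, cfg, states)
  res <- rollnav:::simulate_batch(par, cfg, sim,
                                  rollnav:::sim_control(record = "train"))
  bp <- rollnav:::batch_pass(par, res$caches, 2, cfg, tc, grads = TRUE)
  g_an <- rollnav:::flatten_params(bp$grads)
  theta0 <- rollnav:::flatten_params(par)
  lossfn <- function(th)
    rollnav:::batch_pass(rollnav:::unflatten_params(th, par), res$caches, 2,
                         cfg, tc, advantages = bp$advantages)$loss
  set.seed(7)
  ii <- sample(length(theta0), 40)
  eps <- 1e-5
  g_fd <- vapply(ii, function(i) {
    tp <- theta0; tp[i] <- tp[i] + eps
    tm <- theta0; tm[i] <- tm[i] - eps
    (lossfn(tp) - lossfn(tm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(g_fd - g_an[ii]) / pmax(abs(g_fd), abs(g_an[ii]), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("teleport iterations contribute no policy or value gradient", {
  set.seed(43)
  cfg <- agent_config(hidden_units = 4, episode_ms = 6000)
  par <- init_params(cfg)
  tc <- train_config(episodes_per_batch = 4)
  # collect until a batch contains at least one teleport iteration
  found <- FALSE
  for (try in 1:20) {
    states <- lapply(1:4, function(i) init_episode(cfg))
    sim <- rollnav:::sim_init(par, cfg, states)
    res <- rollnav:::simulate_batch(par, cfg, sim,
                                    rollnav:::sim_control(record = "train"))
    kinds <- unlist(lapply(res$caches, function(ck) ck$kind))
    if (any(kinds == "teleport")) { found <- TRUE; break }
  }
  skip_if_not(found, "no teleport sampled in 20 tries")
  # zeroing the rewards after masking: the teleport iteration's own policy
  # term must not appear -> compare losses with the teleport's action
  # artificially changed (it is NA, so the loss must not reference it)
  bp <- rollnav:::batch_pass(par, res$caches, 4, cfg, tc)
  caches2 <- res$caches
  for (k in seq_along(caches2)) {
    tele <- which(caches2[[k]]$kind == "teleport")
    caches2[[k]]$action[tele] <- 1L  # any value; must be ignored
  }
  bp2 <- rollnav:::batch_pass(par, caches2, 4, cfg, tc)
  expect_equal(bp2$loss, bp$loss, tolerance = 1e-12)
})

test_that("zero advantage suppresses the actor gradient", {
  set.seed(44)
  cfg <- agent_config(hidden_units = 3, episode_ms = 2000)
  par <- init_params(cfg)
  tc <- train_config(episodes_per_batch = 1, beta_v = 0, beta_e = 0,
                     beta_p = 0)
  states <- list(init_episode(cfg))
  sim <- rollnav:::sim_init(par, cfg, states)
  res <- rollnav:::simulate_batch(par, cfg, sim,
                                  rollnav:::sim_control(record = "train"))
  zero_adv <- lapply(rollnav:::batch_returns(res$caches, 1),
                     function(v) numeric(length(v)))
  bp <- rollnav:::batch_pass(par, res$caches, 1, cfg, tc,
                             advantages = zero_adv, grads = TRUE)
  expect_equal(max(abs(rollnav:::flatten_params(bp$grads))), 0)
})

test_that("training is deterministic given the seed and inert at lr = 0", {
  cfg <- agent_config(hidden_units = 6, episode_ms = 4000)
  tc0 <- train_config(n_batches = 2, episodes_per_batch = 3, lr = 0)
  set.seed(99)
  ag0 <- train_agent(cfg, tc0)
  set.seed(99)
  par_init <- init_params(cfg)
  expect_equal(ag0$params, par_init, tolerance = 1e-12)
  tc1 <- train_config(n_batches = 3, episodes_per_batch = 3, lr = 1e-3)
  set.seed(100)
  ag1 <- train_agent(cfg, tc1)
  set.seed(100)
  ag2 <- train_agent(cfg, tc1)
  expect_equal(ag1$params, ag2$params, tolerance = 1e-12)
})
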
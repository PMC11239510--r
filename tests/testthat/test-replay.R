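test_that("decoder excludes sub-threshold neurons and floors silent maps", {
  ses <- small_session()
  # inject a nearly silent neuron
  ses$spikes <- rbind(ses$spikes, 0L)
  ses$spikes[nrow(ses$spikes), 1:3] <- 1L  # ~0.0x Hz over the session
  dec <- fit_decoder(ses)
  expect_false(dec$include[length(dec$include)])
  expect_true(all(dec$rates >= 0.01))
})

test_that("stationary decoding equals brute-force likelihood maximization", {
  ses <- small_session()
  dec <- fit_decoder(ses)
  set.seed(41)
  bins <- sample(ncol(ses$spikes), 200)
  fast <- decode_stationary(dec, ses, bins)
  # brute force: explicit window sums and likelihood loop
  W <- 0.075
  sp <- ses$spikes[dec$include, , drop = FALSE]
  slow <- vapply(seq_along(bins), function(j) {
    i <- bins[j]
    lo <- max(1, i - 7); hi <- min(ncol(sp), i + 7)
    cnt <- rowSums(sp[, lo:hi, drop = FALSE])
    ll <- vapply(1:25, function(s)
      sum(cnt * log(dec$rates[, s] * W) - dec$rates[, s] * W), numeric(1))
    which.max(ll)
  }, integer(1))
  expect_equal(fast, slow)
})

test_that("zero spikes decode to the state with the smallest total rate", {
  ses <- small_session()
  dec <- fit_decoder(ses)
  ses0 <- ses
  ses0$spikes[] <- 0L
  d <- decode_stationary(dec, ses0, 500L)
  expect_equal(d, which.min(colSums(dec$rates)))
})

test_that("chain extraction implements the replay definition", {
  side <- 5L
  tms <- function(n) seq(0, by = 5, length.out = n)
  # constant sequence: no events
  ev <- rollnav:::extract_chains(rep(13L, 50), tms(50), 13L, side)
  expect_length(ev, 0)
  # a clean adjacent sweep starting at the animal's cell: one event
  seqs <- c(rep(13L, 10), rep(14L, 4), rep(15L, 4))
  ev <- rollnav:::extract_chains(seqs, tms(length(seqs)), 13L, side)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$states, c(13L, 14L, 15L))
  # sweep not starting at the animal location: no event
  ev <- rollnav:::extract_chains(seqs, tms(length(seqs)), 8L, side)
  expect_length(ev, 0)
  # two adjacent states only: no event
  seqs2 <- c(rep(13L, 10), rep(14L, 6))
  expect_length(rollnav:::extract_chains(seqs2, tms(16), 13L, side), 0)
})

test_that("lapses of at most 20 ms are bridged and excluded", {
  side <- 5L
  tms <- function(n) seq(0, by = 5, length.out = n)
  # 13 -> 14 -> [25 for 4 bins = 20 ms] -> 15 continues from the tail
  seqs <- c(rep(13L, 6), rep(14L, 4), rep(25L, 4), rep(15L, 4))
  ev <- rollnav:::extract_chains(seqs, tms(length(seqs)), 13L, side)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$states, c(13L, 14L, 15L))
  expect_length(ev[[1]]$lapses, 1)
  # a 25-ms excursion breaks the chain
  seqs2 <- c(rep(13L, 6), rep(14L, 4), rep(25L, 5), rep(15L, 4))
  ev2 <- rollnav:::extract_chains(seqs2, tms(length(seqs2)), 13L, side)
  expect_length(ev2, 0)
})

test_that("extracted chains always satisfy the event invariants", {
  set.seed(42)
  side <- 5L
  for (i in 1:300) {
    n <- sample(20:120, 1)
    seqs <- sample(1:25, n, replace = TRUE,
                   prob = c(rep(1, 12), 8, rep(1, 12)))  # sticky at 13
    ev <- rollnav:::extract_chains(seqs, seq(0, by = 5, length.out = n),
                                   13L, side)
    for (e in ev) {
      expect_gte(length(e$states), 3)
      expect_equal(e$states[1], 13L)
      prs <- cbind(head(e$states, -1), tail(e$states, -1))
      expect_true(all(rollnav:::cells_adjacent(prs[, 1], prs[, 2], side)))
      for (lp in e$lapses) expect_lte(lp[2] - lp[1] + 5, 20)
    }
  }
})

test_that("wall-crossing fractions and dihedral controls", {
  # replay 13 -> 14 -> 15 -> 20 -> 25 with one wall on (14,15)
  maze <- rollnav:::new_maze(5, FALSE, matrix(c(14, 15), ncol = 2))
  rp <- data.frame(trial = 1, states = I(list(c(13L, 14L, 15L, 20L, 25L))))
  st <- wall_crossing_stat(rp, maze)
  expect_equal(st$true_frac, 0.25)  # 1 of 4 transitions
  expect_equal(st$n_transitions, 4)
  # transforms identical to the original wall set are excluded
  seg <- matrix(c(12, 13, 13, 14), ncol = 2, byrow = TRUE)  # centre segment
  mz2 <- rollnav:::new_maze(5, FALSE, seg)
  st2 <- wall_crossing_stat(rp, mz2)
  # the segment is invariant under 3 of the 7 non-identity transforms
  expect_lt(st2$n_controls, 7)
  expect_gt(st2$n_controls, 0)
  expect_false(is.na(st2$control_frac))
  # a fully symmetric wall set (a plus around the centre) excludes all 7
  plus <- matrix(c(8, 13, 13, 18, 12, 13, 13, 14), ncol = 2, byrow = TRUE)
  st3 <- wall_crossing_stat(rp, rollnav:::new_maze(5, FALSE, plus))
  expect_equal(st3$n_controls, 0)
})

test_that("goal passage: scripted-through-goal replays give fraction 1", {
  wells <- as.integer(outer(2:4, 2:4, function(r, c) (r - 1) * 5 + c))
  rp <- data.frame(trial = 1:2, goal = c(13L, 13L), well = c(7L, 9L),
                   states = I(list(c(7L, 8L, 13L), c(9L, 8L, 13L))))
  gp <- goal_passage_stat(rp, wells)
  expect_equal(gp$true_frac, 1)
  expect_lt(gp$control_frac, 1)
})

test_that("session-label permutation test matches exhaustive enumeration", {
  set.seed(43)
  tv <- c(0.10, 0.20, 0.15, 0.30, 0.22)
  cv <- c(0.18, 0.25, 0.12, 0.35, 0.30)
  stat <- function(t, c) mean(c) - mean(t)
  obs <- stat(tv, cv)
  # exhaustive: all 2^5 label flips
  flips <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  exact <- mean(apply(flips, 1, function(f) {
    t2 <- ifelse(f, cv, tv); c2 <- ifelse(f, tv, cv)
    stat(t2, c2) >= obs
  }))
  pt <- permutation_test(tv, cv, n = 20000)
  expect_lt(abs(pt$p - exact), 0.02)
  # identical values: every permutation reaches the observed statistic
  pt2 <- permutation_test(tv, tv, n = 500)
  expect_equal(pt2$p, 1)
  # wildly separated: only the identity assignment reaches the observed
  # statistic, so p is at the 2^-8 resolution limit
  pt3 <- permutation_test(rep(0, 8), rep(1, 8), n = 5000)
  expect_lt(pt3$p, 0.02)
})

test_that("synthetic end-to-end: recall, wall avoidance and goal enrichment", {
  # a handful of goal-biased sessions; heavier multi-session statistics run
  # in the acceptance suite
  accs <- c(); recalls <- c(); wc_t <- c(); wc_c <- c(); gp_t <- c(); gp_c <- c()
  for (seed in c(51, 52, 53)) {
    ses <- small_session(seed = seed, n_trials = 12)
    dec <- fit_decoder(ses)
    mov <- which(ses$pos$speed_cms > 2)
    set.seed(seed)
    tb <- sample(mov, 800)
    truth <- xy_to_cell(ses$pos$x_cm[tb], ses$pos$y_cm[tb], ses$grid)
    accs <- c(accs, mean(decode_stationary(dec, ses, tb) == truth))
    rp <- detect_replays(dec, ses)
    fh <- which(ses$trials$type == "home")[1]
    scr <- Filter(function(s) s$trial != fh, ses$scripts)
    hit <- vapply(scr, function(s) {
      cand <- which(rp$trial == s$trial & rp$t_start <= s$onset_ms + 100 &
                      rp$t_end >= s$onset_ms)
      any(vapply(cand, function(i)
        length(intersect(rp$states[[i]], s$path)) >=
          min(3, length(s$path)), logical(1)))
    }, logical(1))
    recalls <- c(recalls, mean(hit))
    home <- rp[rp$type == "home", ]
    wc <- wall_crossing_stat(home, ses$maze)
    gp <- goal_passage_stat(home, ses$wells)
    wc_t <- c(wc_t, wc$true_frac); wc_c <- c(wc_c, wc$control_frac)
    gp_t <- c(gp_t, gp$true_frac); gp_c <- c(gp_c, gp$control_frac)
  }
  expect_gt(mean(accs), 0.9)
  expect_gte(mean(recalls), 0.9)
  expect_lt(mean(wc_t), mean(wc_c))   # replays avoid the session's walls
  expect_gt(mean(gp_t), mean(gp_c))   # and are enriched for the goal
})

test_that("follow probability is 1 when behaviour is scripted to follow", {
  ses <- small_session(seed = 54, n_trials = 12)
  dec <- fit_decoder(ses)
  rp <- detect_replays(dec, ses)
  home <- rp[rp$type == "home" & !is.na(rp$a1), ]
  # goal-biased scripts start along the shortest path, which is also the
  # direction the animal then takes: successful replays must be followed
  fp <- follow_probability(home, ses$maze, ses$wells)
  expect_gt(fp$n_successful, 5)
  expect_gt(fp$p_successful, 0.8)
})

test_that("consecutive over-representation recovers scripted structure", {
  # null: random-walk scripts, success unrelated to index -> flat ~1
  sess <- lapply(c(61, 62, 63), function(s)
    small_session(seed = s, n_trials = 14, scripts = "random",
                  replays_per_trial = 4))
  adjs <- NULL
  for (ses in sess) {
    dec <- fit_decoder(ses)
    rp <- detect_replays(dec, ses)
    home <- rp[rp$type == "home", ]
    co <- try(consecutive_overrepresentation(home, ses$maze, ses$wells),
              silent = TRUE)
    if (!inherits(co, "try-error"))
      adjs <- rbind(adjs, co$overrep)
  }
  skip_if(is.null(adjs), "no trial with three detected replays")
  m <- colMeans(adjs)
  expect_lt(max(abs(m - 1)), 0.75)  # flat within broad Monte-Carlo noise
})

test_that("within-trial order permutation detects an index-success gradient", {
  set.seed(71)
  # 30 trials x 3 replays; success probability grows with replay index
  mk <- function(p_by_index) {
    adj <- c(); idx <- c(); trial <- c()
    for (tr in 1:30) {
      s <- rbinom(3, 1, p_by_index)
      adj <- c(adj, s); idx <- c(idx, 1:3); trial <- c(trial, rep(tr, 3))
    }
    list(adj = adj, index = idx, trial = trial)
  }
  grad <- mk(c(0.2, 0.5, 0.8))
  p_grad <- consecutive_permutation_test(grad, index = 3, n = 2000)$p
  expect_lt(p_grad, 0.01)
  flat <- mk(c(0.5, 0.5, 0.5))
  p_flat <- consecutive_permutation_test(flat, index = 3, n = 2000)$p
  expect_gt(p_flat, 0.05)
})
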
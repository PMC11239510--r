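# Hippocampal replay pipeline: Poisson position decoding on a 5x5 grid,
# replay detection during stationary epochs at the previously rewarded well,
# and the four replay statistics with permutation nulls.
#
# Sessions use the same cell convention as the mazes: cells 1..25, row-major,
# row 1 at the top; the nine reward wells are the inner 3x3 cells. The arena
# is bounded (no wrap) and "adjacent" means 4-connectivity.

#' Map arena coordinates to grid cells
#' @param x_cm,y_cm coordinates (origin top-left, y increasing downward)
#' @param grid list(side, cell_cm)
#' @return integer cell indices
#' @export
xy_to_cell <- function(x_cm, y_cm, grid) {
  col <- pmin(pmax(floor(x_cm / grid$cell_cm), 0), grid$side - 1) + 1L
  row <- pmin(pmax(floor(y_cm / grid$cell_cm), 0), grid$side - 1) + 1L
  as.integer((row - 1L) * grid$side + col)
}

#' Fit the Bayesian position decoder
#'
#' Per-neuron mean firing rates per grid state, estimated from movement
#' epochs (speed > 2 cm/s) only. Neurons with a session-wide mean rate below
#' 0.1 Hz are excluded; rate maps are floored at 0.01 Hz so that
#' log-likelihoods stay finite.
#'
#' @param session a replay session (see \code{simulate_session})
#' @param min_rate_hz inclusion threshold (default 0.1)
#' @param floor_hz rate-map floor (default 0.01)
#' @return object of class \code{replay_decoder} with the rate map matrix
#'   (included neurons x states, Hz), the inclusion mask and window settings
#' @export
fit_decoder <- function(session, min_rate_hz = 0.1, floor_hz = 0.01) {
  spikes <- session$spikes
  bin_s <- session$bin_ms / 1000
  moving <- session$pos$speed_cms > 2
  if (!any(moving)) stop("session contains no movement epochs")
  n_states <- session$grid$side^2
  cells <- xy_to_cell(session$pos$x_cm, session$pos$y_cm, session$grid)
  total_s <- ncol(spikes) * bin_s
  sess_rate <- rowSums(spikes) / total_s
  include <- sess_rate >= min_rate_hz
  rates <- matrix(floor_hz, sum(include), n_states)
  sp_inc <- spikes[include, , drop = FALSE]
  for (s in seq_len(n_states)) {
    bins <- which(moving & cells == s)
    if (length(bins))
      rates[, s] <- pmax(rowSums(sp_inc[, bins, drop = FALSE]) /
                           (length(bins) * bin_s), floor_hz)
  }
  structure(list(rates = rates, include = include,
                 window_ms = 75, bin_ms = session$bin_ms,
                 grid = session$grid),
            class = "replay_decoder")
}

#' @export
print.replay_decoder <- function(x, ...) {
  cat(sprintf("replay_decoder: %d neurons, %d states, %d-ms window\n",
              nrow(x$rates), ncol(x$rates), x$window_ms))
  invisible(x)
}

# windowed spike counts: centered 75-ms window (15 bins) at every 5-ms bin
window_counts <- function(spikes, window_bins = 15L) {
  nb <- ncol(spikes)
  half <- window_bins %/% 2L
  cs <- cbind(0, t(apply(spikes, 1, cumsum)))
  lo <- pmax(seq_len(nb) - half, 1L)
  hi <- pmin(seq_len(nb) + half, nb)
  cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
}

#' Decode the maximum-likelihood state at every 5-ms step
#'
#' Poisson log-likelihood over a centred 75-ms window:
#' \code{sum_n c_n log(lambda_n(s) W) - lambda_n(s) W}; ties broken to the
#' lowest state index.
#'
#' @param decoder a \code{replay_decoder}
#' @param session the session (for spikes)
#' @param bins bin indices to decode (default all)
#' @return integer vector of decoded states, one per requested bin
#' @export
decode_stationary <- function(decoder, session, bins = NULL) {
  spikes <- session$spikes[decoder$include, , drop = FALSE]
  wc <- window_counts(spikes, decoder$window_ms / decoder$bin_ms)
  if (is.null(bins)) bins <- seq_len(ncol(spikes))
  W <- decoder$window_ms / 1000
  logl <- crossprod(log(decoder$rates), wc[, bins, drop = FALSE]) -
    colSums(decoder$rates) * W
  max.col(t(logl), ties.method = "first")
}

# lattice adjacency on the bounded grid of the session
cells_adjacent <- function(a, b, side) {
  ra <- (a - 1L) %/% side; ca <- (a - 1L) %% side
  rb <- (b - 1L) %/% side; cb <- (b - 1L) %% side
  abs(ra - rb) + abs(ca - cb) == 1L
}

# Compress a decoded sequence into runs and extract replay chains.
# A chain starts at `origin`, extends over lattice-adjacent transitions, and
# may bridge "lapses": runs of total duration <= 20 ms that jump to a
# non-adjacent state, provided the sequence afterwards continues from the
# chain tail (equal or adjacent state). Events need >= 3 distinct states.
extract_chains <- function(states, times_ms, origin, side, lapse_ms = 20) {
  # run-length compression
  if (!length(states)) return(list())
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  runs <- data.frame(state = r$values,
                     t0 = times_ms[starts], t1 = times_ms[ends],
                     dur = times_ms[ends] - times_ms[starts] + 5)
  events <- list()
  i <- 1L
  nr <- nrow(runs)
  while (i <= nr) {
    if (runs$state[i] != origin) { i <- i + 1L; next }
    chain <- runs$state[i]
    t_start <- runs$t0[i]
    t_end <- runs$t1[i]
    lapses <- list()
    j <- i + 1L
    while (j <= nr) {
      s <- runs$state[j]
      tail_s <- chain[length(chain)]
      if (s == tail_s) {            # cannot occur after rle, defensive
        t_end <- runs$t1[j]; j <- j + 1L
      } else if (cells_adjacent(s, tail_s, side)) {
        chain <- c(chain, s)
        t_end <- runs$t1[j]
        j <- j + 1L
      } else if (runs$dur[j] <= lapse_ms) {
        # tolerated excursion; resumes from the chain tail afterwards
        nxt <- j + 1L
        if (nxt <= nr &&
            (runs$state[nxt] == tail_s ||
             cells_adjacent(runs$state[nxt], tail_s, side))) {
          lapses[[length(lapses) + 1L]] <- c(runs$t0[j], runs$t1[j])
          j <- nxt
        } else break
      } else break
    }
    if (length(chain) >= 3L && length(unique(chain)) >= 3L)
      events[[length(events) + 1L]] <-
        list(states = chain, t_start = t_start, t_end = t_end,
             lapses = lapses)
    i <- j
  }
  events
}

# direction (1 up, 2 down, 3 left, 4 right) of a transition a -> b
transition_dir <- function(a, b, side) {
  ra <- (a - 1L) %/% side; ca <- (a - 1L) %% side
  rb <- (b - 1L) %/% side; cb <- (b - 1L) %% side
  if (rb == ra - 1L && cb == ca) return(1L)
  if (rb == ra + 1L && cb == ca) return(2L)
  if (cb == ca - 1L && rb == ra) return(3L)
  if (cb == ca + 1L && rb == ra) return(4L)
  NA_integer_
}

#' Detect forward replays in a session
#'
#' Decodes the stationary period at the previously rewarded well before each
#' trial and extracts temporally and spatially contiguous sequences of three
#' or more adjacent decoded states originating at the animal's location.
#' Trials lasting 40 s or more are discarded, as is the first home trial
#' (where the home location is still unknown). Brief excursions of at most
#' 20 ms (lapses) are bridged and excluded from the state list.
#'
#' @param decoder a \code{replay_decoder}
#' @param session the session
#' @param max_trial_s trial-duration filter (default 40)
#' @return data.frame of replay events with list-columns \code{states} and
#'   \code{lapses}; one row per event
#' @export
detect_replays <- function(decoder, session, max_trial_s = 40) {
  side <- session$grid$side
  tr <- session$trials
  dur_ok <- (tr$t_end - tr$t_start) / 1000 < max_trial_s
  first_home <- which(tr$type == "home")[1]
  keep <- which(dur_ok & seq_len(nrow(tr)) != first_home)
  # decode every stationary bin of the kept trials in one pass
  trial_bins <- lapply(keep, function(ti) {
    which(session$pos$time_ms >= tr$t_arrive[ti] &
            session$pos$time_ms < tr$t_depart[ti] &
            session$pos$speed_cms < 2)
  })
  all_bins <- unlist(trial_bins)
  if (!length(all_bins)) return(NULL)
  dec_all <- decode_stationary(decoder, session, all_bins)
  dec_map <- split(dec_all, rep(seq_along(keep),
                                vapply(trial_bins, length, integer(1))))
  out <- list()
  for (j in seq_along(keep)) {
    ti <- keep[j]
    t0 <- tr$t_arrive[ti]; t1 <- tr$t_depart[ti]
    bins <- trial_bins[[j]]
    if (length(bins) < 3) next
    dec <- dec_map[[j]]
    evs <- extract_chains(dec, session$pos$time_ms[bins], tr$well[ti], side)
    for (e in evs) {
      a1 <- transition_dir(e$states[1], e$states[2], side)
      out[[length(out) + 1L]] <- data.frame(
        trial = tr$trial[ti], type = tr$type[ti], well = tr$well[ti],
        goal = tr$goal_well[ti], t_start = e$t_start, t_end = e$t_end,
        t_since_arrive = e$t_start - t0, t_to_depart = t1 - e$t_end,
        n_states = length(e$states), a1 = a1,
        next_action = if (!is.null(tr$first_move_dir)) tr$first_move_dir[ti]
                      else NA_integer_,
        states = I(list(e$states)), lapses = I(list(e$lapses)))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# ---- replay statistics ----

# the 8 dihedral transforms as cell permutations on a side x side grid
dihedral_perms <- function(side) {
  n <- side^2
  rc <- cbind((seq_len(n) - 1L) %/% side, (seq_len(n) - 1L) %% side)
  maps <- list(
    function(r, c) cbind(r, c),
    function(r, c) cbind(c, side - 1L - r),            # rot90
    function(r, c) cbind(side - 1L - r, side - 1L - c),# rot180
    function(r, c) cbind(side - 1L - c, r),            # rot270
    function(r, c) cbind(r, side - 1L - c),            # horizontal flip
    function(r, c) cbind(side - 1L - r, c),            # vertical flip
    function(r, c) cbind(c, r),                        # main diagonal
    function(r, c) cbind(side - 1L - c, side - 1L - r))# anti-diagonal
  lapply(maps, function(f) {
    m <- f(rc[, 1], rc[, 2])
    as.integer(m[, 1] * side + m[, 2] + 1L)
  })
}

# transform a wall set (2-col matrix of cell pairs) by a cell permutation
transform_walls <- function(walls, perm) {
  w <- cbind(perm[walls[, 1]], perm[walls[, 2]])
  t(apply(w, 1, sort))
}

wall_key <- function(walls) {
  w <- t(apply(walls, 1, sort))
  paste(sort(paste(w[, 1], w[, 2])), collapse = ";")
}

# does the transition a -> b cross a wall under the wall set?
crosses_wall <- function(a, b, walls) {
  if (!nrow(walls)) return(logical(length(a)))
  key <- paste(pmin(a, b), pmax(a, b))
  wk <- paste(walls[, 1], walls[, 2])
  key %in% wk
}

replay_transitions <- function(replays) {
  do.call(rbind, lapply(replays$states, function(s)
    cbind(head(s, -1), tail(s, -1))))
}

#' Wall avoidance of replays
#'
#' Fraction of replay state transitions that pass through a wall, against a
#' control computed for the nonidentical rotations and reflections of the
#' session's wall set (at most 7 transforms).
#'
#' @param replays data.frame from \code{detect_replays}, typically filtered
#'   to replays preceding home trials
#' @param maze the session's wall configuration (a \code{maze})
#' @return list(true_frac, control_frac, n_transitions)
#' @export
wall_crossing_stat <- function(replays, maze) {
  trans <- replay_transitions(replays)
  perms <- dihedral_perms(maze$side)[-1]
  orig_key <- wall_key(maze$walls)
  ctrl <- c()
  for (p in perms) {
    tw <- transform_walls(maze$walls, p)
    if (wall_key(tw) == orig_key) next  # identical under this transform
    ctrl <- c(ctrl, mean(crosses_wall(trans[, 1], trans[, 2], tw)))
  }
  list(true_frac = mean(crosses_wall(trans[, 1], trans[, 2], maze$walls)),
       control_frac = if (length(ctrl)) mean(ctrl) else NA_real_,
       n_controls = length(ctrl),
       n_transitions = nrow(trans))
}

#' Goal passage of replays
#'
#' Fraction of replays (preceding home trials) that pass through the goal
#' well, against the average fraction passing through each of the wells that
#' are neither the goal nor the animal's current location.
#'
#' @param replays data.frame from \code{detect_replays} (home trials)
#' @param wells integer vector of candidate well cells
#' @return list(true_frac, control_frac, n_replays)
#' @export
goal_passage_stat <- function(replays, wells) {
  passes <- function(states, loc) loc %in% states
  true_hits <- mapply(function(s, g) passes(s, g),
                      replays$states, replays$goal)
  ctrl_means <- mapply(function(s, g, w0) {
    ctrl_locs <- setdiff(wells, c(g, w0))
    mean(vapply(ctrl_locs, function(cc) passes(s, cc), logical(1)))
  }, replays$states, replays$goal, replays$well)
  list(true_frac = mean(true_hits), control_frac = mean(ctrl_means),
       n_replays = nrow(replays))
}

# successful replay: reaches `loc` without passing through a wall
replay_success <- function(replays, walls, loc = NULL) {
  mapply(function(s, g) {
    target <- if (is.null(loc)) g else loc
    wallhit <- any(crosses_wall(head(s, -1), tail(s, -1), walls))
    (target %in% s) && !wallhit
  }, replays$states, replays$goal)
}

#' Probability of following a replay, by replay success
#'
#' Computes \code{P(a1 = a1_hat)}: the probability that the animal's first
#' physical action after the stationary period matches the first replayed
#' action. Successful replays reach the goal without crossing a wall.
#' Unsuccessful replays are those successful toward one of the control wells
#' (neither the goal nor the current location) but not toward the true goal;
#' with \code{disjoint = FALSE} the alternative control including
#' goal-successful replays is used.
#'
#' @param replays data.frame from \code{detect_replays} with a column
#'   \code{next_action} (first physical action after the replay's
#'   stationary period)
#' @param maze session wall configuration
#' @param wells candidate well cells
#' @param disjoint discard goal-successful replays from the control set
#' @return list(p_successful, p_unsuccessful, n_successful, n_unsuccessful)
#' @export
follow_probability <- function(replays, maze, wells, disjoint = TRUE) {
  if (is.null(replays$next_action))
    stop("replays need a next_action column")
  ok <- !is.na(replays$a1) & !is.na(replays$next_action)
  replays <- replays[ok, , drop = FALSE]
  succ <- replay_success(replays, maze$walls)
  p_succ <- if (any(succ))
    mean(replays$a1[succ] == replays$next_action[succ]) else NA_real_
  # control: success toward each non-goal, non-current well
  ctrl_ps <- c()
  for (w in wells) {
    rows <- which(replays$goal != w & replays$well != w &
                    (!disjoint | !succ))
    if (!length(rows)) next
    sw <- replay_success(replays[rows, , drop = FALSE], maze$walls, loc = w)
    if (any(sw))
      ctrl_ps <- c(ctrl_ps, mean(replays$a1[rows][sw] ==
                                   replays$next_action[rows][sw]))
  }
  list(p_successful = p_succ,
       p_unsuccessful = if (length(ctrl_ps)) mean(ctrl_ps) else NA_real_,
       n_successful = sum(succ), n_control_locations = length(ctrl_ps))
}

#' Over-representation of successful replays by replay index
#'
#' For trials with at least \code{min_replays} replays, regresses the
#' success indicator on the time since arrival and time until departure
#' (both capped at 15 s), then computes per-index mean adjusted success
#' divided by the analogous control-location baseline (averaged across
#' replays and control wells, with its own time correction).
#'
#' @param replays data.frame from \code{detect_replays}; needs columns
#'   \code{t_arrive_rel} and \code{t_depart_rel} (times relative to the
#'   stationary period, ms) or a session to derive them from
#' @param maze session wall configuration
#' @param wells candidate wells
#' @param min_replays minimum replays per trial (default 3)
#' @param max_index highest replay index reported (default 3)
#' @param cap_s cap on the time predictors (default 15)
#' @return list(overrep (length max_index), n_trials, true_adj, ctrl_base)
#' @export
consecutive_overrepresentation <- function(replays, maze, wells,
                                           min_replays = 3L, max_index = 3L,
                                           cap_s = 15) {
  counts <- table(replays$trial)
  keep_trials <- as.integer(names(counts)[counts >= min_replays])
  if (!length(keep_trials))
    stop("no trial has at least ", min_replays, " replays")
  rp <- replays[replays$trial %in% keep_trials, , drop = FALSE]
  rp <- rp[order(rp$trial, rp$t_start), , drop = FALSE]
  rp$index <- unsplit(lapply(split(rp$trial, rp$trial), seq_along), rp$trial)
  succ <- as.numeric(replay_success(rp, maze$walls))
  t_arr <- pmin(rp$t_since_arrive / 1000, cap_s)
  t_dep <- pmin(rp$t_to_depart / 1000, cap_s)
  fit <- lm(succ ~ t_arr + t_dep)
  adj <- succ - fitted(fit) + mean(succ)
  # control: average success toward control wells, with its own correction
  ctrl_raw <- mapply(function(i) {
    locs <- setdiff(wells, c(rp$goal[i], rp$well[i]))
    mean(vapply(locs, function(w)
      replay_success(rp[i, , drop = FALSE], maze$walls, loc = w),
      logical(1)))
  }, seq_len(nrow(rp)))
  cfit <- lm(ctrl_raw ~ t_arr + t_dep)
  ctrl_adj <- ctrl_raw - fitted(cfit) + mean(ctrl_raw)
  ctrl_base <- mean(ctrl_adj)
  overrep <- vapply(seq_len(max_index), function(j)
    mean(adj[rp$index == j]) / ctrl_base, numeric(1))
  list(overrep = overrep, n_trials = length(keep_trials),
       adj = adj, index = rp$index, trial = rp$trial,
       ctrl_base = ctrl_base)
}

#' Permutation test for the increase of over-representation with index
#'
#' Independently permutes the order of the replays within each trial (after
#' the time correction) and recomputes the gain in adjusted success at a
#' given replay index relative to index 1.
#'
#' @param co output of \code{consecutive_overrepresentation}
#' @param index replay index compared against index 1 (default 3)
#' @param n permutations
#' @return list(p, observed, n)
#' @export
consecutive_permutation_test <- function(co, index = 3L, n = 10000L) {
  gain <- function(idx) mean(co$adj[idx == index]) - mean(co$adj[idx == 1L])
  obs <- gain(co$index)
  cnt <- 0L
  for (i in seq_len(n)) {
    pidx <- unsplit(lapply(split(co$index, co$trial), sample), co$trial)
    if (gain(pidx) >= obs) cnt <- cnt + 1L
  }
  list(p = cnt / n, observed = obs, n = n)
}

#' Session-label permutation test
#'
#' Randomly swaps the 'true' and 'control' values independently for each
#' session and reports the fraction of permutations in which the permuted
#' statistic is at least as large as the observed one.
#'
#' @param true_vals,control_vals per-session values (equal length)
#' @param n number of permutations (default 10,000)
#' @param statistic function(true, control) -> scalar; default
#'   \code{mean(control) - mean(true)} (wall-avoidance direction); pass
#'   \code{function(t, c) mean(t) - mean(c)} for enrichment-style tests
#' @return list(p, observed, n); p of 0 means no permutation reached the
#'   observed value (report as p < 1/n)
#' @export
permutation_test <- function(true_vals, control_vals, n = 10000L,
                             statistic = function(t, c) mean(c) - mean(t)) {
  stopifnot(length(true_vals) == length(control_vals), n >= 1)
  obs <- statistic(true_vals, control_vals)
  ns <- length(true_vals)
  cnt <- 0L
  for (i in seq_len(n)) {
    flip <- runif(ns) < 0.5
    t2 <- ifelse(flip, control_vals, true_vals)
    c2 <- ifelse(flip, true_vals, control_vals)
    if (statistic(t2, c2) >= obs) cnt <- cnt + 1L
  }
  list(p = cnt / n, observed = obs, n = n)
}
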
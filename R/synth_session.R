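# Synthetic rodent-like sessions: place-cell Poisson spiking on a bounded
# 5x5 arena with walls, home/away trial alternation, stationary periods at
# the previously rewarded well containing scripted compressed replay
# trajectories. Every generator is a pure function of the RNG state and its
# configuration, and ground truth (scripts, true positions) is kept in the
# returned object so end-to-end recovery is measurable.

#' Random wall set for the 5x5 arena
#'
#' Samples \code{n_walls} edges of the bounded lattice uniformly at random,
#' rejecting configurations that disconnect the arena.
#'
#' @param side grid side (default 5)
#' @param n_walls number of walls (default 6, as in the rodent task)
#' @return a \code{maze}
#' @export
gen_arena_walls <- function(side = 5L, n_walls = 6L) {
  lat <- lattice(side, FALSE)
  repeat {
    ids <- sample(lat$present, n_walls)
    m <- maze_from_wall_ids(side, FALSE, ids)
    if (maze_connected(m)) return(m)
  }
}

#' Gaussian place-cell population
#'
#' Field centres tile the arena on a jittered lattice so that every location
#' has informative coverage (uniformly random centres leave appreciable
#' gaps at realistic population sizes).
#'
#' @param n_cells number of cells
#' @param arena_cm arena edge length (cm)
#' @param sigma_cm field width
#' @param peak_hz peak in-field rate
#' @param baseline_hz baseline rate
#' @param jitter_cm s.d. of centre jitter around the lattice
#' @return data.frame of per-cell field parameters
#' @export
gen_place_cells <- function(n_cells = 300L, arena_cm = 100, sigma_cm = 6,
                            peak_hz = 30, baseline_hz = 0.05,
                            jitter_cm = 4) {
  stopifnot(peak_hz >= 0, baseline_hz >= 0, sigma_cm > 0)
  k <- ceiling(sqrt(n_cells))
  centers <- (seq_len(k) - 0.5) / k * arena_cm
  gx <- rep(centers, k)[seq_len(n_cells)]
  gy <- rep(centers, each = k)[seq_len(n_cells)]
  clamp <- function(v) pmin(pmax(v, 0), arena_cm)
  data.frame(x_cm = clamp(gx + rnorm(n_cells, 0, jitter_cm)),
             y_cm = clamp(gy + rnorm(n_cells, 0, jitter_cm)),
             sigma_cm = sigma_cm, peak_hz = peak_hz,
             baseline_hz = baseline_hz)
}

# rates (n_cells x n_points) of the population at arena positions
place_cell_rates <- function(cells, x, y) {
  dx2 <- outer(cells$x_cm, x, "-")^2 + outer(cells$y_cm, y, "-")^2
  cells$baseline_hz + cells$peak_hz * exp(-dx2 / (2 * cells$sigma_cm^2))
}

cell_center_xy <- function(cell, grid) {
  row <- (cell - 1L) %/% grid$side
  col <- (cell - 1L) %% grid$side
  cbind((col + 0.5) * grid$cell_cm, (row + 0.5) * grid$cell_cm)
}

# shortest path (sequence of cells) between two cells of a maze
shortest_path_cells <- function(maze, from, to) {
  d <- bfs_distances(maze, to)
  path <- from
  cur <- from
  while (cur != to) {
    opts <- maze$trans[cur, maze$open[cur, ]]
    cur <- opts[which.min(d[opts])]
    path <- c(path, cur)
  }
  path
}

# wall-respecting (or not) random walk of a given number of transitions
random_walk_cells <- function(maze, from, n_steps, respect_walls = TRUE) {
  lat <- lattice(maze$side, FALSE)
  path <- from
  cur <- from
  for (i in seq_len(n_steps)) {
    opts <- if (respect_walls) maze$trans[cur, maze$open[cur, ]]
            else lat$nbr[cur, !is.na(lat$nbr[cur, ])]
    opts <- setdiff(opts, path[max(1, length(path) - 1)])  # avoid backtrack
    if (!length(opts)) opts <- if (respect_walls)
      maze$trans[cur, maze$open[cur, ]] else lat$nbr[cur, !is.na(lat$nbr[cur, ])]
    cur <- if (length(opts) == 1L) opts else sample(opts, 1L)
    path <- c(path, cur)
  }
  path
}

#' Simulate a replay session
#'
#' Home/away trial alternation on a walled 5x5 arena: the animal rests
#' 5-15 s at the previously rewarded well (where scripted replays are
#' embedded) and then runs a wall-respecting shortest path to the next
#' rewarded well. Spikes are Poisson draws from Gaussian place-cell rates
#' evaluated at the true position; during a scripted replay the rates follow
#' the script path at the compression speed, scaled by \code{replay_gain}
#' (replay firing is strongly elevated, mimicking sharp-wave-ripple
#' activity).
#'
#' @param maze arena walls (a bounded \code{maze}); generated when NULL
#' @param n_trials number of trials (alternating home/away, starting home)
#' @param place_cells population from \code{gen_place_cells}
#' @param scripts \code{"goal_biased"} (shortest path to the upcoming goal
#'   before home trials, random walks otherwise), \code{"mixed"} (before a
#'   home trial, a goal path or a random walk with equal probability -- so
#'   both successful and unsuccessful replays occur), \code{"random"}
#'   (wall-respecting random walks), \code{"wall_blind"} (random walks that
#'   ignore walls) or \code{"none"}
#' @param replays_per_trial expected scripted replays per stationary period
#'   (draws are uniform on \code{replays_per_trial + (-1:1)}, floored at 0)
#' @param compression_ms_per_state replay compression (default 40,
#'   i.e. 5 m/s over 20-cm states)
#' @param replay_gain rate multiplier during scripted replays (default 5)
#' @param speed_cms running speed between wells (default 40)
#' @param stationary_s_range min/max stationary duration (default 5-15 s)
#' @param bin_ms spike bin width (default 5)
#' @return a list of class \code{replay_session}: spikes (neurons x bins),
#'   pos, trials, maze, grid, wells, place_cells, scripts (ground truth)
#' @export
simulate_session <- function(maze = NULL, n_trials = 30L, place_cells = NULL,
                             scripts = "goal_biased", replays_per_trial = 3L,
                             compression_ms_per_state = 40,
                             replay_gain = 5, speed_cms = 40,
                             stationary_s_range = c(5, 15), bin_ms = 5) {
  side <- 5L
  grid <- list(side = side, cell_cm = 20)
  if (is.null(maze)) maze <- gen_arena_walls(side)
  stopifnot(!maze$periodic, maze$side == side)
  if (is.null(place_cells)) place_cells <- gen_place_cells()
  wells <- as.integer(outer(2:4, 2:4, function(r, c) (r - 1L) * side + c))
  home <- sample(wells, 1L)
  # ---- trial plan and position trace ----
  ms_per_cell <- grid$cell_cm / speed_cms * 1000
  cur <- sample(setdiff(wells, home), 1L)  # animal starts at a non-home well
  t <- 0
  pos_t <- c(); pos_x <- c(); pos_y <- c(); pos_v <- c()
  trials <- NULL
  script_list <- list()
  add_stationary <- function(cell, dur_ms) {
    nb <- floor(dur_ms / bin_ms)
    xy <- cell_center_xy(cell, grid)
    list(t = t + bin_ms * (seq_len(nb) - 1), x = rep(xy[1], nb),
         y = rep(xy[2], nb), v = rep(0, nb), dur = nb * bin_ms)
  }
  # ---- initial roaming epoch: the animal explores the whole arena before
  # the task, giving the decoder movement coverage of every state ----
  nb_per_cell <- max(1L, floor(ms_per_cell / bin_ms))
  roam <- random_walk_cells(maze, cur, 1L)
  visited <- rep(FALSE, side^2); visited[cur] <- TRUE
  while (!all(visited) || length(roam) < 150L) {
    nxt <- random_walk_cells(maze, roam[length(roam)], 1L)[2]
    roam <- c(roam, nxt); visited[nxt] <- TRUE
    if (length(roam) > 2000L) break
  }
  xy <- cell_center_xy(roam, grid)
  fr <- seq(0, 1, length.out = nb_per_cell + 1L)[-(nb_per_cell + 1L)]
  for (i in seq_len(length(roam) - 1L)) {
    pos_x <- c(pos_x, xy[i, 1] + fr * (xy[i + 1, 1] - xy[i, 1]))
    pos_y <- c(pos_y, xy[i, 2] + fr * (xy[i + 1, 2] - xy[i, 2]))
  }
  nbr_bins <- length(pos_x)
  pos_t <- bin_ms * (seq_len(nbr_bins) - 1)
  pos_v <- rep(speed_cms, nbr_bins)
  t <- nbr_bins * bin_ms
  cur <- roam[length(roam)]
  if (!(cur %in% wells)) {
    path0 <- shortest_path_cells(maze, cur, sample(setdiff(wells, home), 1L))
    xy <- cell_center_xy(path0, grid)
    for (i in seq_len(length(path0) - 1L)) {
      pos_x <- c(pos_x, xy[i, 1] + fr * (xy[i + 1, 1] - xy[i, 1]))
      pos_y <- c(pos_y, xy[i, 2] + fr * (xy[i + 1, 2] - xy[i, 2]))
    }
    add <- length(pos_x) - nbr_bins
    pos_t <- c(pos_t, t + bin_ms * (seq_len(add) - 1))
    pos_v <- c(pos_v, rep(speed_cms, add))
    t <- t + add * bin_ms
    cur <- path0[length(path0)]
  }
  for (ti in seq_len(n_trials)) {
    type <- if (ti %% 2L == 1L) "home" else "away"
    goal <- if (type == "home") home else sample(setdiff(wells, c(home, cur)), 1L)
    stat_dur <- runif(1, stationary_s_range[1], stationary_s_range[2]) * 1000
    st <- add_stationary(cur, stat_dur)
    pos_t <- c(pos_t, st$t); pos_x <- c(pos_x, st$x)
    pos_y <- c(pos_y, st$y); pos_v <- c(pos_v, st$v)
    t_arrive <- t
    t_depart <- t + st$dur
    # scripted replays inside the stationary period
    n_rep <- if (identical(scripts, "none")) 0L else
      max(0L, replays_per_trial + sample(-1:1, 1L))
    if (n_rep > 0L) {
      slots <- seq(500, st$dur - 1500, length.out = max(n_rep, 2))[seq_len(n_rep)]
      for (on in slots) {
        path <- switch(scripts,
          mixed = if (type == "home" && runif(1) < 0.5) {
            p <- shortest_path_cells(maze, cur, goal)
            while (length(p) < 3L) {
              tl <- p[length(p)]
              opts <- setdiff(maze$trans[tl, maze$open[tl, ]],
                              p[length(p) - 1L])
              if (!length(opts)) opts <- maze$trans[tl, maze$open[tl, ]]
              p <- c(p, if (length(opts) == 1L) opts else sample(opts, 1L))
            }
            p
          } else random_walk_cells(maze, cur, sample(4:7, 1L)),
          goal_biased = if (type == "home") {
            p <- shortest_path_cells(maze, cur, goal)
            # replays may overshoot the goal; also guarantees >= 3 states
            while (length(p) < 3L) {
              tl <- p[length(p)]
              opts <- setdiff(maze$trans[tl, maze$open[tl, ]],
                              p[length(p) - 1L])
              if (!length(opts)) opts <- maze$trans[tl, maze$open[tl, ]]
              p <- c(p, if (length(opts) == 1L) opts else sample(opts, 1L))
            }
            p
          } else random_walk_cells(maze, cur, sample(4:7, 1L)),
          random = random_walk_cells(maze, cur, sample(4:7, 1L)),
          wall_blind = random_walk_cells(maze, cur, sample(4:7, 1L),
                                         respect_walls = FALSE))
        script_list[[length(script_list) + 1L]] <-
          list(trial = ti, onset_ms = t_arrive + on, path = path,
               compression_ms = compression_ms_per_state)
      }
    }
    t <- t_depart
    # movement to the goal
    path <- shortest_path_cells(maze, cur, goal)
    first_dir <- if (length(path) > 1)
      transition_dir(path[1], path[2], side) else NA_integer_
    nb_per_cell <- max(1L, floor(ms_per_cell / bin_ms))
    xy <- cell_center_xy(path, grid)
    if (length(path) > 1) {
      fr <- seq(0, 1, length.out = nb_per_cell + 1L)[-(nb_per_cell + 1L)]
      mx <- c(); my <- c()
      for (i in seq_len(length(path) - 1L)) {
        mx <- c(mx, xy[i, 1] + fr * (xy[i + 1, 1] - xy[i, 1]))
        my <- c(my, xy[i, 2] + fr * (xy[i + 1, 2] - xy[i, 2]))
      }
      nbm <- length(mx)
      pos_t <- c(pos_t, t + bin_ms * (seq_len(nbm) - 1))
      pos_x <- c(pos_x, mx); pos_y <- c(pos_y, my)
      pos_v <- c(pos_v, rep(speed_cms, nbm))
      t <- t + nbm * bin_ms
    }
    trials <- rbind(trials, data.frame(
      trial = ti, type = type, well = cur, goal_well = goal,
      t_start = t_arrive, t_end = t, t_arrive = t_arrive,
      t_depart = t_depart, first_move_dir = first_dir))
    cur <- goal
  }
  # ---- spike generation ----
  n_bins <- length(pos_t)
  rates <- place_cell_rates(place_cells, pos_x, pos_y)
  for (sc in script_list) {
    n_states <- length(sc$path)
    bins_per_state <- max(1L, round(sc$compression_ms / bin_ms))
    b0 <- which.min(abs(pos_t - sc$onset_ms))
    for (j in seq_len(n_states)) {
      bb <- b0 + (j - 1L) * bins_per_state + seq_len(bins_per_state) - 1L
      bb <- bb[bb <= n_bins]
      if (!length(bb)) break
      xy <- cell_center_xy(sc$path[j], grid)
      r <- place_cell_rates(place_cells, xy[1], xy[2]) * replay_gain
      rates[, bb] <- matrix(r, nrow = nrow(rates), ncol = length(bb))
    }
  }
  spikes <- matrix(rpois(length(rates), rates * bin_ms / 1000),
                   nrow = nrow(rates))
  structure(list(spikes = spikes, bin_ms = bin_ms,
                 pos = data.frame(time_ms = pos_t, x_cm = pos_x,
                                  y_cm = pos_y, speed_cms = pos_v),
                 trials = trials, maze = maze, grid = grid, wells = wells,
                 home = home, place_cells = place_cells,
                 scripts = script_list),
            class = "replay_session")
}

#' @export
print.replay_session <- function(x, ...) {
  cat(sprintf(
    "replay_session: %d neurons, %.1f min, %d trials, %d scripted replays\n",
    nrow(x$spikes), ncol(x$spikes) * x$bin_ms / 60000, nrow(x$trials),
    length(x$scripts)))
  invisible(x)
}
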
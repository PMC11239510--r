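# Shared fixtures, built once per test run and memoised in this environment.

.test_cache <- new.env(parent = emptyenv())

# small trained agent used by the analysis and acceptance tests
trained_fixture <- function() {
  if (is.null(.test_cache$agent))
    .test_cache$agent <- gen_agent_fixture(seed = 2024L, hidden_units = 48L,
                                           n_batches = 700L, lr = 2e-3)
  .test_cache$agent
}

# an untrained agent of a given size, for structural tests
fresh_agent <- function(hidden_units = 8L, seed = 1L) {
  set.seed(seed)
  cfg <- agent_config(hidden_units = hidden_units)
  rollnav:::new_maze_agent(init_params(cfg), cfg)
}

# independent BFS oracle (deliberately separate from the package's
# implementation: plain queue over an explicit edge list)
oracle_bfs <- function(maze, from, to) {
  n <- maze$side^2
  edges <- list()
  for (cell in seq_len(n)) for (a in 1:4) {
    if (maze$open[cell, a]) {
      nb <- neighbor_cell(cell, a, maze$side, maze$periodic)
      edges[[length(edges) + 1L]] <- c(cell, nb)
    }
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier) && is.na(dist[to])) {
    nxt <- integer(0)
    for (e in edges) {
      if (!is.na(dist[e[1]]) && is.na(dist[e[2]])) nxt <- c(nxt, e[2])
    }
    nxt <- unique(nxt)
    if (!length(nxt)) break
    dist[nxt] <- max(dist, na.rm = TRUE) + 1L
    frontier <- nxt
  }
  dist[to]
}

# tiny deterministic session for replay unit tests
small_session <- function(seed = 11, n_trials = 10, ...) {
  key <- paste0("ses_", seed, "_", n_trials, "_",
                paste(names(list(...)), unlist(list(...)), collapse = "_"))
  if (is.null(.test_cache[[key]])) {
    set.seed(seed)
    .test_cache[[key]] <- simulate_session(n_trials = n_trials, ...)
  }
  .test_cache[[key]]
}
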
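#' @importFrom stats rnorm runif setNames quantile sd cor pnorm lm coef predict rpois rbinom
#' @importFrom utils head tail
NULL

# Cell convention: cells are 1..side^2, row-major, row 1 at the top.
# Actions: 1 = up (row - 1), 2 = down, 3 = left, 4 = right, 5 = rollout.
# External JSON files use 0-based cell indices; conversion happens at IO.

ACTIONS <- c("up", "down", "left", "right", "rollout")

#' Convert between cell index and (row, col)
#' @param cell integer cell index (1-based, row-major, row 1 at top)
#' @param side cells per edge
#' @return integer vector c(row, col)
#' @keywords internal
cell_rc <- function(cell, side) {
  c((cell - 1L) %/% side + 1L, (cell - 1L) %% side + 1L)
}

rc_cell <- function(row, col, side) {
  as.integer((row - 1L) * side + col)
}

#' Neighbouring cell under the maze boundary convention
#'
#' @param cell cell index
#' @param action 1 = up, 2 = down, 3 = left, 4 = right
#' @param side cells per edge
#' @param periodic wrap across edges?
#' @return neighbouring cell index, or NA if the move leaves a bounded arena
#' @export
neighbor_cell <- function(cell, action, side, periodic) {
  rc <- cell_rc(cell, side)
  r <- rc[1]; c <- rc[2]
  if (action == 1L) r <- r - 1L
  else if (action == 2L) r <- r + 1L
  else if (action == 3L) c <- c - 1L
  else if (action == 4L) c <- c + 1L
  else stop("invalid physical action: ", action)
  if (periodic) {
    r <- (r - 1L) %% side + 1L
    c <- (c - 1L) %% side + 1L
  } else if (r < 1L || r > side || c < 1L || c > side) {
    return(NA_integer_)
  }
  rc_cell(r, c, side)
}

# Canonical edge enumeration: for each cell c (1..n), edge 2c-1 joins c to its
# right neighbour and edge 2c joins c to its down neighbour (wrapping iff
# periodic). Non-periodic mazes simply lack the wrap edges. Lattice geometry
# is cached per (side, periodic).
.lattice_cache <- new.env(parent = emptyenv())

lattice <- function(side, periodic) {
  key <- paste0(side, if (periodic) "p" else "b")
  if (!is.null(.lattice_cache[[key]])) return(.lattice_cache[[key]])
  n <- side * side
  nbr <- matrix(NA_integer_, n, 4)
  for (cell in seq_len(n)) for (a in 1:4)
    nbr[cell, a] <- neighbor_cell(cell, a, side, periodic)
  # edge id joining (cell, action); canonical ids live on the periodic lattice
  pnbr <- if (periodic) nbr else {
    pn <- matrix(NA_integer_, n, 4)
    for (cell in seq_len(n)) for (a in 1:4)
      pn[cell, a] <- neighbor_cell(cell, a, side, TRUE)
    pn
  }
  eid <- matrix(NA_integer_, n, 4)
  for (cell in seq_len(n)) {
    eid[cell, 4] <- 2L * cell - 1L          # right
    eid[cell, 2] <- 2L * cell               # down
    eid[pnbr[cell, 4], 3] <- 2L * cell - 1L # left, from the neighbour
    eid[pnbr[cell, 2], 1] <- 2L * cell      # up
  }
  if (!periodic) eid[is.na(nbr)] <- NA_integer_
  # present edge ids and their endpoint pairs (sorted)
  pres <- sort(unique(as.integer(eid[!is.na(eid) & !is.na(nbr)])))
  ends <- matrix(0L, 2L * n, 2)
  for (cell in seq_len(n)) {
    ends[2L * cell - 1L, ] <- sort(c(cell, pnbr[cell, 4]))
    ends[2L * cell, ] <- sort(c(cell, pnbr[cell, 2]))
  }
  nbrl <- lapply(seq_len(n), function(cell) {
    ok <- !is.na(nbr[cell, ]) & !is.na(eid[cell, ])
    list(nb = nbr[cell, ok], id = eid[cell, ok])
  })
  out <- list(n = n, nbr = nbr, eid = eid, present = pres, ends = ends,
              nbrl = nbrl,
              wrap_missing = setdiff(seq_len(2L * n), pres))
  .lattice_cache[[key]] <- out
  out
}

new_maze <- function(side, periodic, wall_pairs) {
  lat <- lattice(side, periodic)
  wall_pairs <- matrix(as.integer(wall_pairs), ncol = 2)
  if (nrow(wall_pairs)) {
    wall_pairs <- t(apply(wall_pairs, 1, sort))
  }
  # map endpoint pairs to edge ids
  ids <- integer(nrow(wall_pairs))
  if (nrow(wall_pairs)) {
    keyz <- paste(lat$ends[lat$present, 1], lat$ends[lat$present, 2])
    ids <- lat$present[match(paste(wall_pairs[, 1], wall_pairs[, 2]), keyz)]
    if (any(is.na(ids))) stop("wall joins non-adjacent cells")
  }
  maze_from_wall_ids(side, periodic, ids)
}

maze_from_wall_ids <- function(side, periodic, wall_ids) {
  lat <- lattice(side, periodic)
  is_wall <- logical(2L * lat$n)
  is_wall[wall_ids] <- TRUE
  open <- !is.na(lat$nbr)
  open[open] <- !is_wall[lat$eid[open]]
  trans <- lat$nbr
  trans[!open] <- rep(seq_len(lat$n), 4)[!open]  # blocked moves stay put
  wp <- lat$ends[sort(wall_ids), , drop = FALSE]
  structure(list(side = as.integer(side), periodic = isTRUE(periodic),
                 walls = wp, wall_ids = sort(as.integer(wall_ids)),
                 open = open, trans = trans),
            class = "maze")
}

#' @export
print.maze <- function(x, ...) {
  cat(sprintf("%s %dx%d maze, %d walls, connected: %s\n",
              if (x$periodic) "periodic" else "bounded", x$side, x$side,
              nrow(x$walls), maze_connected(x)))
  invisible(x)
}

#' Generate a random maze
#'
#' Carves a perfect maze (spanning tree over the lattice) by randomized
#' depth-first search and then removes a few additional walls uniformly at
#' random: 3 for periodic mazes and 4 for bounded mazes, which approximately
#' matches the shortest-path distributions of the two variants. Uses the
#' current R random number generator state, so results are reproducible with
#' \code{set.seed}.
#'
#' @param side cells per edge (default 4)
#' @param periodic wrap across edges? (default TRUE)
#' @param n_extra integer, walls removed after carving; default 3 if periodic
#'   else 4
#' @return an object of class \code{maze}
#' @export
generate_maze <- function(side = 4L, periodic = TRUE, n_extra = NULL) {
  maze_from_wall_ids(side, periodic,
                     carve_wall_ids(side, periodic, n_extra))
}

# DFS-carve a perfect maze and remove n_extra further walls; returns the
# remaining wall edge ids only (cheaper than building the full maze object,
# which matters when sampling hundreds of thousands of layouts)
carve_wall_ids <- function(side = 4L, periodic = TRUE, n_extra = NULL,
                           lat = lattice(side, periodic)) {
  if (is.null(n_extra)) n_extra <- if (periodic) 3L else 4L
  n <- lat$n
  nbrl <- lat$nbrl
  visited <- logical(n)
  carved <- logical(2L * n)  # by edge id
  start <- trunc(runif(1) * n) + 1L
  stack <- integer(n); stack[1] <- start; top <- 1L
  visited[start] <- TRUE
  while (top > 0L) {
    cur <- stack[top]
    nb <- nbrl[[cur]]
    free <- which(!visited[nb$nb])
    nf <- length(free)
    if (!nf) {
      top <- top - 1L
    } else {
      j <- if (nf == 1L) free else free[trunc(runif(1) * nf) + 1L]
      nxt <- nb$nb[j]
      carved[nb$id[j]] <- TRUE
      visited[nxt] <- TRUE
      top <- top + 1L
      stack[top] <- nxt
    }
  }
  remaining <- lat$present[!carved[lat$present]]
  if (n_extra > 0L && length(remaining))
    remaining <- remaining[-sample.int(length(remaining),
                                       min(n_extra, length(remaining)))]
  remaining
}

#' Is the open-passage graph of a maze connected?
#' @param maze a \code{maze}
#' @return logical
#' @export
maze_connected <- function(maze) {
  all(is.finite(bfs_distances(maze, 1L)))
}

# BFS distances from one source over legal moves
bfs_distances <- function(maze, from) {
  n <- maze$side^2
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- integer(n); queue[1] <- from; qh <- 1L; qt <- 1L
  while (qh <= qt) {
    cur <- queue[qh]; qh <- qh + 1L
    for (a in 1:4) {
      if (maze$open[cur, a]) {
        nb <- maze$trans[cur, a]
        if (d[nb] == Inf) {
          d[nb] <- d[cur] + 1
          qt <- qt + 1L
          queue[qt] <- nb
        }
      }
    }
  }
  d
}

#' Shortest path length between two cells
#'
#' Minimal number of legal moves between cells \code{a} and \code{b} under the
#' maze's walls and boundary convention.
#'
#' @param maze a \code{maze}
#' @param a,b cell indices
#' @return integer number of steps
#' @export
shortest_path_length <- function(maze, a, b) {
  n <- maze$side^2
  stopifnot(a >= 1, a <= n, b >= 1, b <= n)
  d <- bfs_distances(maze, as.integer(a))[b]
  if (!is.finite(d)) stop("maze is not connected")
  as.integer(d)
}

#' All-pairs shortest path matrix
#' @param maze a \code{maze}
#' @return integer matrix n x n
#' @export
distance_matrix <- function(maze) {
  n <- maze$side^2
  m <- vapply(seq_len(n), function(s) bfs_distances(maze, s), numeric(n))
  storage.mode(m) <- "integer"
  t(m)
}

#' Expected steps to first reward under the optimal exploration path
#'
#' Brute-force branch-and-bound search for the coverage path that minimises
#' the expected time to first reward, where the hidden goal is uniform over
#' all cells and the path starts at \code{start}. The objective equals the
#' mean over goals of the step index at which each cell is first visited
#' (0 for the start cell).
#'
#' @param maze a \code{maze}
#' @param start starting cell (default 1)
#' @param budget maximum number of search nodes before aborting
#' @return expected number of steps (numeric scalar)
#' @export
optimal_exploration_steps <- function(maze, start = 1L, budget = 5e6) {
  n <- maze$side^2
  dm <- distance_matrix(maze)
  nbrs <- lapply(seq_len(n), function(cell)
    unname(maze$trans[cell, maze$open[cell, ]]))
  best <- Inf
  nodes <- 0L
  # depth-first branch and bound over paths; state: current cell,
  # first-visit times
  rec <- function(cell, visit_time, t, acc) {
    nodes <<- nodes + 1L
    if (nodes > budget) stop("optimal_exploration_steps: search budget exceeded (",
                             budget, " nodes); increase `budget`")
    unv <- which(visit_time < 0L)
    if (!length(unv)) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    # admissible bound: unvisited cells are first visited at distinct future
    # times, each no earlier than the BFS distance from the current cell
    d <- sort(dm[cell, unv])
    lb <- acc + length(unv) * t + sum(pmax(d, seq_along(d)))
    if (lb >= best) return(invisible())
    # explore the nearest-unvisited direction first for a good incumbent
    nbs <- nbrs[[cell]]
    if (length(nbs) > 1L) {
      key <- vapply(nbs, function(nb) min(dm[nb, unv]), numeric(1))
      nbs <- nbs[order(key)]
    }
    for (nb in nbs) {
      vt <- visit_time
      a2 <- acc
      if (vt[nb] < 0L) { vt[nb] <- t + 1L; a2 <- a2 + t + 1L }
      # never revisit more than needed: prune paths that exceed 2n steps
      if (t + 1L <= 2L * n) rec(nb, vt, t + 1L, a2)
    }
    invisible()
  }
  visit0 <- rep(-1L, n)
  visit0[start] <- 0L
  rec(as.integer(start), visit0, 0L, 0)
  best / n
}

#' Write / read a maze as JSON
#'
#' The JSON schema is \code{{side, periodic, walls: [[a, b], ...]}} with
#' 0-based cell indices.
#'
#' @param maze a \code{maze}
#' @param path file path
#' @return \code{read_maze_json} returns a \code{maze}
#' @export
write_maze_json <- function(maze, path) {
  obj <- list(side = maze$side, periodic = maze$periodic,
              walls = unname(lapply(seq_len(nrow(maze$walls)),
                                    function(i) maze$walls[i, ] - 1L)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_maze_json
#' @export
read_maze_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  walls <- if (length(obj$walls) == 0) matrix(integer(0), ncol = 2)
           else if (is.matrix(obj$walls)) obj$walls + 1L
           else matrix(as.integer(unlist(obj$walls)), ncol = 2,
                       byrow = TRUE) + 1L
  new_maze(obj$side, obj$periodic, walls)
}
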
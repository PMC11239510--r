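# Top-level programmatic interface: format validation, run manifests, a
# deterministic small trained fixture, and a thin command-line dispatcher
# (see inst/cli/rollnav) built on the exported functions.

.fixture_cache <- new.env(parent = emptyenv())

#' Deterministic small trained agent fixture
#'
#' Trains (and memoises, per seed and size) a small agent for use in
#' analysis examples and tests. The run is fully determined by its
#' arguments.
#'
#' @param seed RNG seed
#' @param hidden_units GRU size (default 48)
#' @param n_batches training batches of 40 episodes (default 400)
#' @param lr learning rate
#' @return a \code{maze_agent}
#' @export
gen_agent_fixture <- function(seed = 1L, hidden_units = 48L,
                              n_batches = 400L, lr = 2e-3) {
  key <- paste(seed, hidden_units, n_batches, lr, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  set.seed(seed)
  cfg <- agent_config(hidden_units = hidden_units)
  tc <- train_config(n_batches = n_batches, lr = lr, log_every = 25L)
  ag <- train_agent(cfg, tc)
  .fixture_cache[[key]] <- ag
  ag
}

#' Validate an external file against a named schema
#'
#' Supported schemas: \code{"maze_json"} (side/periodic/walls with 0-based
#' adjacent cell pairs), \code{"behavior_csv"} (participant, episode, trial,
#' step, state, action, response_time_ms, guided, first_action) and
#' \code{"prior_json"} (mu, sigma, delta_ms, action_class).
#'
#' @param file path
#' @param schema schema name
#' @return data.frame of violations (zero rows when valid)
#' @export
validate_file <- function(file, schema) {
  if (!file.exists(file)) stop("unreadable file: ", file)
  bad <- function(field, msg) data.frame(field = field, message = msg)
  v <- NULL
  if (schema == "maze_json") {
    obj <- jsonlite::read_json(file, simplifyVector = TRUE)
    for (f in c("side", "periodic", "walls"))
      if (is.null(obj[[f]])) v <- rbind(v, bad(f, "missing field"))
    if (is.null(v)) {
      side <- obj$side
      lat <- lattice(side, isTRUE(obj$periodic))
      keyz <- paste(lat$ends[lat$present, 1], lat$ends[lat$present, 2])
      walls <- obj$walls
      if (is.matrix(walls)) walls <- lapply(seq_len(nrow(walls)),
                                            function(i) walls[i, ])
      for (w in walls) {
        w1 <- sort(unlist(w)) + 1L
        if (any(w1 < 1) || any(w1 > side^2))
          v <- rbind(v, bad("walls", paste("cell out of range:",
                                           paste(w1 - 1L, collapse = ","))))
        else if (!(paste(w1[1], w1[2]) %in% keyz))
          v <- rbind(v, bad("walls", paste("non-adjacent pair:",
                                           paste(w1 - 1L, collapse = ","))))
      }
    }
  } else if (schema == "behavior_csv") {
    tab <- utils::read.csv(file)
    req <- c("participant", "episode", "trial", "step", "state", "action",
             "response_time_ms", "guided", "first_action")
    for (f in setdiff(req, names(tab)))
      v <- rbind(v, bad(f, "missing column"))
    if ("response_time_ms" %in% names(tab) &&
        any(tab$response_time_ms < 0, na.rm = TRUE))
      v <- rbind(v, bad("response_time_ms", "negative response time"))
    if ("action" %in% names(tab) &&
        any(!tab$action %in% 1:5))
      v <- rbind(v, bad("action", "action index outside 1..5"))
  } else if (schema == "prior_json") {
    obj <- jsonlite::read_json(file, simplifyVector = TRUE)
    for (f in c("mu", "sigma", "delta_ms", "action_class"))
      if (is.null(obj[[f]])) v <- rbind(v, bad(f, "missing field"))
    if (!is.null(obj$sigma) && obj$sigma <= 0)
      v <- rbind(v, bad("sigma", "sigma must be positive"))
    if (!is.null(obj$delta_ms) && obj$delta_ms < 0)
      v <- rbind(v, bad("delta_ms", "delta must be nonnegative"))
  } else {
    stop("unknown schema: ", schema)
  }
  if (is.null(v)) data.frame(field = character(0), message = character(0))
  else v
}

#' Write a machine-readable run manifest
#'
#' @param out_dir output directory
#' @param seed master seed
#' @param config_list configuration used (any serialisable list)
#' @return the manifest path, invisibly
#' @export
write_manifest <- function(out_dir, seed, config_list = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_str <- paste(deparse(config_list), collapse = "")
  manifest <- list(
    package = "rollnav",
    version = as.character(utils::packageVersion("rollnav")),
    seed = seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        seq_along(utf8ToInt(cfg_str))) %%
                            .Machine$integer.max),
    config = config_list)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands used by the \code{inst/cli/rollnav} script:
#' \code{taskspace}, \code{thinktime}, \code{synth-rt} and \code{validate}.
#' Heavier work (training, replay statistics) is intended to be driven from
#' R via the exported functions.
#'
#' @param argv character vector of arguments
#' @return exit status (0 on success), invisibly
#' @export
rollnav_main <- function(argv = character()) {
  usage <- paste(
    "usage: rollnav <command> [options]",
    "commands:",
    "  taskspace --n N --reps R --seed S --out FILE",
    "  thinktime --rt FILE --out FILE",
    "  synth-rt --participants N --seed S --out FILE",
    "  validate --file FILE --schema NAME", sep = "\n")
  if (!length(argv) || argv[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  opt <- function(name, default = NULL) {
    i <- which(argv == paste0("--", name))
    if (length(i) && i < length(argv)) argv[i + 1] else default
  }
  cmd <- argv[1]
  seed <- as.integer(opt("seed", "1"))
  set.seed(seed)
  if (cmd == "taskspace") {
    est <- estimate_task_space(n = as.integer(opt("n", "50000")),
                               reps = as.integer(opt("reps", "10")))
    out <- opt("out")
    res <- list(mean = est$mean, sem = est$sem, seed = seed)
    if (!is.null(out)) jsonlite::write_json(res, out, auto_unbox = TRUE,
                                            digits = NA)
    cat(sprintf("task space: %.3g +- %.2g\n", est$mean, est$sem))
  } else if (cmd == "thinktime") {
    rt <- opt("rt")
    if (is.null(rt) || !file.exists(rt)) { cat("missing --rt file\n"); return(invisible(1L)) }
    tab <- utils::read.csv(rt)
    est <- estimate_thinking_times(tab)
    out <- opt("out", "thinking_times.csv")
    utils::write.csv(est, out, row.names = FALSE)
    cat("wrote", out, "\n")
  } else if (cmd == "synth-rt") {
    tab <- gen_rt_dataset(n_participants = as.integer(opt("participants", "10")))
    out <- opt("out", "rt_synth.csv")
    utils::write.csv(tab, out, row.names = FALSE)
    cat("wrote", out, "\n")
  } else if (cmd == "validate") {
    v <- validate_file(opt("file"), opt("schema"))
    if (nrow(v)) {
      print(v)
      return(invisible(1L))
    }
    cat("ok\n")
  } else {
    cat("unknown command:", cmd, "\n", usage, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
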
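# Synthetic response-time tables with known ground-truth thinking times.

#' Generate a synthetic behaviour table of response times
#'
#' Emulates the additive response-time model \code{t_r = t_t + t_d}:
#' guided actions have \code{t_t = 0}, nonguided thinking times are drawn
#' from a configurable (by default distance-dependent exponential) model,
#' and delays come from per-class shifted log-normal priors. Per-row
#' ground-truth thinking times are stored in \code{true_tt_ms} so recovery
#' error is computable.
#'
#' @param n_participants number of participants
#' @param prior_params list with elements \code{first_of_trial} and
#'   \code{other}, each \code{list(mu, sigma, delta)} on the ms scale
#' @param tt_model function(n, distance) returning thinking times (ms); the
#'   default draws from an exponential with mean \code{150 + 150 * distance}
#'   capped at 6 s
#' @param n_guided,n_nonguided actions per participant in each condition
#' @param max_rt_ms response cap: the task resets responses longer than 7 s,
#'   so rows are redrawn until they fall below it
#' @return data.frame with columns participant, episode, trial, step, state,
#'   action, response_time_ms, guided, first_action, distance_to_goal,
#'   true_tt_ms
#' @export
gen_rt_dataset <- function(n_participants = 10,
                           prior_params = list(
                             first_of_trial = list(mu = 5.8, sigma = 0.4, delta = 250),
                             other = list(mu = 5.5, sigma = 0.4, delta = 200)),
                           tt_model = NULL,
                           n_guided = 150, n_nonguided = 300,
                           max_rt_ms = 7000) {
  for (cls in c("first_of_trial", "other")) {
    pp <- prior_params[[cls]]
    if (is.null(pp) || pp$sigma <= 0 || pp$delta < 0)
      stop("invalid prior parameters for class ", cls)
  }
  if (is.null(tt_model))
    tt_model <- function(n, distance)
      pmin(rexp(n, rate = 1 / (150 + 150 * distance)), 6000)
  draw_delay <- function(n, pp) pp$delta + exp(rnorm(n, pp$mu, pp$sigma))
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (guided in c(TRUE, FALSE)) {
      n_act <- if (guided) n_guided else n_nonguided
      step <- ((seq_len(n_act) - 1L) %% 5L) + 1L
      trial <- ((seq_len(n_act) - 1L) %/% 5L) %% 4L + 1L
      episode <- (seq_len(n_act) - 1L) %/% 20L + 1L
      first <- step == 1L
      dist <- sample(1:6, n_act, replace = TRUE)
      tt <- if (guided) numeric(n_act) else tt_model(n_act, dist)
      td <- numeric(n_act)
      td[first] <- draw_delay(sum(first), prior_params$first_of_trial)
      td[!first] <- draw_delay(sum(!first), prior_params$other)
      # the task resets responses longer than the cap; redraw those rows
      for (tries in 1:50) {
        over <- which(tt + td >= max_rt_ms)
        if (!length(over)) break
        if (!guided) tt[over] <- tt_model(length(over), dist[over])
        ov1 <- over[first[over]]; ov2 <- over[!first[over]]
        td[ov1] <- draw_delay(length(ov1), prior_params$first_of_trial)
        td[ov2] <- draw_delay(length(ov2), prior_params$other)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, episode = episode, trial = trial, step = step,
        state = sample(1:16, n_act, replace = TRUE),
        action = sample(1:4, n_act, replace = TRUE),
        response_time_ms = tt + td,
        guided = guided, first_action = first,
        distance_to_goal = dist, true_tt_ms = tt)
    }
  }
  do.call(rbind, rows)
}
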
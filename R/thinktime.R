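# Bayesian decomposition of response times into thinking time plus a
# perception-action delay.
#
# Model: t_r = t_t + t_d with t_t >= 0 (uniform prior on [0, 7 s], which
# never binds because responses are capped at 7 s by task rules) and
# t_d ~ shifted log-normal(mu, sigma, delta). On guided actions t_t = 0, so
# the delay prior is fitted directly to guided response times. The posterior
# mean thinking time given an observed t_r is available in closed form via
# the truncated log-normal conditional expectation.

#' Fit the shifted log-normal perception-action delay prior
#'
#' Maximum-likelihood fit to guided response times. For fixed shift
#' \code{delta}, the ML \code{(mu, sigma)} are the mean and (ML) standard
#' deviation of \code{log(t - delta)}; \code{delta} is found by a 1-ms grid
#' search over \code{[0, min(t) - 1]}, which keeps every observation at
#' positive density.
#'
#' @param guided_rts numeric vector of guided response times (ms), all > 0
#' @param action_class \code{"first_of_trial"} (actions immediately after a
#'   teleport) or \code{"other"}; fitted separately because the first action
#'   of a trial carries an extra perceptual delay
#' @return object of class \code{delay_prior} with fields \code{mu},
#'   \code{sigma}, \code{delta} (ms), \code{action_class},
#'   \code{mean_guided}, \code{loglik}
#' @export
fit_delay_prior <- function(guided_rts, action_class = "other") {
  if (length(guided_rts) < 2) stop("need at least 2 guided response times")
  if (any(guided_rts <= 0)) stop("guided response times must be positive")
  if (any(!is.finite(guided_rts))) stop("non-finite response times")
  dmax <- floor(min(guided_rts)) - 1
  deltas <- if (dmax < 0) 0 else seq(0, dmax, by = 1)
  n <- length(guided_rts)
  best <- NULL
  for (d in deltas) {
    lx <- log(guided_rts - d)
    mu <- mean(lx)
    sg <- sqrt(mean((lx - mu)^2))
    if (sg <= 0) next
    ll <- -sum(lx) - n * log(sg) - n / 2 * log(2 * pi) - n / 2
    if (is.null(best) || ll > best$loglik)
      best <- list(mu = mu, sigma = sg, delta = d, loglik = ll)
  }
  if (is.null(best)) stop("degenerate guided response times (zero variance)")
  structure(c(best, list(action_class = action_class, n = n,
                         mean_guided = mean(guided_rts))),
            class = "delay_prior")
}

#' @export
print.delay_prior <- function(x, ...) {
  cat(sprintf(
    "delay_prior (%s): mu = %.3f, sigma = %.3f, delta = %.0f ms (n = %d)\n",
    x$action_class, x$mu, x$sigma, x$delta, x$n))
  cat(sprintf("  implied mean delay: %.0f ms\n",
              x$delta + exp(x$mu + 0.5 * x$sigma^2)))
  invisible(x)
}

#' @export
coef.delay_prior <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, delta = object$delta)
}

#' Conditional mean of a log-normal variable below a threshold
#'
#' \code{E[x | x < k]} for \code{x ~ lognormal(mu, sigma)}, computed in
#' closed form with log-space normal CDF ratios for numerical stability at
#' extreme arguments.
#'
#' @param k positive truncation point
#' @param mu,sigma log-scale location and scale (sigma > 0)
#' @return numeric in (0, k)
#' @export
truncated_lognormal_mean <- function(k, mu, sigma) {
  if (any(k <= 0)) stop("truncation point k must be positive")
  stopifnot(sigma > 0)
  a <- (log(k) - mu) / sigma
  exp(mu + 0.5 * sigma^2 +
        pnorm(a - sigma, log.p = TRUE) - pnorm(a, log.p = TRUE))
}

#' Posterior-mean thinking time for one response time
#'
#' \code{t_hat = t_r - delta - E[x | x < t_r - delta]} under the fitted
#' delay prior; responses shorter than the estimated minimum delay
#' (\code{t_r <= delta}) get thinking time 0.
#'
#' @param t_r response time(s), ms
#' @param prior a \code{delay_prior}
#' @param strategy \code{"posterior_mean"} (default), \code{"posterior_mode"}
#'   or \code{"constant_delay"} (subtracts the mean guided response time);
#'   the alternatives are robustness checks
#' @return thinking time estimate(s), ms
#' @export
posterior_mean_thinking_time <- function(t_r, prior,
                                         strategy = "posterior_mean") {
  stopifnot(inherits(prior, "delay_prior"))
  strategy <- match.arg(strategy,
                        c("posterior_mean", "posterior_mode", "constant_delay"))
  if (strategy == "constant_delay")
    return(pmax(0, t_r - prior$mean_guided))
  if (strategy == "posterior_mode")
    return(pmax(0, t_r - prior$delta - exp(prior$mu - prior$sigma^2)))
  out <- numeric(length(t_r))
  pos <- which(t_r > prior$delta)
  if (length(pos)) {
    k <- t_r[pos] - prior$delta
    out[pos] <- k - truncated_lognormal_mean(k, prior$mu, prior$sigma)
  }
  out
}

#' @export
predict.delay_prior <- function(object, newdata, ...) {
  posterior_mean_thinking_time(newdata, object, ...)
}

#' Fit delay priors for every participant and action class
#'
#' @param rt_table behaviour table with columns \code{participant},
#'   \code{response_time_ms}, \code{guided} (logical/0-1) and
#'   \code{first_action} (logical/0-1)
#' @return nested list \code{priors[[participant]][[class]]} of
#'   \code{delay_prior} objects
#' @export
fit_thinking_priors <- function(rt_table) {
  req <- c("participant", "response_time_ms", "guided", "first_action")
  if (!all(req %in% names(rt_table)))
    stop("rt_table must contain columns: ", paste(req, collapse = ", "))
  g <- rt_table[as.logical(rt_table$guided), ]
  out <- list()
  for (p in unique(g$participant)) {
    gp <- g[g$participant == p, ]
    out[[as.character(p)]] <- list(
      first_of_trial = fit_delay_prior(
        gp$response_time_ms[as.logical(gp$first_action)], "first_of_trial"),
      other = fit_delay_prior(
        gp$response_time_ms[!as.logical(gp$first_action)], "other"))
  }
  out
}

#' Estimate thinking times for every nonguided action
#'
#' @param rt_table behaviour table (see \code{fit_thinking_priors})
#' @param priors output of \code{fit_thinking_priors}; fitted from the
#'   guided rows of \code{rt_table} when NULL
#' @param strategy estimator variant, see
#'   \code{\link{posterior_mean_thinking_time}}
#' @return the nonguided rows of \code{rt_table} with an added
#'   \code{thinking_time_ms} column; the fraction of responses below the
#'   fitted minimum delay is attached as attribute \code{"frac_below_delta"}
#' @export
estimate_thinking_times <- function(rt_table, priors = NULL,
                                    strategy = "posterior_mean") {
  if (is.null(priors)) priors <- fit_thinking_priors(rt_table)
  ng <- rt_table[!as.logical(rt_table$guided), , drop = FALSE]
  tt <- numeric(nrow(ng))
  below <- 0L
  for (p in unique(ng$participant)) {
    pp <- priors[[as.character(p)]]
    if (is.null(pp)) stop("no fitted prior for participant ", p)
    for (cls in c(TRUE, FALSE)) {
      rows <- which(ng$participant == p & as.logical(ng$first_action) == cls)
      if (!length(rows)) next
      prior <- if (cls) pp$first_of_trial else pp$other
      if (is.null(prior)) stop("missing prior class for participant ", p)
      rts <- ng$response_time_ms[rows]
      tt[rows] <- posterior_mean_thinking_time(rts, prior, strategy)
      below <- below + sum(rts <= prior$delta)
    }
  }
  ng$thinking_time_ms <- tt
  attr(ng, "frac_below_delta") <- below / max(1L, nrow(ng))
  ng
}
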
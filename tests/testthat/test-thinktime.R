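test_that("delay-prior fit recovers known shifted log-normal parameters", {
  set.seed(31)
  x <- 200 + exp(rnorm(10000, 5.5, 0.4))
  pr <- fit_delay_prior(x)
  expect_lt(abs(pr$mu - 5.5), 0.05)
  expect_lt(abs(pr$sigma - 0.4), 0.05)
  expect_lt(abs(pr$delta - 200), 20)
})

test_that("unshifted data fit a near-zero delta and sample log-moments", {
  set.seed(32)
  x <- exp(rnorm(8000, 6, 0.3))
  pr <- fit_delay_prior(x)
  expect_lt(pr$delta / min(x), 0.25)
  lx <- log(x - pr$delta)
  expect_equal(pr$mu, mean(lx), tolerance = 1e-9)
})

test_that("fitted delta never exceeds min(data) - 1 ms", {
  set.seed(33)
  for (i in 1:10) {
    x <- 50 + exp(rnorm(200, 5, 0.5))
    pr <- fit_delay_prior(x)
    expect_lte(pr$delta, min(x) - 1)
  }
  expect_error(fit_delay_prior(c(500)), "at least 2")
  expect_error(fit_delay_prior(c(-1, 500, 600)), "positive")
})

test_that("truncated log-normal mean matches numerical quadrature on a grid", {
  grid <- expand.grid(mu = c(-1, 0, 5.5, 6.2), sigma = c(0.2, 0.5, 1),
                      kfac = c(0.3, 1, 3, 10, 100))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; sg <- grid$sigma[i]
    k <- grid$kfac[i] * exp(mu)
    num <- integrate(function(x) x * dlnorm(x, mu, sg), 0, k,
                     rel.tol = 1e-12)$value / plnorm(k, mu, sg)
    cf <- truncated_lognormal_mean(k, mu, sg)
    expect_lt(abs(cf - num) / num, 1e-6)
    expect_gt(cf, 0); expect_lt(cf, k)
  }
  expect_error(truncated_lognormal_mean(-1, 0, 1), "positive")
})

test_that("truncated mean is increasing in k and approaches the full mean", {
  ks <- exp(seq(-2, 6, length.out = 60))
  v <- truncated_lognormal_mean(ks, 0.5, 0.6)
  expect_true(all(diff(v) >= 0))
  expect_true(all(diff(v[ks < exp(0.5 + 3 * 0.6)]) > 0))  # strict before saturation
  expect_equal(v[60], exp(0.5 + 0.18), tolerance = 1e-6)
})

test_that("posterior-mean thinking time: edge cases and limits", {
  pr <- structure(list(mu = 5.5, sigma = 0.4, delta = 200,
                       action_class = "other", n = 10, mean_guided = 450,
                       loglik = 0), class = "delay_prior")
  # response faster than the minimum delay
  expect_equal(posterior_mean_thinking_time(150, pr), 0)
  expect_equal(posterior_mean_thinking_time(200, pr), 0)
  # monotone nondecreasing in t_r
  tr <- seq(100, 4000, by = 25)
  est <- posterior_mean_thinking_time(tr, pr)
  expect_true(all(diff(est) >= -1e-9))
  expect_true(all(est >= 0 & est <= pmax(0, tr - pr$delta)))
  # sigma -> 0: delay becomes the constant delta + exp(mu)
  pr2 <- pr; pr2$sigma <- 1e-4
  tr2 <- 2000
  expect_equal(posterior_mean_thinking_time(tr2, pr2),
               tr2 - 200 - exp(5.5), tolerance = 0.5)
})

test_that("posterior mean agrees with a Monte-Carlo rejection oracle", {
  set.seed(34)
  pr <- structure(list(mu = 5.5, sigma = 0.4, delta = 200,
                       action_class = "other", n = 10, mean_guided = 450,
                       loglik = 0), class = "delay_prior")
  for (tr in c(600, 1000, 2000)) {
    td <- 200 + exp(rnorm(4e5, 5.5, 0.4))
    keep <- td < tr
    mc <- mean(tr - td[keep])
    se <- sd(tr - td[keep]) / sqrt(sum(keep))
    cf <- posterior_mean_thinking_time(tr, pr)
    expect_lt(abs(cf - mc), 3 * se + 1e-9)
  }
})

test_that("estimator variants behave sensibly", {
  pr <- structure(list(mu = 5.5, sigma = 0.4, delta = 200,
                       action_class = "other", n = 10, mean_guided = 450,
                       loglik = 0), class = "delay_prior")
  expect_equal(posterior_mean_thinking_time(1000, pr, "constant_delay"),
               1000 - 450)
  expect_equal(posterior_mean_thinking_time(1000, pr, "posterior_mode"),
               max(0, 1000 - 200 - exp(5.5 - 0.16)))
})

test_that("estimate_thinking_times excludes guided rows and recovers truth", {
  set.seed(35)
  tab <- gen_rt_dataset(n_participants = 6)
  est <- estimate_thinking_times(tab)
  expect_true(all(!est$guided))
  expect_equal(nrow(est), sum(!tab$guided))
  # constant response times give constant estimates within a class
  one <- tab[tab$participant == 1, ]
  one$response_time_ms[!one$guided] <- 800
  est1 <- estimate_thinking_times(one)
  expect_equal(length(unique(est1$thinking_time_ms[est1$first_action])), 1)
  # recovery: mean absolute error below the delay prior's s.d. (~110 ms)
  delay_sd <- sqrt((exp(0.16) - 1) * exp(2 * 5.5 + 0.16))
  expect_lt(mean(abs(est$thinking_time_ms - est$true_tt_ms)), delay_sd)
})

test_that("fit-estimate round trip is approximately unbiased", {
  # per-condition bias within 3 s.e. over simulated participants
  set.seed(36)
  tab <- gen_rt_dataset(n_participants = 30, n_guided = 120,
                        n_nonguided = 150)
  est <- estimate_thinking_times(tab)
  per_p <- tapply(est$thinking_time_ms - est$true_tt_ms, est$participant,
                  mean)
  bias <- mean(per_p)
  se <- sd(per_p) / sqrt(length(per_p))
  expect_lt(abs(bias), 3 * se + 15)  # 15 ms numerical floor
})
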
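test_that("posterior shapes follow the conjugate update identities", {
  # s = 5 current + t = 3 future successes of N = 20 trials, uniform prior
  post <- posterior_update(beta_state(1, 1), successes = 5 + 3,
                           failures = 20 - 5 - 3)
  expect_equal(post$alpha, 9)
  expect_equal(post$beta, 13)

  # no data leaves the prior untouched
  same <- posterior_update(beta_state(1, 1), 0, 0)
  expect_equal(c(same$alpha, same$beta), c(1, 1))

  # updating in two batches equals one combined update
  a <- posterior_update(posterior_update(beta_state(2, 3), 4, 6), 1, 2)
  b <- posterior_update(beta_state(2, 3), 5, 8)
  expect_equal(c(a$alpha, a$beta), c(b$alpha, b$beta))

  expect_error(posterior_update(beta_state(), -1, 0), "non-negative")
  expect_error(beta_state(0, 1), "positive")
})

test_that("the predictive pmf normalizes and matches its moments on a grid", {
  for (a in c(0.5, 1, 2, 5)) {
    for (b in c(0.5, 1, 2, 5)) {
      for (N in c(1, 7, 23, 50)) {
        for (n in unique(c(0, 1, N %/% 2, N))) {
          s <- min(n, 1 + n %/% 3)
          pmf <- predictive_pmf(beta_state(a, b), N, n, s)
          expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
          # law of total expectation: E[T] = (N-n)(a+s)/(a+b+n)
          expect_equal(sum(pmf$t * pmf$prob),
                       (N - n) * (a + s) / (a + b + n),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("a uniform prior with no data yields a uniform predictive", {
  pmf <- predictive_pmf(beta_state(1, 1), N = 10, n = 0, s = 0)
  expect_equal(pmf$prob, rep(1 / 11, 11), tolerance = 1e-12)
  # and the independent quadrature oracle agrees on a non-trivial state
  q <- quad_predictive(2, 3, N = 12, n = 5, s = 2)
  pmf2 <- predictive_pmf(beta_state(2, 3), N = 12, n = 5, s = 2)
  expect_equal(pmf2$prob, q / sum(q), tolerance = 1e-8)
})

test_that("the predictive pmf matches Monte-Carlo sampling", {
  set.seed(31)
  a <- 1.5; b <- 2; N <- 30; n <- 12; s <- 7
  draws <- 1e5
  p_star <- rbeta(draws, a + s, b + n - s)
  t_draw <- rbinom(draws, N - n, p_star)
  pmf <- predictive_pmf(beta_state(a, b), N, n, s)
  for (tv in c(0, 5, 10, 18)) {
    phat <- mean(t_draw == tv)
    se <- sqrt(max(phat * (1 - phat), 1e-8) / draws)
    expect_lt(abs(phat - pmf$prob[pmf$t == tv]), 3 * se + 1e-6)
  }
})

test_that("no remaining cells gives a point mass at zero future successes", {
  pmf <- predictive_pmf(beta_state(2, 2), N = 8, n = 8, s = 3)
  expect_equal(pmf$t, 0L)
  expect_equal(pmf$prob, 1)
})

test_that("goal probabilities reduce to sums of the predictive pmf", {
  prior <- beta_state(1, 1)
  expect_equal(prob_goal(prior, N = 20, n = 10, s = 6, goal = 5), 1)
  expect_equal(prob_goal(prior, N = 20, n = 18, s = 2, goal = 10), 0)
  expect_error(prob_goal(prior, N = 20, n = 5, s = 2, goal = 25), "goal")

  # direct-summation oracle over a grid of goals
  pmf <- predictive_pmf(prior, N = 20, n = 8, s = 5)
  for (g in 0:20) {
    expect_equal(prob_goal(prior, 20, 8, 5, g),
                 min(1, sum(pmf$prob[pmf$t >= g - 5])),
                 tolerance = 1e-12)
  }

  # monotone: nonincreasing in goal, nondecreasing in s
  pg <- sapply(0:20, function(g) prob_goal(prior, 20, 8, 5, g))
  expect_true(all(diff(pg) <= 1e-12))
  ps <- sapply(0:8, function(s) prob_goal(prior, 20, 8, s, 12))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("monitoring stops at the first threshold crossing", {
  prior <- beta_state(1, 1)
  # certain success at the first look
  sure <- monitor_trial(tibble::tibble(n = 10, s = 10), prior,
                        N = 10, goal = 5)
  expect_equal(sure$action, "stop_superiority")
  # certain failure at the first look
  lost <- monitor_trial(tibble::tibble(n = 18, s = 0), prior,
                        N = 20, goal = 15)
  expect_equal(lost$action, "stop_futility")

  # three-look trajectory checked against an independent quadrature oracle
  looks <- tibble::tibble(n = c(6, 12, 18), s = c(3, 8, 14))
  N <- 24; goal <- 17
  res <- monitor_trial(looks, prior, N = N, goal = goal,
                       superiority = 0.9, futility = 0.1)
  oracle_actions <- character(3)
  stopped <- FALSE
  for (i in 1:3) {
    if (stopped) { oracle_actions[i] <- "not_evaluated"; next }
    q <- quad_predictive(1, 1, N, looks$n[i], looks$s[i])
    p <- sum(q[seq_along(q) - 1 >= goal - looks$s[i]]) / sum(q)
    expect_equal(res$prob_success[i], p, tolerance = 1e-8)
    oracle_actions[i] <- if (p >= 0.9) { stopped <- TRUE; "stop_superiority" }
      else if (p <= 0.1) { stopped <- TRUE; "stop_futility" }
      else "continue"
  }
  expect_equal(res$action, oracle_actions)

  expect_error(monitor_trial(tibble::tibble(n = c(5, 4), s = c(1, 1)),
                             prior, N = 10, goal = 5), "nondecreasing")
})

test_that("credible intervals invert the beta distribution", {
  ci <- credible_interval(beta_state(1, 1), 0.95)
  expect_equal(ci$lower, 0.025)
  expect_equal(ci$upper, 0.975)

  # quadrature-inversion oracle for Beta(9, 13)
  cdf <- function(x) stats::integrate(function(p) stats::dbeta(p, 9, 13),
                                      0, x, rel.tol = 1e-12)$value
  lo <- stats::uniroot(function(x) cdf(x) - 0.025, c(1e-9, 1 - 1e-9),
                       tol = 1e-12)$root
  hi <- stats::uniroot(function(x) cdf(x) - 0.975, c(1e-9, 1 - 1e-9),
                       tol = 1e-12)$root
  ci2 <- credible_interval(beta_state(9, 13), 0.95)
  expect_lt(abs(ci2$lower - lo), 1e-6)
  expect_lt(abs(ci2$upper - hi), 1e-6)

  # concentration: width shrinks as evidence grows at fixed mean
  widths <- sapply(c(1, 4, 16, 64), function(m) {
    ci <- credible_interval(beta_state(2 * m, 3 * m), 0.95)
    ci$upper - ci$lower
  })
  expect_true(all(diff(widths) < 0))
  expect_error(credible_interval(beta_state(1, 1), 1.5), "level")
})

test_that("prior sensitivity reports divergence of posterior means", {
  grid <- tibble::tibble(alpha = c(0.5, 1, 2), beta = c(0.5, 1, 2))

  # no data: posterior means equal prior means
  none <- prior_sensitivity(grid, N = 10, n = 0, s = 0, goal = 5)
  expect_equal(none$post_mean, rep(0.5, 3))
  expect_equal(attr(none, "divergence"), 0)

  # closed form: posterior mean spread is (a+s)/(a+b+n) over the grid
  sens <- prior_sensitivity(grid, N = 20, n = 8, s = 5, goal = 12)
  means <- (grid$alpha + 5) / (grid$alpha + grid$beta + 8)
  expect_equal(sens$post_mean, means)
  expect_equal(attr(sens, "divergence"), max(means) - min(means))

  # data swamp the prior
  big <- prior_sensitivity(grid, N = 2e4, n = 1e4, s = 6e3, goal = 1.2e4)
  expect_lt(attr(big, "divergence"), 1e-3)
  expect_false(attr(big, "prior_dominated"))

  expect_error(prior_sensitivity(grid[0, ], N = 10, n = 0, s = 0, goal = 5),
               "nonempty")
})
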
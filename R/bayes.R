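#' Beta prior/posterior state
#'
#' A conjugate Beta(alpha, beta) distribution over the differentiation rate.
#' The default uniform Beta(1, 1) is the recommended noninformative starting
#' prior before any cells have been assayed.
#'
#' @param alpha,beta Strictly positive shape parameters.
#' @return An object of class `beta_state`.
#' @examples
#' beta_state()          # the Beta(1, 1) default
#' beta_state(9, 13)
#' @export
beta_state <- function(alpha = 1, beta = 1) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    rlang::abort("alpha and beta must be finite and strictly positive")
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_state")
}

#' @export
print.beta_state <- function(x, ...) {
  cat(sprintf("Beta(%g, %g); mean %.4f\n", x$alpha, x$beta,
              x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Conjugate posterior update of a beta state
#'
#' Adds observed successes (differentiated cells) and failures to the beta
#' shape parameters. With a prior Beta(alpha, beta), observing `s` current
#' successes and `t` future successes out of `N` trials in total gives the
#' posterior shapes `alpha* = s + t + alpha` and `beta* = N - s - t + beta`,
#' i.e. `posterior_update(prior, s + t, N - s - t)`.
#'
#' @param prior A [beta_state()].
#' @param successes,failures Non-negative counts.
#' @return The posterior [beta_state()].
#' @examples
#' posterior_update(beta_state(1, 1), successes = 5 + 3, failures = 20 - 5 - 3)
#' @export
posterior_update <- function(prior, successes, failures) {
  stopifnot(inherits(prior, "beta_state"))
  if (successes < 0 || failures < 0) {
    rlang::abort("successes and failures must be non-negative")
  }
  beta_state(prior$alpha + successes, prior$beta + failures)
}

check_trial <- function(N, n, s) {
  if (N < 0 || n < 0 || s < 0 || s > n || n > N) {
    rlang::abort("trial state must satisfy 0 <= s <= n <= N")
  }
}

#' Beta-binomial predictive distribution over future successes
#'
#' Given `s` differentiated cells among `n` assayed so far out of `N` cells
#' that can differentiate, and a Beta(alpha, beta) prior on the
#' differentiation rate, the number `T` of additional differentiated cells
#' among the `N - n` remaining follows the beta-binomial predictive
#' \deqn{p(t \mid s) = \binom{N-n}{t}
#'   \frac{B(\alpha+s+t,\; \beta+n-s+N-n-t)}{B(\alpha+s,\; \beta+n-s)}}
#' for `t = 0, ..., N - n`. Computed in log space so counts up to 10^6 are
#' handled without overflow.
#'
#' @param prior A [beta_state()].
#' @param N Total number of cells that can differentiate.
#' @param n Cells assayed so far.
#' @param s Differentiated cells among those assayed.
#' @return A tibble with columns `t` (0..N-n) and `prob`, summing to 1.
#' @examples
#' # uniform prior, no data: the predictive over totals is uniform
#' predictive_pmf(beta_state(1, 1), N = 10, n = 0, s = 0)
#' @export
predictive_pmf <- function(prior, N, n, s) {
  stopifnot(inherits(prior, "beta_state"))
  check_trial(N, n, s)
  m <- N - n
  t <- 0:m
  if (m == 0) {
    return(tibble::tibble(t = 0L, prob = 1))
  }
  logp <- lchoose(m, t) +
    lbeta(prior$alpha + s + t, prior$beta + n - s + m - t) -
    lbeta(prior$alpha + s, prior$beta + n - s)
  prob <- exp(logp)
  tibble::tibble(t = t, prob = prob / sum(prob))
}

#' Predictive probability of reaching a differentiation goal
#'
#' The probability, under the beta-binomial predictive, that the trial ends
#' with at least `goal` differentiated cells in total, i.e.
#' `P(s + T >= goal)`.
#'
#' @inheritParams predictive_pmf
#' @param goal Required total number of successes, `0 <= goal <= N`.
#' @return A probability in \[0, 1\].
#' @export
prob_goal <- function(prior, N, n, s, goal) {
  check_trial(N, n, s)
  if (goal < 0 || goal > N) rlang::abort("goal must lie in [0, N]")
  need <- goal - s
  if (need <= 0) return(1)
  if (need > N - n) return(0)
  pmf <- predictive_pmf(prior, N, n, s)
  min(max(sum(pmf$prob[pmf$t >= need]), 0), 1)
}

#' Sequential predictive monitoring with stopping rules
#'
#' Evaluates interim looks in order, computing at each the predictive
#' probability of reaching the trial goal. The first look whose probability
#' crosses a threshold stops the run: `stop_superiority` when the probability
#' is at least `superiority`, `stop_futility` when it is at most `futility`.
#' Looks after a stop are reported but not evaluated.
#'
#' @param looks A data frame with columns `n` and `s`, one row per interim
#'   look, nondecreasing in both.
#' @param prior A [beta_state()].
#' @param N Total number of cells that can differentiate.
#' @param goal Required total successes.
#' @param superiority,futility Stopping thresholds in (0, 1) with
#'   `futility < superiority`.
#' @return A tibble with one row per look: `look`, `n`, `s`, `prob_success`,
#'   `action` (`continue`, `stop_superiority`, `stop_futility`, or
#'   `not_evaluated`).
#' @examples
#' looks <- tibble::tibble(n = c(5, 10, 15), s = c(4, 8, 13))
#' monitor_trial(looks, beta_state(), N = 20, goal = 15)
#' @export
monitor_trial <- function(looks, prior = beta_state(), N, goal,
                          superiority = 0.95, futility = 0.05) {
  looks <- tibble::as_tibble(looks)
  if (!all(c("n", "s") %in% names(looks))) {
    rlang::abort("looks needs columns n and s")
  }
  if (futility >= superiority || futility <= 0 || superiority >= 1) {
    rlang::abort("need 0 < futility < superiority < 1")
  }
  if (any(diff(looks$n) < 0) || any(diff(looks$s) < 0)) {
    rlang::abort("looks must be nondecreasing in n and s")
  }
  out <- dplyr::mutate(looks, look = dplyr::row_number(),
                       prob_success = NA_real_, action = "not_evaluated")
  stopped <- FALSE
  for (i in seq_len(nrow(out))) {
    if (stopped) break
    p <- prob_goal(prior, N, out$n[i], out$s[i], goal)
    out$prob_success[i] <- p
    out$action[i] <- if (p >= superiority) {
      stopped <- TRUE; "stop_superiority"
    } else if (p <= futility) {
      stopped <- TRUE; "stop_futility"
    } else "continue"
  }
  dplyr::select(out, "look", "n", "s", "prob_success", "action")
}

#' Equal-tailed credible interval for a beta state
#'
#' @param state A [beta_state()] (typically a posterior).
#' @param level Coverage in (0, 1); default 0.95.
#' @return A tibble with `lower`, `upper` and `level`.
#' @examples
#' credible_interval(beta_state(9, 13))
#' @export
credible_interval <- function(state, level = 0.95) {
  stopifnot(inherits(state, "beta_state"))
  if (level <= 0 || level >= 1) rlang::abort("level must lie in (0, 1)")
  a <- (1 - level) / 2
  tibble::tibble(lower = stats::qbeta(a, state$alpha, state$beta),
                 upper = stats::qbeta(1 - a, state$alpha, state$beta),
                 level = level)
}

#' Prior-sensitivity analysis for the beta-binomial monitor
#'
#' Recomputes the posterior mean, credible interval and predictive probability
#' of reaching the goal under each prior in a grid, and summarises how far the
#' posterior means diverge. When the maximum pairwise divergence exceeds
#' `tolerance`, the analysis is flagged prior-dominated: the data cannot yet
#' overcome the choice of prior.
#'
#' @param priors A data frame with columns `alpha` and `beta`, one prior per
#'   row (include the uniform Beta(1, 1)).
#' @inheritParams prob_goal
#' @param level Credible-interval coverage.
#' @param tolerance Divergence (in posterior-mean units) above which the
#'   result is flagged prior-dominated.
#' @return A tibble with one row per prior (`alpha`, `beta`, `post_mean`,
#'   `lower`, `upper`, `prob_goal`) carrying attributes `divergence` and
#'   `prior_dominated`.
#' @export
prior_sensitivity <- function(priors, N, n, s, goal, level = 0.95,
                              tolerance = 0.05) {
  priors <- tibble::as_tibble(priors)
  if (nrow(priors) == 0 || !all(c("alpha", "beta") %in% names(priors))) {
    rlang::abort("priors must be a nonempty data frame with columns alpha, beta")
  }
  check_trial(N, n, s)
  rows <- purrr::pmap(priors, function(alpha, beta, ...) {
    prior <- beta_state(alpha, beta)
    post <- posterior_update(prior, s, n - s)
    ci <- credible_interval(post, level)
    tibble::tibble(
      alpha = alpha, beta = beta,
      post_mean = post$alpha / (post$alpha + post$beta),
      lower = ci$lower, upper = ci$upper,
      prob_goal = prob_goal(prior, N, n, s, goal)
    )
  })
  out <- dplyr::bind_rows(rows)
  divergence <- max(out$post_mean) - min(out$post_mean)
  attr(out, "divergence") <- divergence
  attr(out, "prior_dominated") <- divergence > tolerance
  out
}

#' Plot a beta-binomial predictive distribution
#'
#' @param object A tibble from [predictive_pmf()].
#' @param ... Unused.
#' @return A ggplot bar chart of the predictive mass.
#' @export
plot_predictive <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Future differentiated cells t",
                  y = "Predictive probability") +
    ggplot2::theme_minimal()
}
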
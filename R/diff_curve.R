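#' Fit a logistic curve to cumulative differentiation counts
#'
#' Models the proportion of cells differentiated by day `t` as
#' `p(t) = L / (1 + exp(-k (t - t0)))`: a lag phase while inductive signals
#' accumulate, a growth phase, and a plateau `L` below 1 when a residual
#' subpopulation never differentiates. The inflection day `t0` is the peak
#' differentiation day (maximal slope), and the implied spread of commitment
#' times is `sd_days = pi / (k * sqrt(3))`, the standard deviation of the
#' logistic distribution whose CDF the curve traces.
#'
#' @param counts A data frame with columns `time_days`, `n_assayed`,
#'   `n_differentiated` (replicate rows may repeat a time point).
#' @param method `"ls"` for least squares on proportions (default) or
#'   `"binomial"` for maximum likelihood under a binomial count model.
#' @return An object of class `diff_logistic` with elements `L`, `k`, `t0`,
#'   `peak_day`, `sd_days`, `rss`, `method` and the fitting data;
#'   see [tidy.diff_logistic()] and [autoplot.diff_logistic()].
#' @examples
#' tt <- 0:10
#' counts <- tibble::tibble(
#'   time_days = tt, n_assayed = 500,
#'   n_differentiated = round(500 * 0.9 / (1 + exp(-1.2 * (tt - 5))))
#' )
#' fit <- fit_logistic(counts)
#' glance(fit)
#' @export
fit_logistic <- function(counts, method = c("ls", "binomial")) {
  method <- match.arg(method)
  counts <- tibble::as_tibble(counts)
  req <- c("time_days", "n_assayed", "n_differentiated")
  if (!all(req %in% names(counts))) {
    rlang::abort(paste("counts needs columns:", paste(req, collapse = ", ")))
  }
  if (any(counts$n_differentiated < 0 | counts$n_differentiated > counts$n_assayed)) {
    rlang::abort("n_differentiated must lie in [0, n_assayed]")
  }
  if (length(unique(counts$time_days)) < 4) {
    rlang::abort("need at least 4 distinct time points")
  }
  if (all(counts$n_differentiated == 0)) {
    rlang::abort("all differentiated counts are zero; nothing to fit")
  }

  dat <- dplyr::mutate(counts, prop = .data$n_differentiated / .data$n_assayed)
  byt <- dplyr::summarise(dplyr::group_by(dat, .data$time_days),
                          prop = mean(.data$prop), .groups = "drop")
  byt <- dplyr::arrange(byt, .data$time_days)

  dp <- diff(byt$prop) / diff(byt$time_days)
  i <- which.max(dp)
  t0_init <- mean(byt$time_days[c(i, i + 1)])
  L_init <- min(max(byt$prop), 1)
  k_init <- max(4 * max(dp) / L_init, 1e-3)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      prop ~ L / (1 + exp(-k * (time_days - t0))),
      data = dat,
      start = list(L = L_init, k = k_init, t0 = t0_init),
      lower = c(L = 1e-9, k = 1e-9, t0 = min(dat$time_days) - diff(range(dat$time_days))),
      upper = c(L = 1, k = Inf, t0 = max(dat$time_days) + diff(range(dat$time_days))),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) rlang::abort(paste("logistic fit failed:", conditionMessage(e)))
  )
  est <- as.list(stats::coef(fit))

  if (method == "binomial") {
    nll <- function(par) {
      L <- stats::plogis(par[1]); k <- exp(par[2]); t0 <- par[3]
      p <- pmin(pmax(L / (1 + exp(-k * (dat$time_days - t0))), 1e-12), 1 - 1e-12)
      -sum(stats::dbinom(dat$n_differentiated, dat$n_assayed, p, log = TRUE))
    }
    opt <- stats::optim(
      c(stats::qlogis(min(max(est$L, 1e-6), 1 - 1e-6)), log(est$k), est$t0),
      nll, method = "BFGS", control = list(maxit = 1000, reltol = 1e-12)
    )
    est <- list(L = stats::plogis(opt$par[1]), k = exp(opt$par[2]), t0 = opt$par[3])
  }

  pred <- est$L / (1 + exp(-est$k * (dat$time_days - est$t0)))
  structure(
    list(L = unname(est$L), k = unname(est$k), t0 = unname(est$t0),
         peak_day = unname(est$t0),
         sd_days = pi / (unname(est$k) * sqrt(3)),
         rss = sum((dat$prop - pred)^2),
         method = method, data = dat),
    class = "diff_logistic"
  )
}

#' @export
print.diff_logistic <- function(x, ...) {
  cat("Logistic differentiation curve fit (", x$method, ")\n", sep = "")
  cat(sprintf("  plateau L = %.4f, rate k = %.4f /day, inflection t0 = %.3f d\n",
              x$L, x$k, x$t0))
  cat(sprintf("  peak day = %.3f, implied commitment SD = %.3f d, RSS = %.3g\n",
              x$peak_day, x$sd_days, x$rss))
  invisible(x)
}

#' Tidiers for differentiation-curve fits
#'
#' @param x A `diff_logistic` or `peak_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per parameter; `glance()` a one-row
#'   model summary.
#' @method tidy diff_logistic
#' @export
tidy.diff_logistic <- function(x, ...) {
  tibble::tibble(term = c("L", "k", "t0"),
                 estimate = c(x$L, x$k, x$t0))
}

#' @rdname tidy.diff_logistic
#' @method glance diff_logistic
#' @export
glance.diff_logistic <- function(x, ...) {
  tibble::tibble(L = x$L, k = x$k, t0 = x$t0, peak_day = x$peak_day,
                 sd_days = x$sd_days, rss = x$rss, nobs = nrow(x$data),
                 method = x$method)
}

#' Plot a fitted logistic differentiation curve
#'
#' @param object A `diff_logistic` fit.
#' @param ... Unused.
#' @return A ggplot of observed proportions and the fitted curve.
#' @method autoplot diff_logistic
#' @export
autoplot.diff_logistic <- function(object, ...) {
  grid <- tibble::tibble(
    time_days = seq(min(object$data$time_days), max(object$data$time_days),
                    length.out = 200)
  )
  grid$prop <- object$L / (1 + exp(-object$k * (grid$time_days - object$t0)))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_days, .data$prop)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$t0, linetype = "dashed") +
    ggplot2::labs(x = "Day of differentiation", y = "Proportion differentiated",
                  title = sprintf("Logistic fit: peak day %.2f, SD %.2f d",
                                  object$peak_day, object$sd_days)) +
    ggplot2::theme_minimal()
}

#' Fit a Gaussian rate curve to newly differentiated counts
#'
#' Estimates the peak commitment day and its spread for one fate by fitting a
#' scaled Gaussian `a * exp(-(t - mean)^2 / (2 sd^2))` to per-day counts of
#' newly differentiated cells. When the counts are a single spike the SD is
#' floored at half the sampling interval and flagged.
#'
#' @param counts A data frame with columns `time_days` and `n_new` (newly
#'   differentiated cells per day; replicate rows may repeat a time point).
#' @param fate Optional fate label carried into the result.
#' @param sd_floor Lower bound for the SD in the degenerate case; defaults to
#'   half the smallest spacing of the time grid.
#' @return An object of class `peak_fit` with `mean_day`, `sd_days`,
#'   `amplitude`, `rss`, `sd_floored`, `fate` and the fitting data.
#' @examples
#' tt <- seq(0, 12, 0.5)
#' fit <- fit_peak(tibble::tibble(time_days = tt,
#'                                n_new = 100 * exp(-(tt - 6)^2 / 18)))
#' c(fit$mean_day, fit$sd_days)
#' @export
fit_peak <- function(counts, fate = NULL, sd_floor = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("time_days", "n_new") %in% names(counts))) {
    rlang::abort("counts needs columns time_days and n_new")
  }
  times <- sort(unique(counts$time_days))
  if (length(times) < 3 && sum(counts$n_new > 0) > 1) {
    rlang::abort("need at least 3 distinct time points")
  }
  if (is.null(sd_floor)) {
    sd_floor <- if (length(times) > 1) min(diff(times)) / 2 else 0.5
  }

  pos <- counts$n_new > 0
  if (sum(tapply(counts$n_new, counts$time_days, sum) > 0) <= 1) {
    if (!any(pos)) rlang::abort("all counts are zero; nothing to fit")
    day <- unique(counts$time_days[pos])
    return(structure(
      list(mean_day = day, sd_days = sd_floor,
           amplitude = max(counts$n_new), rss = 0, sd_floored = TRUE,
           fate = fate, data = counts,
           n_replicates = NA_integer_),
      class = "peak_fit"
    ))
  }

  w <- pmax(counts$n_new, 0)
  mu0 <- stats::weighted.mean(counts$time_days, w)
  sig0 <- max(sqrt(stats::weighted.mean((counts$time_days - mu0)^2, w)), sd_floor)
  a0 <- max(counts$n_new)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      n_new ~ a * exp(-(time_days - mu)^2 / (2 * sigma^2)),
      data = counts,
      start = list(a = a0, mu = min(max(mu0, min(times)), max(times)),
                   sigma = min(sig0, diff(range(times)))),
      lower = c(a = 0, mu = min(times) - min(diff(times)), sigma = 1e-6),
      upper = c(a = Inf, mu = max(times) + min(diff(times)),
                sigma = diff(range(times))),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) rlang::abort(paste("peak fit failed:", conditionMessage(e)))
  )
  est <- as.list(stats::coef(fit))
  sd_days <- abs(est$sigma)
  floored <- sd_days < sd_floor
  if (floored) sd_days <- sd_floor
  pred <- est$a * exp(-(counts$time_days - est$mu)^2 / (2 * est$sigma^2))
  structure(
    list(mean_day = unname(est$mu), sd_days = sd_days,
         amplitude = unname(est$a),
         rss = sum((counts$n_new - pred)^2), sd_floored = floored,
         fate = fate, data = counts,
         n_replicates = if ("replicate" %in% names(counts))
           length(unique(counts$replicate)) else NA_integer_),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("Gaussian differentiation-rate fit",
      if (!is.null(x$fate)) paste0(" (", x$fate, ")"), "\n", sep = "")
  cat(sprintf("  peak day = %.3f, SD = %.3f d%s\n", x$mean_day, x$sd_days,
              if (isTRUE(x$sd_floored)) " [floored]" else ""))
  invisible(x)
}

#' @rdname tidy.diff_logistic
#' @method tidy peak_fit
#' @export
tidy.peak_fit <- function(x, ...) {
  tibble::tibble(term = c("mean_day", "sd_days", "amplitude"),
                 estimate = c(x$mean_day, x$sd_days, x$amplitude))
}

#' @rdname tidy.diff_logistic
#' @method glance peak_fit
#' @export
glance.peak_fit <- function(x, ...) {
  tibble::tibble(mean_day = x$mean_day, sd_days = x$sd_days,
                 amplitude = x$amplitude, rss = x$rss,
                 sd_floored = x$sd_floored,
                 fate = if (is.null(x$fate)) NA_character_ else x$fate)
}
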
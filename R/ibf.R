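#' Build a sampling window around a peak estimate
#'
#' Constructs the analysis schedule for one IBF iteration: a uniform grid of
#' assay days from `mean_day - sd_days` to `mean_day + sd_days + 1`, at the
#' requested spacing. The one-day upper extension reproduces the worked
#' schedule for a predicted mean of day 5 with SD 2 days, which runs day 3
#' through day 8 at 24-hour intervals. Windows reaching outside the culture
#' horizon are clipped with a warning.
#'
#' @param mean_day Current peak-day estimate (days).
#' @param sd_days Current SD of the peak-day estimate (days, >= 0).
#' @param interval Grid spacing in days (1 for 24-hour, 0.5 for 12-hour).
#' @param replicates Replicate assays per day in this window.
#' @param horizon Optional culture horizon; times are clipped to \[0, horizon\].
#' @return An object of class `design_window`: a list with `times`,
#'   `interval`, `replicates`.
#' @examples
#' make_window(5, 2, interval = 1)$times    # days 3,4,5,6,7,8
#' make_window(6, 3, interval = 0.5)$times  # 15 half-day points
#' @export
make_window <- function(mean_day, sd_days, interval = 1, replicates = 3,
                        horizon = NULL) {
  if (sd_days < 0) rlang::abort("sd_days must be non-negative")
  if (interval <= 0) rlang::abort("interval must be positive")
  if (replicates < 1) rlang::abort("replicates must be at least 1")
  lo <- mean_day - sd_days
  hi <- mean_day + sd_days + 1
  times <- seq(lo, hi + 1e-9, by = interval)
  if (!is.null(horizon)) {
    clipped <- times[times >= 0 & times <= horizon]
    if (length(clipped) < length(times)) {
      rlang::warn(sprintf(
        "window [%g, %g] clipped to the culture horizon [0, %g]",
        lo, hi, horizon))
    }
    times <- clipped
  }
  if (length(times) == 0) rlang::abort("window contains no usable time points")
  structure(list(times = times, interval = interval, replicates = replicates),
            class = "design_window")
}

#' @export
print.design_window <- function(x, ...) {
  cat(sprintf("Sampling window: %d days at %g-hour intervals, %d replicates\n",
              length(x$times), x$interval * 24, x$replicates))
  cat("  days:", paste(format(x$times), collapse = ", "), "\n")
  invisible(x)
}

#' Closed-loop assay source for a simulated population
#'
#' Returns a function that, given a [make_window()] schedule and a fate,
#' measures per-day newly differentiated counts on the simulated population.
#' Each replicate is an independently seeded subculture (cohort) of
#' `sample_size` cells drawn from the population when the window opens; the
#' cohort's fate composition is read out (with fresh per-marker flip noise)
#' at every bin boundary `t - interval/2`, `t + interval/2` of the window
#' days. The count assigned to analysis day `t` is the increment of the
#' cohort's viable fate-classified fraction over the centred bin, scaled to
#' cells, so cumulative death does not deflate later bins. Each call
#' advances an internal counter so repeated iterations draw fresh,
#' reproducible cohorts.
#'
#' @param cells A truth table from [simulate_population()].
#' @param sample_size Cells per replicate cohort.
#' @param flip_noise Per-marker flip probability applied at each readout.
#' @param seed Base seed; call `i` of the source uses `seed + i`.
#' @param horizon Culture horizon in days.
#' @return A function `f(window, fate)` returning a tibble with columns
#'   `time_days`, `replicate`, `n_new`.
#' @export
population_assay_source <- function(cells, sample_size = 500,
                                    flip_noise = 0.02, seed = 1L,
                                    horizon = 10) {
  calls <- 0L
  function(window, fate) {
    stopifnot(inherits(window, "design_window"))
    calls <<- calls + 1L
    set.seed(seed + calls)
    half <- window$interval / 2
    # consecutive bins share an edge exactly: K+1 boundaries for K days
    k <- length(window$times)
    bounds <- pmin(pmax(c(window$times - half, window$times[k] + half), 0),
                   horizon)
    n <- nrow(cells)
    if (sample_size > n) {
      rlang::abort("sample_size exceeds the population size")
    }
    ev <- purrr::map_dfr(seq_len(window$replicates), function(r) {
      cohort <- cells[sample.int(n, sample_size), ]
      purrr::map_dfr(unique(bounds), function(b) {
        st <- marker_state(cohort, b, on_dead = "freeze")
        mk <- as.matrix(st[marker_names()])
        if (flip_noise > 0) {
          flips <- matrix(stats::rbinom(length(mk), 1, flip_noise), nrow(mk))
          mk <- abs(mk - flips)
        }
        dplyr::bind_cols(
          tibble::tibble(cell_id = st$cell_id, time_days = b, replicate = r,
                         condition = cohort$condition,
                         viability = ifelse(st$alive, "alive", "dead")),
          tibble::as_tibble(mk)
        )
      })
    })
    counts <- daily_counts(ev, fate = fate)
    purrr::map_dfr(seq_len(k), function(i) {
      a <- dplyr::arrange(counts[counts$time_days == bounds[i], ],
                          .data$replicate)
      b <- dplyr::arrange(counts[counts$time_days == bounds[i + 1], ],
                          .data$replicate)
      tibble::tibble(time_days = window$times[i], replicate = a$replicate,
                     n_new = sample_size *
                       (b$n_differentiated / b$n_assayed -
                          a$n_differentiated / a$n_assayed))
    })
  }
}

#' Run one IBF iteration over a sampling window
#'
#' Summarises replicated newly-differentiated counts over a window: per-day
#' mean and SD across replicates, the selected peak day (maximal mean count;
#' ties broken by minimal SD, then by the earlier day), and the SD of the
#' peak from a Gaussian-rate fit to the per-day mean counts.
#'
#' @param window A [make_window()] schedule.
#' @param counts A tibble with columns `time_days`, `replicate`, `n_new`
#'   covering every (window day, replicate) pair.
#' @param fate Optional fate label carried through.
#' @return An object of class `ibf_iteration`: list with `summary` (per-day
#'   tibble), `selected_day` (argmax day), `mean_day` (the iteration's peak
#'   estimate: the Gaussian-fit mean, or the argmax day if the fit leaves the
#'   window), `selected_sd`, `peak_fit`, `window`, `fate`.
#' @export
run_iteration <- function(window, counts, fate = NULL) {
  stopifnot(inherits(window, "design_window"))
  counts <- tibble::as_tibble(counts)
  if (!all(c("time_days", "replicate", "n_new") %in% names(counts))) {
    rlang::abort("counts needs columns time_days, replicate, n_new")
  }
  have <- unique(counts[c("time_days", "replicate")])
  want <- tidyr::expand_grid(time_days = window$times,
                             replicate = seq_len(window$replicates))
  gaps <- dplyr::anti_join(want, have, by = c("time_days", "replicate"))
  if (nrow(gaps) > 0) {
    rlang::abort(paste0(
      "missing counts for (day, replicate): ",
      paste(sprintf("(%g, %d)", gaps$time_days, gaps$replicate),
            collapse = ", ")))
  }

  smry <- dplyr::summarise(
    dplyr::group_by(counts, .data$time_days),
    mean_count = mean(.data$n_new),
    sd_count = stats::sd(.data$n_new),
    .groups = "drop"
  )
  smry <- dplyr::arrange(smry, .data$time_days)
  ord <- order(-smry$mean_count, smry$sd_count, smry$time_days)
  selected_day <- smry$time_days[ord[1]]

  pk <- fit_peak(
    tibble::tibble(time_days = smry$time_days, n_new = smry$mean_count),
    fate = fate
  )
  # the fitted peak uses every window day and is the stabler location
  # estimate; fall back to the argmax day if the fit drifts off the window
  mean_day <- if (pk$mean_day >= min(window$times) &&
                  pk$mean_day <= max(window$times)) {
    pk$mean_day
  } else {
    selected_day
  }
  structure(
    list(summary = smry, selected_day = selected_day,
         mean_day = mean_day,
         selected_sd = pk$sd_days, peak_fit = pk,
         window = window, fate = fate, counts = counts),
    class = "ibf_iteration"
  )
}

#' @export
print.ibf_iteration <- function(x, ...) {
  cat(sprintf("IBF iteration (%g-hour interval, %d replicates)\n",
              x$window$interval * 24, x$window$replicates))
  cat(sprintf("  selected day %.2f, peak SD %.3f d\n",
              x$selected_day, x$selected_sd))
  invisible(x)
}

#' Run the two-iteration iterative Bayesian framework
#'
#' Starting from an initial peak estimate (from a Step-1 curve fit or prior
#' knowledge), runs the adaptive sampling loop: iteration 1 assays a
#' mean +/- SD window at 24-hour intervals with 3 replicates; iteration 2
#' narrows to 12-hour intervals with 5 replicates around the updated
#' estimate. Each iteration's peak estimate (see [run_iteration()]) replaces
#' the predicted mean for the next, and the iteration-2 estimate is the final
#' prediction.
#' Finer-than-12-hour resolution is deliberately not pursued: spontaneous
#' background differentiation makes the system too variable to resolve over
#' smaller increments.
#'
#' @param mean_day,sd_days Initial peak-day estimate and SD in days.
#' @param assay_source A function `f(window, fate)` returning per-(day,
#'   replicate) `n_new` counts; see [population_assay_source()].
#' @param fate Fate whose peak is being located.
#' @param schedule A data frame with columns `interval` (days) and
#'   `replicates`, one row per iteration; the default is the two-iteration
#'   24-hour/12-hour design.
#' @param horizon Culture horizon; windows are clipped to it.
#' @return An object of class `ibf_run`: `estimate` (a one-row tibble with
#'   `fate`, `mean_day`, `sd_days`, `n_replicates`) plus the full audit trail
#'   in `iterations` and `initial`.
#' @examples
#' cells <- simulate_population(population_config(n_cells = 2000, seed = 11))
#' src <- population_assay_source(cells, sample_size = 300, flip_noise = 0,
#'                                seed = 99)
#' run <- run_ibf(mean_day = 3, sd_days = 1, assay_source = src,
#'                fate = "endoderm")
#' glance(run)
#' @export
run_ibf <- function(mean_day, sd_days, assay_source, fate,
                    schedule = tibble::tibble(interval = c(1, 0.5),
                                              replicates = c(3L, 5L)),
                    horizon = 10) {
  schedule <- tibble::as_tibble(schedule)
  if (!all(c("interval", "replicates") %in% names(schedule)) ||
      nrow(schedule) == 0) {
    rlang::abort("schedule needs columns interval and replicates")
  }
  cur_mean <- mean_day
  cur_sd <- sd_days
  half_width <- Inf
  iterations <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    # cap the half-width so successive windows never widen
    use_sd <- min(cur_sd, half_width)
    win <- make_window(cur_mean, use_sd, interval = schedule$interval[i],
                       replicates = schedule$replicates[i], horizon = horizon)
    counts <- assay_source(win, fate)
    it <- run_iteration(win, counts, fate = fate)
    iterations[[i]] <- it
    cur_mean <- it$mean_day
    cur_sd <- it$selected_sd
    half_width <- use_sd
  }
  last <- iterations[[length(iterations)]]
  structure(
    list(
      estimate = tibble::tibble(
        fate = fate,
        mean_day = last$mean_day,
        sd_days = last$selected_sd,
        n_replicates = last$window$replicates
      ),
      initial = tibble::tibble(mean_day = mean_day, sd_days = sd_days),
      iterations = iterations,
      schedule = schedule
    ),
    class = "ibf_run"
  )
}

#' Closed-loop IBF pipeline on a simulated population
#'
#' Convenience wrapper running the whole study design against one simulated
#' population: (Step 1) daily assays over the culture horizon, a logistic fit
#' of the cumulative counts for the fate of interest giving the starting
#' peak-day estimate and SD; (Step 2) the two-iteration [run_ibf()] loop with
#' fresh window assays. All randomness derives from `config$seed`.
#'
#' @param config A [population_config()].
#' @param fate Fate whose peak is being located.
#' @param sample_size Cells sampled per assay and replicate.
#' @param step1_replicates Replicates for the daily Step-1 assays.
#' @param schedule Iteration schedule passed to [run_ibf()].
#' @return An `ibf_run` (see [run_ibf()]) with the Step-1 `diff_logistic` fit
#'   attached as `$step1`.
#' @examples
#' run <- ibf_pipeline(population_config(n_cells = 2000, seed = 5),
#'                     fate = "endoderm", sample_size = 300)
#' glance(run)
#' @export
ibf_pipeline <- function(config, fate, sample_size = 500,
                         step1_replicates = 3,
                         schedule = tibble::tibble(interval = c(1, 0.5),
                                                   replicates = c(3L, 5L))) {
  stopifnot(inherits(config, "population_config"))
  cells <- simulate_population(config)
  h <- config$horizon_days
  events <- assay_population(cells, times = seq(0, h, by = 1),
                             replicates = step1_replicates,
                             sample_size = sample_size,
                             flip_noise = config$flip_noise,
                             seed = config$seed + 1L)
  step1 <- fit_logistic(daily_counts(events, fate = fate))
  src <- population_assay_source(cells, sample_size = sample_size,
                                 flip_noise = config$flip_noise,
                                 seed = config$seed + 1000L, horizon = h)
  run <- run_ibf(step1$peak_day, step1$sd_days, src, fate,
                 schedule = schedule, horizon = h)
  run$step1 <- step1
  run
}

#' @export
print.ibf_run <- function(x, ...) {
  cat(sprintf("IBF run (%d iteration(s)) for fate '%s'\n",
              length(x$iterations), x$estimate$fate))
  cat(sprintf("  initial estimate: day %.2f (SD %.2f)\n",
              x$initial$mean_day, x$initial$sd_days))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf(
      "  iteration %d: %g-h grid, %d reps -> day %.2f (SD %.3f; argmax day %g)\n",
      i, it$window$interval * 24, it$window$replicates,
      it$mean_day, it$selected_sd, it$selected_day))
  }
  cat(sprintf("  final prediction: day %.2f (SD %.3f)\n",
              x$estimate$mean_day, x$estimate$sd_days))
  invisible(x)
}

#' Tidiers for IBF runs
#'
#' @param x An `ibf_run`.
#' @param ... Unused.
#' @return `tidy()` gives one row per iteration (window span, interval,
#'   replicates, selected day and SD); `glance()` the final one-row estimate.
#' @method tidy ibf_run
#' @export
tidy.ibf_run <- function(x, ...) {
  purrr::imap_dfr(x$iterations, function(it, i) {
    tibble::tibble(
      iteration = i,
      interval = it$window$interval,
      replicates = it$window$replicates,
      window_start = min(it$window$times),
      window_end = max(it$window$times),
      selected_day = it$selected_day,
      selected_sd = it$selected_sd
    )
  })
}

#' @rdname tidy.ibf_run
#' @method glance ibf_run
#' @export
glance.ibf_run <- function(x, ...) {
  x$estimate
}

#' Plot the audit trail of an IBF run
#'
#' Shows per-day mean newly-differentiated counts (with replicate SD ribbons)
#' for each iteration, and the selected peak day.
#'
#' @param object An `ibf_run`.
#' @param ... Unused.
#' @return A ggplot faceted by iteration.
#' @method autoplot ibf_run
#' @export
autoplot.ibf_run <- function(object, ...) {
  dat <- purrr::imap_dfr(object$iterations, function(it, i) {
    dplyr::mutate(it$summary, iteration = paste0(
      "iteration ", i, " (", it$window$interval * 24, " h)"))
  })
  sel <- tidy(object)
  sel$iteration <- paste0("iteration ", sel$iteration, " (",
                          sel$interval * 24, " h)")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_days, .data$mean_count)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_count - .data$sd_count,
      ymax = .data$mean_count + .data$sd_count), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = sel,
                        ggplot2::aes(xintercept = .data$selected_day),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~iteration, scales = "free") +
    ggplot2::labs(x = "Day of differentiation",
                  y = "Newly differentiated cells (mean over replicates)") +
    ggplot2::theme_minimal()
}
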
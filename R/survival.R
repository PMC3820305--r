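#' Derive time-to-commitment survival records from a simulated population
#'
#' Converts the cell-level truth table into one record per cell for
#' competing-risks analysis of neuroectodermal commitment: the event of
#' interest is the first expression of Sox3-promoter GFP (the neuroectoderm
#' transition); competing events are death (PI+) and terminal differentiation
#' into a non-neural fate; cells with no event by the horizon are
#' administratively censored.
#'
#' @param cells A truth table from [simulate_population()].
#' @param horizon Censoring time in days.
#' @return A tibble with `subject_id`, `time`, `event` (one of
#'   `neuroectoderm_commit`, `death`, `other_fate`, `censored`) and `group`
#'   (the simulation condition).
#' @export
as_survival_records <- function(cells, horizon = 10) {
  fate <- as.character(cells$true_fate)
  event_day <- ifelse(fate == "neuroectoderm", cells$gfp_onset_day,
                      cells$commitment_day)
  event_type <- ifelse(fate == "neuroectoderm", "neuroectoderm_commit",
                       ifelse(fate == "undifferentiated", NA, "other_fate"))
  death <- cells$death_day

  time <- pmin(event_day, death, horizon, na.rm = TRUE)
  event <- rep("censored", nrow(cells))
  has_event <- !is.na(event_day) & event_day <= horizon &
    (is.na(death) | event_day <= death)
  event[has_event] <- event_type[has_event]
  died_first <- !is.na(death) & death <= horizon &
    (is.na(event_day) | death < event_day)
  event[died_first] <- "death"

  tibble::tibble(
    subject_id = cells$cell_id,
    time = time,
    event = factor(event, levels = c("censored", "neuroectoderm_commit",
                                     "death", "other_fate")),
    group = cells$condition
  )
}

check_records <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) rlang::abort("records is empty")
  if (!all(c("time", "event") %in% names(records))) {
    rlang::abort("records needs columns time and event")
  }
  if (any(records$time < 0)) rlang::abort("times must be non-negative")
  records
}

#' Kaplan-Meier estimate of time to commitment
#'
#' Product-limit survival curve for one event of interest; all other event
#' types (competing events included) are treated as censoring at their time,
#' so the curve answers "how long until the fate of interest, among cells
#' still able to reach it".
#'
#' @param records Survival records (see [as_survival_records()]): columns
#'   `time`, `event`, optionally `group` (ignored here).
#' @param event_of_interest Event level counted as the event.
#' @return An object of class `km_estimate`: a tibble with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `std_err`.
#' @export
km_estimate <- function(records, event_of_interest = "neuroectoderm_commit") {
  records <- check_records(records)
  status <- as.integer(records$event == event_of_interest)
  sf <- survival::survfit(survival::Surv(records$time, status) ~ 1)
  out <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, survival = sf$surv, std_err = sf$std.err
  )
  class(out) <- c("km_estimate", class(out))
  attr(out, "event_of_interest") <- event_of_interest
  out
}

#' Cumulative incidence under competing risks
#'
#' Aalen-Johansen estimator of the cumulative incidence function (CIF) of
#' every competing event (neuroectodermal commitment, death, non-neural
#' differentiation). At any time the probability of still being event-free
#' plus the CIFs of all events sums to one.
#'
#' @inheritParams km_estimate
#' @return An object of class `cif_estimate`: a tibble with `time`, `n_risk`,
#'   `surviving` (probability of no event yet), and one `cif_<event>` column
#'   per observed competing event.
#' @export
cif_estimate <- function(records) {
  records <- check_records(records)
  ev <- droplevels(factor(records$event))
  # censoring must be the first level for multi-state survfit
  lev <- c("censored", setdiff(levels(ev), "censored"))
  ev <- factor(as.character(ev), levels = lev)
  sf <- survival::survfit(survival::Surv(records$time, ev) ~ 1)
  states <- sf$states
  p <- sf$pstate
  out <- tibble::tibble(time = sf$time, n_risk = unname(sf$n.risk[, 1]),
                        surviving = unname(p[, states == "(s0)"]))
  for (st in setdiff(states, "(s0)")) {
    out[[paste0("cif_", st)]] <- unname(p[, states == st])
  }
  class(out) <- c("cif_estimate", class(out))
  out
}

#' Compare commitment times between conditions
#'
#' Log-rank test on the event of interest (competing events censored) between
#' the groups in `records`, with median commitment times per group. Used to
#' contrast wild-type and STAT3-beta populations, where dominant-negative
#' STAT3 is expected to delay and reduce ectodermal/neuroectodermal
#' commitment.
#'
#' @inheritParams km_estimate
#' @return A one-row tibble: `chisq`, `df`, `p_value`, and one
#'   `median_<group>` column per group.
#' @export
compare_groups <- function(records, event_of_interest = "neuroectoderm_commit") {
  records <- check_records(records)
  if (!"group" %in% names(records)) rlang::abort("records needs a group column")
  groups <- unique(records$group)
  if (length(groups) < 2) rlang::abort("need at least two groups to compare")
  status <- as.integer(records$event == event_of_interest)
  sd <- survival::survdiff(
    survival::Surv(time, status) ~ group,
    data = data.frame(time = records$time, status = status,
                      group = records$group)
  )
  df <- length(sd$n) - 1
  out <- tibble::tibble(chisq = sd$chisq, df = df,
                        p_value = stats::pchisq(sd$chisq, df,
                                                lower.tail = FALSE))
  sf <- survival::survfit(
    survival::Surv(time, status) ~ group,
    data = data.frame(time = records$time, status = status,
                      group = records$group)
  )
  med <- summary(sf)$table[, "median"]
  names(med) <- sub("^group=", "median_", rownames(summary(sf)$table))
  for (nm in names(med)) out[[nm]] <- unname(med[nm])
  out
}

#' Plot survival and cumulative incidence curves
#'
#' @param object A `km_estimate` or `cif_estimate`.
#' @param ... Unused.
#' @return A ggplot of the step functions.
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days of differentiation",
                  y = "Probability not yet committed",
                  title = paste("Kaplan-Meier:",
                                attr(object, "event_of_interest"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_estimate
#' @method autoplot cif_estimate
#' @export
autoplot.cif_estimate <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::starts_with("cif_"),
    names_to = "event", values_to = "cif", names_prefix = "cif_"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$cif,
                                     colour = .data$event)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days of differentiation",
                  y = "Cumulative incidence") +
    ggplot2::theme_minimal()
}
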
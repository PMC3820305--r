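#' Configuration for the synthetic embryoid-body population
#'
#' Assembles and validates the parameters of the population simulator. The
#' defaults encode the working hypotheses for murine embryoid-body (EB)
#' differentiation over a 10-day culture: cumulative differentiation follows a
#' sigmoid (logistic-like) curve, per-lineage commitment days are unimodal with
#' endoderm peaking near day 3 and mesoderm/ectoderm near day 7, a small
#' residual Nanog+ subpopulation never differentiates by day 10, and a
#' dominant-negative STAT3 (STAT3-beta) condition reduces and delays
#' ectodermal commitment.
#'
#' @param n_cells Number of cells in the population.
#' @param horizon_days Length of the culture in days (time runs 0..horizon).
#' @param fate_fractions Named proportions over `endoderm`, `mesoderm`,
#'   `ectoderm` for differentiating cells; must sum to 1.
#' @param commitment_mean,commitment_sd Named per-fate mean and SD (days) of
#'   the commitment-day distribution (Normal, truncated to the horizon).
#' @param mesendoderm_lead Days a committing endoderm/mesoderm cell spends in
#'   the transitional Foxa2+ Noggin+ mesendoderm state before commitment.
#' @param neuro_fraction Fraction of ectodermal cells that progress onward to
#'   the Sox3-only neuroectoderm state.
#' @param neuro_lag Days between ectodermal (Ap-2alpha+ Sox3+) onset and the
#'   neuroectodermal transition for those cells.
#' @param residual_nanog_fraction Fraction of cells that remain Nanog+
#'   (undifferentiated) through the horizon.
#' @param flip_noise Default per-marker probability that an assay inverts a
#'   binary call (assay noise, not biology).
#' @param death_hazard Constant per-day death hazard (exponential waiting
#'   time); death is retained as a competing risk.
#' @param condition `"wt"` or `"stat3b"`.
#' @param stat3b_ecto_factor Multiplier (< 1) applied to the ectoderm fraction
#'   under `stat3b`; the displaced mass is reassigned proportionally to the
#'   other fates.
#' @param stat3b_ecto_delay Days added to the ectoderm commitment mean under
#'   `stat3b`.
#' @param seed Integer seed; a fixed seed makes the whole simulation
#'   reproducible.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_cells = 5000,
                              horizon_days = 10,
                              fate_fractions = c(endoderm = 1 / 3,
                                                 mesoderm = 1 / 3,
                                                 ectoderm = 1 / 3),
                              commitment_mean = c(endoderm = 3,
                                                  mesoderm = 7,
                                                  ectoderm = 7),
                              commitment_sd = c(endoderm = 1,
                                                mesoderm = 1,
                                                ectoderm = 1),
                              mesendoderm_lead = 1,
                              neuro_fraction = 0.25,
                              neuro_lag = 2,
                              residual_nanog_fraction = 0.05,
                              flip_noise = 0.02,
                              death_hazard = 0.01,
                              condition = c("wt", "stat3b"),
                              stat3b_ecto_factor = 0.5,
                              stat3b_ecto_delay = 1,
                              seed = 1L) {
  condition <- match.arg(condition)
  layers <- c("endoderm", "mesoderm", "ectoderm")
  if (!setequal(names(fate_fractions), layers)) {
    rlang::abort("fate_fractions must be named over endoderm, mesoderm, ectoderm")
  }
  fate_fractions <- fate_fractions[layers]
  if (any(fate_fractions < 0) || any(fate_fractions > 1) ||
      abs(sum(fate_fractions) - 1) > 1e-9) {
    rlang::abort("fate_fractions must lie in [0,1] and sum to 1")
  }
  if (any(commitment_sd[layers] < 0)) {
    rlang::abort("commitment_sd must be non-negative")
  }
  for (p in c(residual_nanog_fraction, flip_noise, neuro_fraction,
              stat3b_ecto_factor)) {
    if (p < 0 || p > 1) rlang::abort("proportions must lie in [0,1]")
  }
  if (death_hazard < 0) rlang::abort("death_hazard must be non-negative")
  structure(
    list(n_cells = as.integer(n_cells), horizon_days = horizon_days,
         fate_fractions = fate_fractions,
         commitment_mean = commitment_mean[layers],
         commitment_sd = commitment_sd[layers],
         mesendoderm_lead = mesendoderm_lead,
         neuro_fraction = neuro_fraction, neuro_lag = neuro_lag,
         residual_nanog_fraction = residual_nanog_fraction,
         flip_noise = flip_noise, death_hazard = death_hazard,
         condition = condition,
         stat3b_ecto_factor = stat3b_ecto_factor,
         stat3b_ecto_delay = stat3b_ecto_delay,
         seed = as.integer(seed)),
    class = "population_config"
  )
}

# Normal(mean, sd) truncated to [lo, hi] by quantile inversion so that a
# fixed RNG stream gives identical draws regardless of rejection behaviour.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- numeric(n)
  zero <- sd == 0
  out[zero] <- pmin(pmax(mean[zero], lo), hi)
  if (any(!zero)) {
    m <- mean[!zero]; s <- sd[!zero]
    plo <- stats::pnorm((lo - m) / s)
    phi <- stats::pnorm((hi - m) / s)
    u <- stats::runif(sum(!zero), plo, phi)
    out[!zero] <- m + s * stats::qnorm(u)
  }
  out
}

#' Simulate a differentiating embryoid-body population
#'
#' Draws one cell-level truth table under a [population_config()]: each cell is
#' assigned a fate (or remains a residual Nanog+ cell), a commitment day from a
#' truncated Normal, transitional-state entry days (mesendoderm for
#' endoderm/mesoderm, an ectodermal Ap-2alpha+ Sox3+ stage for
#' neuroectoderm-destined cells), an optional death day from a constant hazard,
#' and, for neuroectodermal cells, the Sox3-promoter GFP onset day. Under the
#' `stat3b` condition the ectoderm fraction is multiplied by
#' `stat3b_ecto_factor` (mass reassigned proportionally to the other fates)
#' and the ectoderm commitment mean is shifted by `stat3b_ecto_delay`.
#'
#' @param config A [population_config()].
#' @return A tibble with one row per cell: `cell_id`, `condition`, `true_fate`,
#'   `mesendoderm_entry_day`, `ectoderm_entry_day`, `commitment_day`,
#'   `gfp_onset_day`, `death_day`. Entry/commitment days are `NA` for residual
#'   undifferentiated cells; `gfp_onset_day` is defined only for
#'   neuroectodermal cells.
#' @examples
#' cells <- simulate_population(population_config(n_cells = 100, seed = 7))
#' dplyr::count(cells, true_fate)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_cells
  h <- config$horizon_days

  frac <- config$fate_fractions
  cmean <- config$commitment_mean
  if (config$condition == "stat3b") {
    displaced <- frac[["ectoderm"]] * (1 - config$stat3b_ecto_factor)
    frac[["ectoderm"]] <- frac[["ectoderm"]] * config$stat3b_ecto_factor
    other <- c("endoderm", "mesoderm")
    if (sum(frac[other]) > 0) {
      frac[other] <- frac[other] + displaced * frac[other] / sum(frac[other])
    } else {
      frac[["ectoderm"]] <- frac[["ectoderm"]] + displaced
    }
    cmean[["ectoderm"]] <- cmean[["ectoderm"]] + config$stat3b_ecto_delay
  }

  residual <- stats::runif(n) < config$residual_nanog_fraction
  layer <- sample(names(frac), n, replace = TRUE, prob = frac)
  layer[residual] <- NA_character_
  neuro <- !is.na(layer) & layer == "ectoderm" &
    stats::runif(n) < config$neuro_fraction

  commit <- rep(NA_real_, n)
  for (f in names(frac)) {
    idx <- which(!is.na(layer) & layer == f)
    if (length(idx) > 0) {
      commit[idx] <- rtruncnorm(length(idx), cmean[[f]],
                                config$commitment_sd[[f]], 0, h)
    }
  }

  true_fate <- ifelse(is.na(layer), "undifferentiated", layer)
  true_fate[neuro] <- "neuroectoderm"

  mesendo_entry <- ifelse(true_fate %in% c("endoderm", "mesoderm"),
                          pmax(commit - config$mesendoderm_lead, 0), NA_real_)
  ecto_entry <- ifelse(true_fate %in% c("ectoderm", "neuroectoderm"),
                       commit, NA_real_)
  # neuroectoderm commitment = Sox3-only transition, after the ectodermal stage
  commit[neuro] <- commit[neuro] + config$neuro_lag
  gfp_onset <- ifelse(true_fate == "neuroectoderm", commit, NA_real_)

  death <- if (config$death_hazard > 0) {
    d <- stats::rexp(n, rate = config$death_hazard)
    ifelse(d <= h, d, NA_real_)
  } else {
    rep(NA_real_, n)
  }

  tibble::tibble(
    cell_id = seq_len(n),
    condition = config$condition,
    true_fate = factor(true_fate, levels = fate_levels()),
    mesendoderm_entry_day = mesendo_entry,
    ectoderm_entry_day = ecto_entry,
    commitment_day = commit,
    gfp_onset_day = gfp_onset,
    death_day = death
  )
}

#' Noise-free marker state of cells at a time point
#'
#' Renders each cell's true binary marker profile at `time`: Nanog+ (all other
#' markers negative) before any transition; the canonical mesendoderm pattern
#' (Foxa2+ Noggin+) during the transitional window of endoderm/mesoderm cells;
#' the canonical committed pattern of the true fate afterwards (endoderm
#' Foxa2+ Hex+, mesoderm Noggin+ Tbx6+, ectoderm Ap-2alpha+ Sox3+,
#' neuroectoderm Sox3 only). Neuroectoderm-destined cells pass through the
#' ectodermal pattern before their Sox3-only transition. No assay noise is
#' applied here; see [assay_population()].
#'
#' @param cells A truth table from [simulate_population()].
#' @param time Time in days.
#' @param on_dead How to treat cells dead by `time`: `"freeze"` reports the
#'   marker state at the death day (antigens retained, PI+), `"error"` aborts.
#' @return A tibble with `cell_id`, `alive`, and the seven 0/1 marker columns.
#' @export
marker_state <- function(cells, time, on_dead = c("freeze", "error")) {
  on_dead <- match.arg(on_dead)
  dead <- !is.na(cells$death_day) & cells$death_day <= time
  if (on_dead == "error" && any(dead)) {
    rlang::abort(sprintf("%d cell(s) are dead at day %g", sum(dead), time))
  }
  t_eff <- rep(time, nrow(cells))
  t_eff[dead] <- cells$death_day[dead]

  n <- nrow(cells)
  m <- matrix(0L, nrow = n, ncol = 7,
              dimnames = list(NULL, marker_names()))
  fate <- as.character(cells$true_fate)
  # strict inequalities: at the instant of induction (day 0) every cell is
  # still Nanog+, even those whose entry day truncates to 0
  committed <- !is.na(cells$commitment_day) & t_eff > cells$commitment_day
  in_mesendo <- fate %in% c("endoderm", "mesoderm") & !committed &
    !is.na(cells$mesendoderm_entry_day) & t_eff > cells$mesendoderm_entry_day
  in_ecto_stage <- fate == "neuroectoderm" & !committed &
    !is.na(cells$ectoderm_entry_day) & t_eff > cells$ectoderm_entry_day

  pat <- fate_patterns()
  canonical <- pat[!duplicated(pat$fate), ]
  for (f in canonical$fate) {
    rows <- which(committed & fate == f)
    if (length(rows) > 0) {
      m[rows, setdiff(marker_names(), "nanog")] <-
        matrix(as.integer(canonical[canonical$fate == f,
                                    setdiff(marker_names(), "nanog")]),
               nrow = length(rows), ncol = 6, byrow = TRUE)
    }
  }
  m[in_mesendo, "foxa2"] <- 1L
  m[in_mesendo, "noggin"] <- 1L
  m[in_ecto_stage, "ap2a"] <- 1L
  m[in_ecto_stage, "sox3"] <- 1L
  pre <- !(committed | in_mesendo | in_ecto_stage)
  m[pre, "nanog"] <- 1L

  dplyr::bind_cols(
    tibble::tibble(cell_id = cells$cell_id, alive = !dead),
    tibble::as_tibble(m)
  )
}

#' Assay a population as a flow-cytometry-style event table
#'
#' For each requested time and replicate, samples `sample_size` cells without
#' replacement, records viability, and reports each sampled cell's marker
#' profile with independent per-marker flip noise (a call is inverted with
#' probability `flip_noise`). Dead cells are retained in the table with
#' `viability = "dead"` (the propidium-iodide analogue) and marker state
#' frozen at death.
#'
#' @param cells A truth table from [simulate_population()].
#' @param times Numeric vector of assay days.
#' @param replicates Number of independent replicate samples per time.
#' @param sample_size Cells sampled per time x replicate; must not exceed the
#'   number of cells alive at the assay time.
#' @param flip_noise Per-marker flip probability in \[0, 1\].
#' @param seed Optional integer seed for the sampling and noise draws.
#' @return An event-table tibble with columns `cell_id`, `time_days`,
#'   `replicate`, `condition`, `viability`, and the seven marker columns.
#' @examples
#' cells <- simulate_population(population_config(n_cells = 200, seed = 1))
#' ev <- assay_population(cells, times = c(3, 7), replicates = 2,
#'                        sample_size = 50, flip_noise = 0, seed = 2)
#' dplyr::count(classify_fate(ev), time_days, fate)
#' @export
assay_population <- function(cells, times, replicates = 3, sample_size,
                             flip_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (flip_noise < 0 || flip_noise > 1) {
    rlang::abort("flip_noise must lie in [0,1]")
  }
  n <- nrow(cells)
  out <- vector("list", length(times) * replicates)
  i <- 0L
  for (tm in times) {
    alive_n <- sum(is.na(cells$death_day) | cells$death_day > tm)
    if (sample_size > alive_n) {
      rlang::abort(sprintf(
        "sample_size (%d) exceeds cells alive at day %g (%d)",
        sample_size, tm, alive_n))
    }
    state <- marker_state(cells, tm, on_dead = "freeze")
    for (r in seq_len(replicates)) {
      idx <- sample.int(n, sample_size)
      st <- state[idx, ]
      mk <- as.matrix(st[marker_names()])
      if (flip_noise > 0) {
        flips <- matrix(stats::rbinom(length(mk), 1, flip_noise), nrow(mk))
        mk <- abs(mk - flips)
      }
      i <- i + 1L
      out[[i]] <- dplyr::bind_cols(
        tibble::tibble(
          cell_id = st$cell_id,
          time_days = tm,
          replicate = r,
          condition = cells$condition[idx],
          viability = ifelse(st$alive, "alive", "dead")
        ),
        tibble::as_tibble(mk)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Tabulate differentiated counts from an event table
#'
#' Summarises an event table into per-time, per-replicate counts suitable for
#' curve fitting: the number of viable cells assayed and, among them, the
#' number called differentiated (Nanog-) or, when `fate` is given, the number
#' classified into that fate. Dead cells are excluded from both numerator and
#' denominator (PI gating).
#'
#' @param events An event table (see [assay_population()] or
#'   [read_event_table()]).
#' @param fate Optional fate name from [fate_levels()]; when `NULL`, counts
#'   all differentiated (Nanog-) cells.
#' @param lineage If `TRUE` (default), a fate's count includes its derived
#'   states, so cells that progressed onward still count toward the layer
#'   they entered: ectoderm includes neuroectoderm (Sox3-only cells remain
#'   ectodermal derivatives) and mesendoderm includes endoderm and mesoderm.
#'   `FALSE` counts the exact classifier category only.
#' @return A tibble with `time_days`, `replicate`, `n_assayed`,
#'   `n_differentiated`.
#' @export
daily_counts <- function(events, fate = NULL, lineage = TRUE) {
  ev <- classify_fate(events)
  ev <- dplyr::filter(ev, .data$viability == "alive")
  if (is.null(fate)) {
    ev$hit <- ev$nanog == 0
  } else {
    fate <- match.arg(fate, fate_levels())
    wanted <- if (lineage) {
      switch(fate,
             ectoderm = c("ectoderm", "neuroectoderm"),
             mesendoderm = c("mesendoderm", "endoderm", "mesoderm"),
             fate)
    } else {
      fate
    }
    ev$hit <- as.character(ev$fate) %in% wanted
  }
  dplyr::summarise(
    dplyr::group_by(ev, .data$time_days, .data$replicate),
    n_assayed = dplyr::n(),
    n_differentiated = sum(.data$hit),
    .groups = "drop"
  )
}
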
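test_that("simulation conserves cells and is seed-reproducible", {
  cfg <- population_config(n_cells = 1000, seed = 11)
  cells <- simulate_population(cfg)
  expect_equal(nrow(cells), 1000L)
  expect_equal(sum(table(cells$true_fate)), 1000L)
  expect_identical(cells, simulate_population(cfg))
})

test_that("degenerate config commits every cell exactly at the mean day", {
  cfg <- population_config(
    n_cells = 200,
    fate_fractions = c(endoderm = 0, mesoderm = 0, ectoderm = 1),
    commitment_sd = c(endoderm = 0, mesoderm = 0, ectoderm = 0),
    residual_nanog_fraction = 0, neuro_fraction = 0, death_hazard = 0,
    seed = 3
  )
  cells <- simulate_population(cfg)
  expect_true(all(cells$true_fate == "ectoderm"))
  expect_true(all(cells$commitment_day == 7))
})

test_that("invalid configurations are rejected", {
  expect_error(population_config(fate_fractions = c(endoderm = 0.5,
                                                    mesoderm = 0.5,
                                                    ectoderm = 0.5)),
               "sum to 1")
  expect_error(population_config(commitment_sd = c(endoderm = -1,
                                                   mesoderm = 1,
                                                   ectoderm = 1)),
               "non-negative")
  expect_error(population_config(residual_nanog_fraction = 1.2), "0,1")
})

test_that("marker truth states follow the staged patterns", {
  cells <- fixture_population()
  at0 <- marker_state(cells, 0)
  undiff <- profile_row(nanog = 1)
  expect_true(all(at0$nanog[at0$alive] == 1))
  expect_true(all(as.matrix(at0[at0$alive, setdiff(marker_names(), "nanog")]) == 0))

  # a surviving endoderm cell after commitment shows Foxa2+ Hex+ only
  endo <- cells[cells$true_fate == "endoderm" & is.na(cells$death_day), ][1, ]
  st <- marker_state(endo, endo$commitment_day + 0.1)
  expect_equal(unlist(st[marker_names()]),
               c(nanog = 0L, foxa2 = 1L, hex = 1L, noggin = 0L,
                 tbx6 = 0L, ap2a = 0L, sox3 = 0L))

  # the same cell inside its transitional window shows Foxa2+ Noggin+
  mid <- (endo$mesendoderm_entry_day + endo$commitment_day) / 2
  if (endo$commitment_day > endo$mesendoderm_entry_day) {
    st2 <- marker_state(endo, mid)
    expect_equal(unlist(st2[marker_names()]),
                 c(nanog = 0L, foxa2 = 1L, hex = 0L, noggin = 1L,
                   tbx6 = 0L, ap2a = 0L, sox3 = 0L))
  }
})

test_that("noiseless assays recover true fates of committed cells", {
  cells <- fixture_population()
  ev <- assay_population(cells, times = 10, replicates = 1,
                         sample_size = sum(is.na(cells$death_day)),
                         flip_noise = 0, seed = 4)
  ev <- classify_fate(ev)
  ev <- ev[ev$viability == "alive", ]
  truth <- cells$true_fate[match(ev$cell_id, cells$cell_id)]
  committed <- !is.na(cells$commitment_day[match(ev$cell_id, cells$cell_id)]) &
    cells$commitment_day[match(ev$cell_id, cells$cell_id)] <= 10
  expect_true(all(as.character(ev$fate[committed]) ==
                    as.character(truth[committed])))
})

test_that("census assay samples every cell exactly once", {
  cfg <- population_config(n_cells = 300, death_hazard = 0, seed = 9)
  cells <- simulate_population(cfg)
  ev <- assay_population(cells, times = 5, replicates = 1,
                         sample_size = 300, flip_noise = 0, seed = 2)
  expect_equal(sort(ev$cell_id), 1:300)
  expect_error(
    assay_population(cells, times = 5, replicates = 1, sample_size = 301),
    "exceeds"
  )
})

test_that("flip noise inverts calls at the nominal binomial rate", {
  cfg <- population_config(
    n_cells = 4000, residual_nanog_fraction = 1, death_hazard = 0, seed = 21
  )
  cells <- simulate_population(cfg)      # everyone stays Nanog+
  ev <- assay_population(cells, times = 5, replicates = 1,
                         sample_size = 4000, flip_noise = 0.05, seed = 22)
  phat <- mean(ev$nanog == 0)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(phat - 0.05), 3 * se)
})

test_that("cumulative differentiation is monotone and plateaus below 1", {
  cells <- fixture_population()
  frac <- sapply(seq(0, 10, by = 0.5), function(t) {
    st <- marker_state(cells, t)
    mean(st$nanog[st$alive] == 0)
  })
  expect_true(all(diff(frac) >= 0))
  expect_lte(max(frac), 1 - 0)
  # plateau is bounded by 1 - residual fraction (0.05 by default)
  expect_lt(max(frac), 1)
  expect_gt(max(frac), 0.85)
})

test_that("STAT3-beta reduces and delays ectodermal commitment", {
  wt <- simulate_population(population_config(n_cells = 3000, seed = 5,
                                              condition = "wt"))
  mu <- simulate_population(population_config(n_cells = 3000, seed = 5,
                                              condition = "stat3b"))
  ecto_wt <- wt[wt$true_fate %in% c("ectoderm", "neuroectoderm"), ]
  ecto_mu <- mu[mu$true_fate %in% c("ectoderm", "neuroectoderm"), ]
  # halved fraction (binomial slack) and ~1 day later entry
  expect_lt(nrow(ecto_mu), 0.65 * nrow(ecto_wt))
  expect_gt(mean(ecto_mu$ectoderm_entry_day) - mean(ecto_wt$ectoderm_entry_day),
            0.5)
  # the mutant's commitment-time CDF is stochastically later
  qs <- seq(0.1, 0.9, 0.2)
  expect_true(all(stats::quantile(ecto_mu$ectoderm_entry_day, qs) >
                    stats::quantile(ecto_wt$ectoderm_entry_day, qs)))
})
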
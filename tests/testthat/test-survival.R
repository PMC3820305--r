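records <- function(time, event, group = "wt") {
  tibble::tibble(subject_id = seq_along(time), time = time,
                 event = event, group = group)
}

test_that("Kaplan-Meier matches a hand-computed product-limit table", {
  # 10 cells: events (e) and censorings (c) at
  # 1e 2c 3e 3e 4c 5e 6c 7e 8c 9c
  rec <- records(c(1, 2, 3, 3, 4, 5, 6, 7, 8, 9),
                 c("x", "censored", "x", "x", "censored", "x",
                   "censored", "x", "censored", "censored"))
  km <- km_estimate(rec, event_of_interest = "x")
  at <- function(t) km$survival[km$time == t]
  # S(1) = 9/10; S(3) = .9 * 6/8; S(5) = .675 * 4/5; S(7) = .54 * 2/3
  expect_equal(at(1), 0.9)
  expect_equal(at(3), 0.675)
  expect_equal(at(5), 0.54)
  expect_equal(at(7), 0.36, tolerance = 1e-12)
})

test_that("no events leaves survival at one; no censoring gives the ecdf", {
  none <- records(1:5, rep("censored", 5))
  expect_true(all(km_estimate(none, "x")$survival == 1))

  full <- records(1:6, rep("x", 6))
  km <- km_estimate(full, "x")
  expect_equal(km$survival, 1 - (1:6) / 6)
})

test_that("with one risk the CIF complements the KM curve", {
  rec <- records(c(1, 2, 3, 4, 5, 6), c("x", "x", "censored", "x",
                                        "censored", "x"))
  km <- km_estimate(rec, "x")
  cif <- cif_estimate(rec)
  expect_equal(cif$cif_x, 1 - km$survival[match(cif$time, km$time)],
               tolerance = 1e-12)
})

test_that("competing-risk CIFs conserve total probability", {
  # all die at t = 1: death CIF jumps to 1, nothing else moves
  dead <- records(rep(1, 5), rep("death", 5))
  cd <- cif_estimate(dead)
  expect_equal(cd$cif_death, 1)
  expect_equal(cd$surviving, 0)

  # three risks, no censoring: CIFs equal empirical incidence
  rec <- records(1:9, rep(c("commit", "death", "other"), 3))
  cif <- cif_estimate(rec)
  for (i in seq_len(nrow(cif))) {
    t <- cif$time[i]
    expect_equal(cif$cif_commit[i], sum(rec$time <= t & rec$event == "commit") / 9)
    expect_equal(cif$cif_death[i], sum(rec$time <= t & rec$event == "death") / 9)
    expect_equal(cif$cif_other[i], sum(rec$time <= t & rec$event == "other") / 9)
  }
  tot <- cif$surviving + cif$cif_commit + cif$cif_death + cif$cif_other
  expect_equal(tot, rep(1, nrow(cif)), tolerance = 1e-9)

  # conservation holds on simulated populations too
  sim <- as_survival_records(fixture_population())
  sc <- cif_estimate(sim)
  cifs <- as.matrix(sc[grep("^cif_", names(sc))])
  expect_equal(unname(sc$surviving + rowSums(cifs)),
               rep(1, nrow(sc)), tolerance = 1e-9)
})

test_that("group comparison matches the hand-computed log-rank statistic", {
  # identical groups: statistic is exactly zero
  g1 <- records(1:5, rep("x", 5), "wt")
  g2 <- records(1:5, rep("x", 5), "stat3b")
  same <- compare_groups(dplyr::bind_rows(g1, g2), "x")
  expect_equal(same$chisq, 0, tolerance = 1e-12)

  # one event time: A has 2/4 events, B 1/4.
  # O_A = 2, E_A = 3*4/8 = 1.5, V = 3*(4/8)*(4/8)*(8-3)/(8-1) = 15/28,
  # chisq = 0.25 / (15/28) = 7/15
  rec <- dplyr::bind_rows(
    records(c(1, 1, 5, 5), c("x", "x", "censored", "censored"), "A"),
    records(c(1, 5, 5, 5), c("x", "censored", "censored", "censored"), "B")
  )
  lr <- compare_groups(rec, "x")
  expect_equal(lr$chisq, 7 / 15, tolerance = 1e-9)
  expect_equal(lr$df, 1)

  expect_error(compare_groups(g1, "x"), "two groups")
})

test_that("survival records code the first event per cell", {
  cells <- fixture_population()
  rec <- as_survival_records(cells, horizon = 10)
  expect_equal(nrow(rec), nrow(cells))
  expect_true(all(rec$time >= 0 & rec$time <= 10))
  # residual undifferentiated cells never commit: censored or dead only
  res <- rec[cells$true_fate == "undifferentiated", ]
  expect_true(all(res$event %in% c("censored", "death")))
  # neuroectoderm events happen at the GFP onset day
  neu <- rec[rec$event == "neuroectoderm_commit", ]
  onset <- cells$gfp_onset_day[match(neu$subject_id, cells$cell_id)]
  expect_equal(neu$time, onset)
})

test_that("STAT3-beta commitment curves lag wild type", {
  wt <- simulate_population(population_config(n_cells = 3000, seed = 5,
                                              condition = "wt"))
  mu <- simulate_population(population_config(n_cells = 3000, seed = 6,
                                              condition = "stat3b"))
  rec <- dplyr::bind_rows(as_survival_records(wt), as_survival_records(mu))
  cmp <- compare_groups(rec)
  expect_gt(cmp$chisq, 10)
  # wild type accumulates neuroectoderm commitments faster
  cif_wt <- cif_estimate(as_survival_records(wt))
  cif_mu <- cif_estimate(as_survival_records(mu))
  expect_gt(max(cif_wt$cif_neuroectoderm_commit),
            max(cif_mu$cif_neuroectoderm_commit))
})
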
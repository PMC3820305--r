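# ibfstem

Iterative Bayesian framework (IBF) for stem cell differentiation time
courses.

When embryonic or induced pluripotent stem cells differentiate in embryoid
bodies, each germ layer has a day on which commitment is most probable — the
*peak differentiation day* — and knowing it is what lets a protocol designer
sort the purest population of a desired fate. `ibfstem` is for
stem-cell biologists and biostatisticians planning such time courses. It
provides:

* a **seven-marker fate classifier** (Nanog, Foxa2, Hex, Noggin, Tbx6,
  Ap-2α, Sox3) mapping binary flow-cytometry calls to undifferentiated /
  mesendoderm / endoderm / mesoderm / ectoderm / neuroectoderm;
* a **synthetic embryoid-body simulator** (logistic cumulative
  differentiation, per-fate commitment-day distributions, transitional
  states, assay flip noise, death as a competing risk, and a STAT3β
  condition with reduced/delayed ectoderm);
* **curve fitting**: the Step-1 logistic `p(t) = L / (1 + exp(−k(t − t₀)))`
  whose inflection `t₀` is the peak day, and a Gaussian-rate fit for
  per-fate peaks;
* the **beta-binomial predictive monitor**: with `s` successes in `n` of `N`
  cells and a Beta(α, β) prior,
  `p(t|s) = C(N−n, t) · B(α+s+t, β+n−s+N−n−t) / B(α+s, β+n−s)`,
  with conjugate updates `α* = s + t + α`, `β* = N − s − t + β`, sequential
  superiority/futility stopping, credible intervals and prior-sensitivity
  analysis;
* the **two-iteration adaptive design**: sample `mean ± SD (+1 d)` at
  24-hour intervals with 3 replicates, update, then 12-hour intervals with
  5 replicates — the iteration-2 estimate is the final prediction;
* **competing-risks survival analysis** of time to neuroectodermal
  commitment (Kaplan–Meier, Aalen–Johansen CIFs, log-rank wt vs STAT3β);
* a **pulmonary-nodule pCa calculator**: `odds = Π LRᵢ`,
  `pCa = odds / (1 + odds)`, with the observation / biopsy / resection
  management thresholds at 0.05 and 0.60.

## Worked example

Simulate a 5,000-cell differentiating population, fit the Step-1 curve for
endoderm, and run the two-iteration IBF (500 cells per assay, 2% marker
flip noise):

```r
library(ibfstem)

cfg <- population_config(n_cells = 5000, seed = 42)
run <- ibf_pipeline(cfg, fate = "endoderm", sample_size = 500)
run$step1
#> Logistic differentiation curve fit (ls)
#>   plateau L = 0.2860, rate k = 1.6091 /day, inflection t0 = 3.008 d
#>   peak day = 3.008, implied commitment SD = 1.127 d, RSS = 0.0067
run
#> IBF run (2 iteration(s)) for fate 'endoderm'
#>   initial estimate: day 3.01 (SD 1.13)
#>   iteration 1: 24-h grid, 3 reps -> day 2.99 (SD 1.291; argmax day 2.8811)
#>   iteration 2: 12-h grid, 5 reps -> day 2.92 (SD 1.178; argmax day 2.8673)
#>   final prediction: day 2.92 (SD 1.178)
```

The simulation truth put the endoderm commitment peak at day 3 (SD 1 d);
Step 1 estimates day 3.0 from daily counts, and the final 12-hour iteration
lands at day 2.92 — within a tenth of a day. `tidy(run)` exposes the full
audit trail (windows, intervals, replicates, per-iteration estimates) and
`autoplot(run)` draws the per-day counts with the selected peak.

The Bayesian monitor and the pCa calculator are plain function calls:

```r
posterior_update(beta_state(1, 1), successes = 5 + 3, failures = 20 - 5 - 3)
#> Beta(9, 13); mean 0.4091
credible_interval(beta_state(9, 13))
#> # A tibble: 1 × 3
#>   lower upper level
#>   <dbl> <dbl> <dbl>
#> 1 0.218 0.616  0.95
nodule_pca(c(1.7, 0.4, 2.3))
#> # A tibble: 1 × 3
#>    odds   pca decision
#>   <dbl> <dbl> <chr>
#> 1  1.56 0.610 resection
```

A thin command-line launcher over the same functions ships in
`inst/cli/ibf.R` with subcommands `simulate`, `classify`, `fit`, `monitor`,
`design`, `survive` and `pca`.

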
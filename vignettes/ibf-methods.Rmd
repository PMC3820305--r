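---
title: "Methods: the iterative Bayesian framework for differentiation time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the iterative Bayesian framework for differentiation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibfstem)
```

## The problem

Embryonic and induced pluripotent stem cells differentiating in embryoid
bodies (EBs) commit to the three germ layers over a span of days, and the day
on which commitment to a given fate is most probable — the *peak
differentiation day* — is what a protocol designer needs in order to sort the
purest possible population. `ibfstem` implements an iterative Bayesian
framework (IBF) for locating that peak: classify single cells from a
seven-marker panel, fit the cumulative differentiation curve, then adaptively
re-sample a shrinking window around the current peak estimate, updating the
estimate after each iteration. Because no public single-cell data set exists
for this design, the package ships a synthetic EB population generator whose
statistical structure matches the framework's working hypotheses; every
quantitative claim the package tests is computed on that generator or on
closed-form fixtures.

## Marker panel and fate classifier

Seven binary marker calls define the cell states: Nanog (pluripotency),
Foxa2 and Noggin (mesendoderm), Hex (endoderm), Tbx6 (mesoderm), Ap-2&alpha;
(ectoderm), Sox3 (neuroectoderm). A cell is *undifferentiated* iff Nanog is
positive; this takes absolute precedence over the other six markers. Nanog-
cells are matched exactly against the nine published differentiated patterns
(three mesendoderm, two endoderm, two mesoderm, one ectoderm, one
neuroectoderm). Profiles matching no pattern are *unclassified*: the marker
tables do not define them, and inventing a nearest-fate rule would silently
relabel assay noise. Enumerating all `2^7 = 128` profiles partitions them
into 64 undifferentiated, 9 fate-matched and 55 unclassified profiles — a
fixed QA surface (`enumerate_fate_partition()`).

One wrinkle in the sources is that Noggin appears both as a mesendoderm
marker and inside the mesoderm pattern (Noggin+ Tbx6+); the classifier
follows the fate-definition table literally.

## The synthetic population

`simulate_population()` draws, per cell: a fate (endoderm / mesoderm /
ectoderm, with a residual fraction that never differentiates), a commitment
day from a Normal truncated to the culture horizon, transitional-state entry
days, a death day from a constant hazard, and — for the configurable
sub-fraction of ectodermal cells that progress to neuroectoderm — a
Sox3-only transition day. Defaults encode the framework's working
hypotheses for a 10-day mouse EB culture:

* endoderm commitment peaks at day 3; mesoderm and ectoderm at day 7
  (commitment SD 1.0 d each — the sources give peaks, not spreads; 1 day
  makes the cumulative curve plateau on the observed schedule);
* equal thirds across the germ layers (no published fractions exist; equal
  mass is the neutral choice and is fully configurable);
* 5% residual Nanog+ cells at day 10 (residual Nanog+ cells are described
  qualitatively; 5% keeps them visible at realistic sample sizes);
* a 1-day mesendoderm (Foxa2+ Noggin+) lead before endoderm/mesoderm
  commitment, motivated by endoderm markers appearing days before the
  day-5 mesoderm/ectoderm markers;
* 25% of ectoderm cells progress to Sox3-only neuroectoderm after a 2-day
  lag (both unstated in the sources; configurable);
* per-marker assay flip noise 2%, death hazard 0.01/day (PI+ cells are
  retained as a competing risk, not discarded).

The `stat3b` condition models dominant-negative STAT3: the ectoderm fraction
is halved (displaced mass reassigned proportionally) and the ectoderm
commitment mean shifts one day later. These two knobs produce the predicted
"reduced and delayed" ectoderm phenotype that the survival module is meant
to detect; they are predictions, not measured effect sizes.

Truncated-Normal commitment days are drawn by quantile inversion rather than
rejection so that a fixed seed yields byte-identical populations regardless
of parameter values. What the generator does **not** emulate: continuous
fluorescence intensities, spectral spillover and compensation, doublets,
spatial EB structure, cell division, or fate-dependent death. Passing tests
therefore demonstrate the statistical machinery under the stated model, not
robustness to those real-data features.

## Step 1: the cumulative differentiation curve

`fit_logistic()` fits `p(t) = L / (1 + exp(-k (t - t0)))` to the proportion
of Nanog- cells over time, by least squares on proportions (default) or
binomial maximum likelihood. The inflection `t0` is the peak differentiation
day; the plateau `L` sits below 1 by the residual fraction. The SD handed to
Step 2 is `pi / (k * sqrt(3))` — the SD of the logistic distribution whose
CDF the curve traces. The sources never specify how Step 1's SD is obtained;
this identity is the natural choice because it makes the (peak, SD) pair a
genuine location/scale summary of the implied commitment-time distribution.
Initialisation: `t0` at the time of maximal first difference, `L` at the
maximum observed proportion, `k = 4 * max slope / L`; Levenberg–Marquardt
with `ftol = ptol = 1e-12`, at most 500 iterations, `L` bounded in (0, 1].
A decreasing tail (detachment/death after day 9) is deliberately not part of
the curve model; the simulator's death hazard covers it and dead cells are
excluded from proportions (PI gating).

## The Bayesian monitor

For `N` cells that can differentiate, `s` successes among `n` assayed, and a
Beta(&alpha;, &beta;) prior on the differentiation rate, the number `T` of
further successes among the remaining `N - n` follows the beta-binomial
predictive

$$ p(t \mid s) = \binom{N-n}{t}\,
   \frac{B(\alpha+s+t,\ \beta+n-s+N-n-t)}{B(\alpha+s,\ \beta+n-s)},
   \qquad t = 0,\dots,N-n, $$

and the posterior after observing both is Beta(&alpha; + s + t,
&beta; + N - s - t). The default prior is the uniform Beta(1, 1). All beta
functions are evaluated in log space, so `N` up to 10^6 is safe.
`monitor_trial()` applies the standard sequential rules: stop for
superiority when the predictive probability of reaching the goal is at least
0.95, for futility when at most 0.05 (both configurable; the sources say
only "a priori threshold values"). `prior_sensitivity()` re-runs the
analysis over a prior grid and flags the result *prior-dominated* when
posterior means diverge by more than a tolerance (default 0.05), the
recommended guard against a prior the data cannot overcome.

The predictive is validated three independent ways in the test suite:
normalisation and the law of total expectation on a parameter grid,
agreement with numerical quadrature over the beta posterior, and Monte-Carlo
sampling (draw the rate, then the binomial) at 10^5 draws.

## Step 2: the iterative sampling loop

`make_window(mean, sd, interval)` builds the analysis schedule: a uniform
grid from `mean - sd` to `mean + sd + 1` day. The worked schedule in the
framework's description (mean day 5, SD 2 → days 3, 4, 5, 6, 7, 8) is
asymmetric — `mean + sd` is day 7, yet day 8 is analysed — so the upper
bound carries a one-day extension; the rule here reproduces the printed
schedule exactly rather than second-guessing it. Windows are clipped to the
culture horizon.

The default schedule is two iterations: 24-hour intervals with 3 replicates,
then 12-hour intervals with 5 replicates, after which the estimate is final.
Finer resolution is deliberately not pursued — spontaneous background
differentiation makes the system too variable to resolve below half-day
increments. The iteration-2 window half-width is capped at iteration 1's so
successive windows never widen.

Three measurement/estimation choices here were genuinely open and deserve
their rationale:

* **Centred bins.** The "newly differentiated" count for analysis day `t` is
  the increment of the fate-classified fraction between readouts at
  `t - interval/2` and `t + interval/2`. A count labelled by the right edge
  of its bin would bias the peak by half an interval.
* **Cohort replicates.** Each replicate is an independently drawn subculture
  of `sample_size` cells read out at every bin boundary. Differencing two
  *independent* 500-cell samples instead would double the sampling variance
  and leave the per-bin signal comparable to its noise at 12-hour
  resolution. Increments are computed on the viable-cell fraction and scaled
  back to cells so accumulating deaths do not deflate later bins.
* **Lineage counting.** A fate's count includes its derived states
  (ectoderm includes neuroectoderm; mesendoderm includes endoderm and
  mesoderm): a cell that reached Ap-2&alpha;+ Sox3+ and then progressed to
  Sox3-only *did* differentiate into ectoderm. Counting the exact classifier
  category instead (`lineage = FALSE`) drains the right flank of the window
  and biases the ectoderm peak early.

Each iteration reports two location summaries. The *argmax day* follows the
literal selection rule — maximal mean count, ties broken by minimal
replicate SD, then by the earlier day. The iteration's *peak estimate*,
which is handed to the next window and reported as the final prediction, is
the mean of a scaled-Gaussian fit (`fit_peak()`) to the per-day mean counts,
falling back to the argmax day if the fitted mean leaves the window. The
argmax alone is a poor estimator on a 24-hour grid: when the true peak sits
near a grid midpoint the two adjacent bins tie in expectation and the argmax
is a coin flip a full day wide; the fitted mean uses every window day. The
Gaussian-rate fit floors its SD at half the sampling interval when the
counts degenerate to a single spike, and flags it.

## Survival analysis of commitment times

`as_survival_records()` turns the simulation truth into one record per cell:
the event of interest is neuroectodermal commitment (first Sox3-promoter-GFP
expression), with death and non-neural terminal differentiation as competing
events and administrative censoring at the horizon (the sources leave
censoring undefined; the horizon is the only defensible cut). Estimation
goes through the survival package: `survfit` for the product-limit curve
(competing events censored), multi-state `survfit` for the Aalen–Johansen
cumulative incidence, `survdiff` for the log-rank comparison of wild type
against STAT3&beta;. Ties follow the standard convention (events before
censorings). Conservation — survival plus all cumulative incidences equals
one — is asserted on every estimate in the tests, alongside hand-computed
product-limit and log-rank fixtures.

## The pulmonary-nodule pCa calculator

A small, self-contained Bayesian calculator included because its formulas
sit alongside the framework in the same methodological exposition: feature
likelihood ratios `LR = (malignant with feature) / (benign with feature)`
multiply into the odds of malignancy, `pCa = odds / (1 + odds)`, and
management follows the cost-effectiveness thresholds — observation when
`pCa <= 0.05`, resection when `pCa >= 0.60`, biopsy in between. The
published worked cases place pCa = 0.05 under observation even though the
prose describes biopsy as "between 0.05 and 0.60"; the inclusive 0.05
boundary here follows the worked cases. LR tables for specific radiologic
features are inputs, not shipped data.

## Numerical choices and degenerate inputs

* Logistic and Gaussian-rate fits: `minpack.lm::nlsLM`,
  `ftol = ptol = 1e-12`, 500 iterations; Gaussian location bounded to the
  window span plus one grid step, scale bounded by the span.
* Beta quantiles via `stats::qbeta`; predictive pmf renormalised after the
  log-space exponentiation (guards the `1e-12` sum-to-one contract).
* `fit_peak` on a single nonzero day: mean at that day, SD floored at half
  the sampling interval, `sd_floored` flag set.
* `predictive_pmf` with `N = n`: point mass at zero future successes.
* Windows clipped to `[0, horizon]` warn; empty windows abort.
* Event-table validation names the offending column and row.

## Problem sizes

The shipped tests and the acceptance script use 5,000-cell populations with
500 cells per assay for end-to-end recovery runs (a realistic FACS aliquot),
2,000-cell populations for property sweeps over 20–25 seeds, 10^5 draws for
Monte-Carlo checks of the predictive, and 200 seeded data sets for the
logistic-recovery simulation. At these sizes the whole suite runs in well
under a minute of compute for the statistical checks plus a few seconds per
end-to-end IBF run.

## Known limitations

* Binary marker calls are taken as given; thresholding continuous
  fluorescence, compensation and doublet exclusion happen upstream.
* The simulator's commitment model is a single truncated-Normal wave per
  fate; bimodal or skewed commitment would be summarised, not detected.
* The beta-binomial monitor covers a single arm with a conjugate prior; no
  two-arm comparisons, non-conjugate priors or MCMC.
* The IBF assumes the Step-1 estimate lands the first window over the true
  peak; a grossly wrong prior (off by more than `sd + 1` day) cannot be
  recovered within the two-iteration default, only diagnosed from the audit
  trail (counts rising monotonically toward a window edge).
* Fig-style survival comparisons are qualitative: the wild-type versus
  STAT3&beta; contrast is a direction check, not a calibrated effect size.
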
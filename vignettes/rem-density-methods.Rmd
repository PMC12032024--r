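---
title: "REM density biomarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{REM density biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remdensity)
```

## The problem

In depression, REM sleep is disturbed in characteristic ways: REM latency
(RL, the time from sleep onset to the first REM period) tends to shorten,
and the density of rapid eye movements during REM sleep tends to rise,
particularly in the *first* REM period of the night (RD1). RD1 is of
special interest as a candidate endophenotype and as a possible predictor
of antidepressant response. `remdensity` implements the full quantitative
chain from scored polysomnography to that prediction: eye-movement
detection from the electrooculogram (EOG), REM-period segmentation from the
hypnogram, a per-night metric panel, a non-parametric group/paired
comparison workflow, and a stratified hold-out harness that scores baseline
RD1 as a classifier feature for treatment response.

No clinical recordings ship with the package. Instead, a synthetic cohort
generator reproduces the statistical *structure* such a study assumes, so
every stage is testable end-to-end.

## Metric definitions

All metrics operate on a hypnogram: a sequence of 30-second epochs scored
as W, S1--S4, REM or UNSCORED, anchored at lights out.

* **Sleep onset**: first epoch of stage 2. **Final waking**: one past the
  last sleep epoch; terminal wake is excluded from every windowed metric.
* **TST** = minutes of S1--S4/REM in [onset, final waking); **WASO** =
  wake minutes in the same window; **SWS** = minutes of S3+S4 there.
* **SE** = 100 x sleep minutes anywhere / in-bed minutes. The standard PSG
  definition; it is a package-level choice (recorded in `run_config()`) and
  can be swapped.
* **REM period (REMP)**: REM epochs separated by < 15 min of non-REM form
  one candidate; candidates with < 3 min of cumulative REM are discarded.
  The 3-min rule applies to *cumulative* REM within a candidate, because
  candidates may legitimately contain brief non-REM interruptions. A REMP
  is *completed* when at least 15 min of non-REM follow it before final
  waking; a period truncated by the end of the record is not completed.
* **RL** = elapsed minutes (wake included) from sleep onset to the first
  REMP. **REM Time** = all REM minutes in the analysis window, inside or
  outside surviving REMPs. **REM Percent** = 100 x REM Time / TST.
  **REM Efficiency** = 100 x REM minutes in completed REMPs / span of
  completed REMPs.
* **Total-night RD** = eye movements in REM epochs of the window / REM
  Time. Movements scored during non-REM epochs are excluded from the
  numerator: the denominator is REM time, so a numerator that counted
  non-REM movements would not be a density. The flag
  (`numerator_rem_only`) is recorded in the run configuration.
* **RD1** = eye movements in the REM epochs of the first REMP / that
  REMP's REM minutes, in counts/min. A doubly normalized reading (a rate
  divided again by minutes) would carry counts/min^2 and is rejected on
  dimensional grounds.

Two conventions are genuinely open and are therefore explicit config
switches with recorded defaults: whether wake counts toward the 15-min
separation (`gap_counts_wake`, default `TRUE` -- a REM episode interrupted
by 20 min of wakefulness is not one continuous period), and RL counting
elapsed rather than sleep-only time.

## Eye-movement detection

The detector implements an amplitude criterion with no duration criterion:
after band-limiting (0.3--10 Hz zero-phase Butterworth, order 2), local
extrema of the trace are located at the zero crossings of its first
difference, and every peak-to-trough excursion strictly greater than 25 uV
becomes an event. The inequality is strict: a 25.0 uV deflection is not an
event. Two practical guards are configurable: a per-channel refractory
interval (default 0.1 s) collapses multi-lobed saccade waveforms, and a
binocular coincidence window (default 0.2 s) counts a saccade seen on both
EOG channels once. Pre-detected event tables can be supplied instead of
traces; densities are identical either way.

The band edges, refractory and coincidence windows are not dictated by the
detection criterion itself; they are this package's operationalization,
exposed in `run_config()` so alternatives can be recorded and compared.

## Statistical workflow

Sleep metrics are skewed at these sample sizes, so the workflow is
non-parametric throughout, with `normality_gate()` (Shapiro-Wilk) kept
advisory. Group contrasts use the two-tailed Mann-Whitney U test, paired
treatment contrasts the Wilcoxon signed-rank test (zero differences
dropped before ranking). Both use exact distributions when the sample
permits (both groups <= 20 without ties; <= 25 non-zero differences) and
the tie- and continuity-corrected normal approximation otherwise, which is
the regime of the default cohort sizes (63/41 independent, ~61 paired).
A normal-approximation Z accompanies every p-value. Families are corrected
with Bonferroni-Holm: the REM marker trio {RL, RD1, Total RD} forms one
family and the eight-metric architecture panel another; the partition is a
recorded assumption, not a fact of the design.

## Response prediction

Responders are subjects whose day-1 depression score fell by at least 50%
of baseline (inclusive). The harness runs 1000 iterations of stratified
70--30 hold-out validation of an RBF-kernel SVM on the baseline RD1
feature. Unstated details are fixed as follows and recorded in the report:

* C = 1 and kernel width 1/d on standardized features (the data-scaled
  default of the algorithm family; with a single near-threshold feature
  the decision is insensitive to these).
* Standardization statistics come from each training split only, so no
  information leaks from test to train.
* Per-class training counts are `round(n_class * 0.7)`, which keeps every
  split's class proportions within one subject of the cohort's.
* ROC aggregation across iterations is not uniquely defined; the package
  pools test-set decision scores across all iterations into one curve and
  AUC, and also reports the per-iteration AUC distribution. The accuracy
  interval is the 2.5/97.5 percentile interval of per-iteration accuracy.
* ROC axes follow the universal convention (FPR on X, TPR on Y).

`roc_and_auc()` is a tie-aware threshold sweep whose trapezoidal AUC
equals the normalized Mann-Whitney rank statistic exactly; the test suite
checks that identity on random instances and against an independent
implementation.

## The synthetic cohort generator

`simulate_cohort()` emulates a two-group study -- a treatment-resistant
group (n = 63) recorded at baseline and after treatment, and healthy
volunteers (n = 41) at baseline -- with these designed features:

* **Night structure**: semi-Markov blocks rather than epoch-wise Markov
  transitions, because the analysis depends on period structure (latency,
  episode durations, 15-min separations), not on microstructure realism.
  Nights are 480 min; REM episodes lengthen across cycles
  (means 10--25 min), inter-REM NREM blocks are floored at 16 min so
  distinct episodes always segment as distinct periods; slow-wave epochs
  load onto early cycles; 5% of interior REM epochs are brief stage-2
  interruptions (keeping REM efficiency realistically below 100%); wake
  intrusions hit stage-2 epochs.
* **Latency**: group means 70 min (patients) vs 84 min (volunteers),
  gamma-distributed with SD 16 min; treatment leaves latency unchanged.
  Published group tables report mean +/- SEM, which conflates
  between-subject spread with night-to-night measurement noise; the
  generator's 16-min between-subject SD was chosen a priori so that the
  designed latency difference is a reliably detectable effect at these
  sample sizes while staying within the plausible clinical range.
* **Eye movements**: homogeneous Poisson trains within REM epochs. Both
  groups share one night-average rate distribution (lognormal, mean
  1.2/min, CV 0.5, constant within subject across nights). Group structure
  enters only through the first-period multiplier (1.35 patients, 0.70
  volunteers) with late-night compensation that preserves the night
  average exactly -- so RD1 separates the groups while total-night RD is
  null by construction. Treatment multiplies the patients' first-period
  multiplier by 0.70 (again compensated) and REM episode durations by
  1.18, reproducing the designed pattern "RD1 falls, total RD and RL
  unchanged, REM time and TST rise".
* **Clinical scores**: baseline HAM-D ~ Normal(21.45, 3.98) truncated at
  17; response probability follows a logistic link in baseline RD1 (slope
  1.5 per count/min) whose intercept is root-solved per cohort so the
  expected responder count is 20 of the 61 subjects with observed
  outcomes (2 are missing by design); day-1 scores are drawn consistently
  with each label under the inclusive 50% rule. Slope 0 gives the null
  configuration. No responder-vs-non-responder RD1 means are published,
  so the slope is a free parameter: the generator makes no claim that its
  prediction accuracy reproduces any particular study's.

What the generator does *not* emulate: physiological EEG content,
circadian modulation of eye-movement rate, scorer disagreement, apnea or
arousal microstructure, diagnostic subgroups. Passing tests therefore
demonstrate correctness of the computational chain under the designed
statistical structure, not clinical validity on real recordings.

## Numerical choices and degenerate inputs

* Epochs are 1-based half-open intervals `[start, end)`; every duration is
  `0.5 * epoch count` minutes. File interchange keeps the 0-based `epoch`
  column of the CSV dialect.
* Undefined metrics (REM-free nights, missing onset, no completed REMP)
  are `NA`, never 0; composition (`night_metrics()`) propagates them.
* UNSCORED epochs count as neither sleep nor wake and do not break
  analysis windows.
* All-zero paired differences give the no-effect result (p = 1) rather
  than an error; constant samples short-circuit the normality gate with a
  degenerate flag.
* The detector refuses sampling rates below twice the band's upper edge;
  exact-threshold excursions are non-events by the strict inequality.
* Reproducibility is seed-exact end-to-end: `simulate_cohort()`,
  `holdout_validate()` and `run_analysis()` produce byte-identical numeric
  output for identical seeds.

## Problem sizes used by the test suite

The suite verifies segmentation against a brute-force oracle exhaustively
over all 16,384 two-stage nights of length 14 (and all shorter lengths to
12 in unit tests), metric equality against naive recounts on 200 random
synthetic nights, Poisson rate recovery over 500 nights, test size with
1000 null replicates at the study's n, the prediction null with 1000
pooled hold-out iterations across 25 label permutations, the binormal
closed form (AUC = Phi(delta/sqrt(2)) at delta = 0.87) at n = 2000 with
150 iterations, and the designed effect pattern over 100 replicate
cohorts. These sizes give comfortable Monte-Carlo margins for every
property checked while keeping a full run in a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_spec(), seed = 1)
bundle <- run_analysis(run_config(seed = 1), cohort = cohort)
bundle$group_tests
bundle$prediction
```

## Known limitations

* EDF/EDF+ reading is not provided; hypnograms, events and traces are
  exchanged as the documented CSV dialects.
* The generator's effect sizes are design targets, not estimates from any
  dataset; group means match published magnitudes but spreads are the
  package's own calibration.
* The SVM's pooled-score AUC slightly compresses toward 0.5 relative to
  the feature's own AUC (score scales differ across training splits);
  the per-iteration AUC distribution in the report makes this visible.
* With a single feature the harness is deliberately minimal: no
  hyperparameter search, no multi-feature models, no calibration curves.
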
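# remdensity

Quantitative REM-sleep biomarkers from scored polysomnography, and an
evaluation of first-REM-period eye-movement density (**RD1**) as a
predictor of antidepressant treatment response.

In depression, REM sleep shows a characteristic signature: shortened REM
latency (RL) and elevated REM density — eye movements per minute of REM
sleep — especially during the first REM period of the night. `remdensity`
implements the full chain needed to study that signature:

1. **Eye-movement detection** from electrooculogram traces: an event is any
   peak-to-trough excursion of the band-limited (0.3–10 Hz) signal strictly
   exceeding 25 µV, with no duration criterion
   (`detect_eye_movements()`, `count_events_by_epoch()`).
2. **REM-period segmentation** from 30-s epoch hypnograms: REM epochs
   separated by < 15 min of non-REM form one period, periods need ≥ 3 min
   of cumulative REM (`segment_rem_periods()`).
3. **The per-night metric panel** (`night_metrics()`):
   * RD1 = movements in the first REM period / its REM minutes (counts/min)
   * Total-night RD = movements across the night's REM sleep / REM Time
   * RL = minutes from sleep onset (first S2 epoch) to the first REM period
   * TST, SWS, WASO, REM Time, REM Percent, REM Efficiency, SE
4. **Non-parametric cohort statistics**: two-tailed Mann-Whitney U for
   group contrasts, Wilcoxon signed-rank for paired treatment contrasts,
   Bonferroni-Holm family correction, mean ± SEM tables
   (`compare_groups()`, `compare_paired()`, `holm_adjust()`,
   `summary_table()`).
5. **Response prediction**: responders are subjects with a ≥ 50% drop in
   HAM-D score one day post-treatment; 1000 iterations of stratified 70–30
   hold-out validation of an RBF-kernel SVM on baseline RD1, with a pooled
   ROC curve, AUC and the per-iteration accuracy distribution
   (`label_responders()`, `holdout_validate()`, `roc_and_auc()`).

Because clinical recordings ship with no public study of this design, a
synthetic cohort generator (`simulate_cohort()`) reproduces the designed
statistical structure — 63 patients vs 41 volunteers, shorter RL and higher
RD1 in patients with *no* group difference in total-night RD, a treatment
effect that lowers RD1 and raises REM Time/TST, and a responder subgroup
(expected 20 of 61) whose response probability rises with baseline RD1 —
so the whole pipeline is testable end-to-end. See the methods vignette
(`vignettes/rem-density-methods.Rmd`) for the models and every recorded
design choice.

## Worked example

```r
library(remdensity)

cohort <- simulate_cohort(cohort_spec(), seed = 1)
bundle <- run_analysis(run_config(seed = 1), cohort = cohort)

bundle$group_tests[, c("metric", "z", "p", "p_adjusted", "significant")]
#>           metric         z            p   p_adjusted significant
#> 1     rl_minutes -2.5648664 1.032155e-02 2.064311e-02        TRUE
#> 2            rd1  5.1955454 2.041205e-07 6.123615e-07        TRUE
#> 3 total_night_rd  0.5720477 5.672897e-01 5.672897e-01       FALSE

bundle$prediction
#> <prediction_report> 1000 iterations, 61 subjects (21 responders)
#>   median accuracy 0.83 (95% CI [0.72; 0.94]), pooled AUC 0.83
#>   mean TPR 64.10, mean FPR 5.28 (0-100 scale)
```

Reading: in this simulated cohort the patient group shows significantly
higher RD1 and shorter RL at baseline (Holm-corrected within the
{RL, RD1, Total RD} family) while total-night RD does not differ — the
designed dissociation — and baseline RD1 separates simulated responders
from non-responders well above chance. A thin CLI over the same functions
lives at `inst/cli/remdensity.R` (subcommands `simulate`, `metrics`,
`compare`, `predict`, `run-all`).

Hypnograms interchange as CSV (`epoch,stage` plus `#lights_out=HH:MM:SS`
header lines; AASM tokens N1–N3/R are mapped), events as
`time_s,amplitude_uv,channel`, clinical tables as
`subject_id,group,hamd_baseline,hamd_day1`.

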
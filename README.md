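# sepsiskit

Evaluation and data machinery for **hourly sepsis prediction in the ICU**.

Sepsis is among the leading causes of in-hospital death, and earlier
recognition improves outcomes, yet conventional classifier metrics (AUROC,
AUPRC, accuracy, F-measure) say nothing about *when* an alarm fires relative
to sepsis onset, and they neither reward early detection nor charge for false
alarms. `sepsiskit` is aimed at researchers who develop or benchmark
sequential sepsis-prediction algorithms on hourly EHR time series. It
provides:

- **Clinical utility score** — a time-dependent, piecewise-linear
  reward/penalty per hourly prediction. For a septic patient with onset
  `t_sepsis`, a positive prediction at hour `t` earns

  ```
  U_TP(t) = u_tp_max * (t - (t_sepsis - 12)) / 6      for t in [t_sepsis - 12, t_sepsis - 6]
          = u_tp_max * ((t_sepsis + 3) - t) / 9       for t in (t_sepsis - 6, t_sepsis + 3]
  ```

  with the apex (`u_tp_max = 1`) six hours before onset; positives earlier
  than `t_sepsis - 12` and all positives in nonseptic patients incur the
  false-alarm penalty `u_fp = -0.05`; negatives in septic patients are
  increasingly penalized from `t_sepsis - 6`, reaching `u_fn_min = -2` at
  `t_sepsis + 3`. Per-window scores are summed over the cohort and
  normalized so a per-window **optimal** predictor scores 1 and the
  all-negative **inaction** predictor scores 0.
- **Sepsis-3 onset labeler** — `t_suspicion` from qualifying IV-antibiotic /
  blood-culture pairs (culture within 24 h after antibiotics, or antibiotics
  within 72 h after culture; course at least 72 h), `t_SOFA` from a 2-point
  SOFA rise within 24 h, and `t_sepsis = min(t_suspicion, t_SOFA)` when
  `t_SOFA` falls in `[t_suspicion - 24, t_suspicion + 12]`.
- **Record I/O and cohort rules** — the pipe-separated hourly patient-record
  format (40 clinical variables: 8 vitals, 26 labs, 6 demographics; missing
  cells as `NaN`), hourly median condensation of raw observations, and the
  inclusion rules (at least 8 hourly windows; septic onset at least 4 h after
  admission; truncation at 336 h).
- **Synthetic multi-hospital cohorts** — a seeded generator of records with
  near-hourly vitals, daily-draw labs, planted onsets whose treatment events
  and SOFA series the labeler provably recovers, configurable inter-hospital
  distribution shift, and a Jensen-Shannon divergence shift report.
- **Weibull-Cox baseline** — a Weibull proportional-hazards time-to-sepsis
  model (forward-fill/mean imputation, z-scoring, ridge-stabilized MLE) that
  emits per-hour risks and thresholded predictions.

## Worked example

```r
library(sepsiskit)

cfg <- cohort_config(n_patients = 60, prevalence = 0.2, seed = 3)
rep <- run_end_to_end(cfg)
rep$scores[, c("predictor", "total", "normalized", "auroc")]
#>   predictor       total normalized auroc
#> 1 optimal      79.8          1.00     NA
#> 2 inaction   -110.0          0.00     NA
#> 3 all_positive -44.0         0.348    NA
#> 4 baseline     -8.44         0.535  0.839
rep$label_check
#> [1] 1
```

The cohort has 60 patients (11 septic at this seed). The optimal predictor
anchors the normalized score at 1 and inaction at 0; predicting sepsis at
every hour scores 0.35 here because the cohort is small and stays are short,
while on predominantly nonseptic cohorts it goes negative. The Weibull-Cox
baseline, trained on the same cohort, reaches normalized utility 0.53 with a
pooled per-window AUROC of 0.84. `label_check = 1` says the Sepsis-3 labeler
re-derived every planted onset from the generated antibiotic/culture events
and SOFA series.

Individual pieces compose with pipes:

```r
coh <- generate_cohort(cfg)
ann <- annotate_cohort(coh$events, coh$sofa,
                       patient_ids = coh$annotations$patient_id) |>
  dplyr::mutate(hours = coh$annotations$hours)
model <- fit_weibull_cox(coh$records, ann)
predict_cohort_risk(model, coh$records) |>
  score_report(annotations = ann, predictions = _)
```

A command-line wrapper over the same functions ships in
`inst/cli/sepsiskit.R` with subcommands `generate`, `label`, `score`,
`baseline-fit`, `baseline-predict`, and `report`.

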
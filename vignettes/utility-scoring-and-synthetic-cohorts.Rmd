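---
title: "Utility scoring, Sepsis-3 labeling, and synthetic ICU cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utility scoring, Sepsis-3 labeling, and synthetic ICU cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsiskit)
```

`sepsiskit` evaluates algorithms that must issue a positive or negative
sepsis prediction at *every* hourly window of an ICU stay. This vignette
explains the scoring model, the Sepsis-3 labeling procedure, the synthetic
cohort generator, and the Weibull-Cox baseline, together with the design
choices behind each and what the package's tests do and do not establish.

## The clinical utility score

One-shot metrics do not fit the hourly prediction task: accuracy and
F-measure ignore timing entirely, and AUC metrics assume no operating
threshold, whereas a deployed alarm has one. The utility score instead
assigns each hourly prediction a value that depends on the patient's outcome
and, for septic patients, on the prediction's timing relative to onset:

* **Positive, septic.** Zero reward at `dt_early = -12` h relative to onset,
  rising linearly to the apex `u_tp_max = 1` at `dt_optimal = -6` h, then
  declining linearly to zero at `dt_late = +3` h. Earlier than `dt_early`
  the prediction is treated as a false alarm (`u_fp = -0.05`): a positive
  half a day or more before onset is clinically unactionable. The jump from
  `u_fp` to 0 at exactly `dt_early` is an intentional discontinuity and is
  asserted as such in the tests.
* **Negative, septic.** Free up to `dt_optimal`, then an increasing penalty
  reaching `u_fn_min = -2` at `dt_late`: from six hours before onset onward,
  staying silent costs more each hour.
* **Nonseptic.** Every positive costs `u_fp`; negatives are free
  (`u_tn = 0`).
* **Beyond `dt_late`** both choices score zero in septic patients, so all of
  the score's weight lies in the decision window around onset. The missed
  case has by then accumulated its full penalty along the ramp.

The time points (-12, -6, +3) define the task: predictions are wanted at
least 6 hours but at most 12 hours ahead of onset. The *levels* are a
convention — they are the defaults shipped with the public scoring tools for
this metric, widely used but not canonical constants — and every breakpoint
and level in `utility_params()` can be re-chosen to encode a particular
hospital's trade-offs.

Per-window scores are summed over all windows and patients
(`total_utility()`), then normalized (`normalized_utility()`) as
`(S - S_inaction) / (S_optimal - S_inaction)`, where the optimal predictor
takes the higher-utility option at every window and the inaction predictor is
all-negative. The anchors (optimal = 1, inaction = 0) hold by construction on
any cohort with at least one septic patient; on an all-nonseptic cohort the
denominator vanishes and the score is reported as undefined rather than
silently 0/0.

```{r utility}
p <- utility_params()
prediction_utility(TRUE, t_sepsis = 48, hour = c(30, 36, 42, 48, 51), 1, p)
prediction_utility(TRUE, t_sepsis = 48, hour = c(42, 48, 51), 0, p)
```

`score_report()` adds pooled per-window AUROC (mid-rank Mann-Whitney,
ties at 0.5), AUPRC (step integration over tie groups), accuracy, and
F-measure, which is what allows the package to contrast threshold-free
rankings with the utility view of the same predictions.

## Sepsis-3 labeling

A patient is labeled septic when clinical suspicion of infection and organ
failure co-occur:

* `find_t_suspicion()`: the earlier member of the earliest qualifying
  antibiotic/culture pair — culture within 24 h after the antibiotic start,
  or antibiotic start within 72 h after the culture, with the antibiotic
  course lasting at least 72 consecutive hours. With several qualifying
  pairs the global earliest time is used; the brute-force pair scan in the
  tests confirms order-invariance.
* `find_t_sofa()`: the first hour whose SOFA total exceeds the minimum over
  the trailing 24 h by at least 2. The reference event is a "two-point
  increase within 24 hours", which leaves the baseline anchor open; the
  rolling-minimum reading was chosen because it is local (no global
  baseline), causal (uses no future values), and detects every such
  increase. A fixed pre-suspicion baseline is the main alternative; `window`
  and `rise` are arguments, so other conventions are one call away.
* `find_t_sepsis()`: `min(t_suspicion, t_SOFA)` when
  `t_SOFA ∈ [t_suspicion - 24, t_suspicion + 12]`, else not septic.

SOFA totals come from `sofa_total()`, which grades six organ systems 0-4
from a configurable threshold table. Two simplifications are deliberate
(documented non-goals): cardiovascular scoring uses MAP plus a binary
vasopressor flag rather than dose tiers, and renal scoring omits urine
output. Because hourly labs are sparse, a missing component carries its last
observed subscore forward (never observed contributes 0); a
`carry_forward = FALSE` switch treats missing as normal instead.

Hourly labels for training and scoring are emitted by `emit_labels()`:
positives start `lead = 6` h before onset, the earliest optimally-rewarded
prediction time, clamped at admission. For an onset that lies beyond a
truncated record's end the labels are all zero and flagged, rather than the
record being dropped — exclusion rules are owned by
`apply_cohort_filters()`, not the labeler.

## Records, filters, and densities

Records are tibbles with exactly 40 columns — 8 vitals, 26 laboratory
values, 6 demographics — one row per ICU hour from hour 0, missing cells
`NA`, serialized to the pipe-separated layout with literal `NaN` tokens
(header required, no quoting, Unix newlines). `condense_hourly()` collapses
raw timestamped observations to the grid by the within-hour median (an even
count averages the middle pair), merging aliased source names (the default
map covers the serum/arterial hemoglobin merge) before binning; median over
the window is applied uniformly, including to duplicate timestamps.

`apply_cohort_filters()` enforces: fewer than 8 hourly windows → excluded;
septic onset earlier than 4 h after admission → excluded; longer than
336 h (2 weeks × 24 h) → truncated, never altering retained cells.
Discharge-time truncation is assumed to have happened upstream (for real
extracts) or is the generator's responsibility (for synthetic data). The
filter is idempotent and reports every exclusion with a reason. Whether
onsets at hours 4-5 (inside the record but within the label lead) should be
clamped or excluded is not fixed by the inclusion rules; the package clamps,
and the 4-hour exclusion is the only onset-based filter.

`measurement_density()` reports the fraction of non-missing hourly cells per
time-varying variable — near 1 for vitals, near 1/24 for daily labs — the
package's first diagnostic for comparing a synthetic cohort with a real one.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of multi-hospital hourly ICU
extracts, not their physiology:

* **Stays** are log-normal (median 38 h, log-SD 0.6 — a typical ICU
  length-of-stay scale consistent with tens of hourly windows per record),
  clamped to [8, 336] h so every record passes the filters unchanged.
* **Marginals** are truncated normals with conventional adult-ICU locations
  and spreads per variable (`default_variable_marginals()`), plus a
  per-patient random intercept at half the within-patient SD. Real marginals
  are skewed and multimodal; first-order location/spread realism is all the
  evaluation machinery needs.
* **Missingness**: vitals are independent Bernoulli per cell (target 0.9;
  end-tidal CO2 0.15, since it is only recorded during ventilation), labs
  are clustered at one per-patient daily draw hour with per-draw inclusion
  calibrated so the per-cell density hits the roughly-daily target. Observed
  densities land within ±0.05 of targets for cohorts of ≥ 100 patients.
* **Onsets**: a `prevalence` fraction of patients (default 0.1, the order of
  sepsis prevalence in shared ICU research datasets) receive an onset drawn
  uniformly from hour 4 to the penultimate hour. The generator then plants
  evidence that the labeler must re-derive: with equal probability either
  organ failure leads (SOFA steps +2 at the onset, culture 0-24 h later) or
  suspicion leads (culture at the onset, SOFA step 0-12 h later), with the
  antibiotic start within 48 h of the culture and a course of at least
  72 h. Nonseptic patients get sub-threshold SOFA wiggle and, 30% of the
  time, non-qualifying treatment events (short antibiotic courses). This
  self-consistency — `annotate_cohort()` recovering every planted onset — is
  what end-to-end tests lean on.
* **Pre-onset drift**: over the 12 h before onset, selected variables drift
  linearly to the early-sepsis signature (tachycardia, fever, hypotension,
  rising lactate; `default_sepsis_effect()`) and hold after onset. This is
  an artifact convention so that a survival model has signal to find; its
  magnitudes are not calibrated to any dataset.
* **Hospital shift**: per-variable location offsets and scale multipliers
  (`shift_loc`, `shift_scale`) emulate systematically different measurement
  distributions across hospital systems.

What passing tests therefore show: the scoring, labeling, filtering, and
fitting machinery is correct on data with the right shape, sampling
cadence, and event logic. What they do not show: performance or
calibration on real EMR data, whose missingness is informative, whose
marginals are heavy-tailed, and whose onset evidence is noisier than the
planted kind.

`jensen_shannon_divergence()` quantifies per-variable shift between cohorts:
samples are binned on a shared Freedman-Diaconis grid (minimum 10 bins — FD
adapts the width to spread and sample size; the floor keeps coarse samples
from degenerating into one or two bins), and the divergence
`H(M) - (H(P) + H(Q))/2`, `M = (P+Q)/2`, uses base-2 entropy so the result
is bounded in [0, 1]. `shift_report()` applies it to every clinical
variable, flagging (not scoring) variables unobserved in either cohort.

## The Weibull-Cox baseline

The baseline treats time to sepsis onset as right-censored survival:
septic patients contribute their onset hour as an event, nonseptic patients
are censored at record end. The hazard is Weibull proportional-hazards,

`h(t | x) = (k / λ) (t / λ)^(k-1) exp(β'x)`,

fit by BFGS on `(log k, log λ, β)` with analytic gradients, maximizing
`Σ d_i log h(t_i | x_i) - H(t_i | x_i)`. A ridge penalty of `1e-4` on `β`
keeps the fit identified when imputation produces near-constant columns; if
the optimizer still fails to converge (quasi-separation on small cohorts)
the model is refit once at ridge 0.01 with a warning. The optimizer's
relative tolerance is `1e-12` with up to 3000 iterations — with analytic
gradients the dominant cost is the cohort preprocessing, not the
optimization.

Design choices the survival framing leaves open, fixed here as follows:

* **Covariate summarization**: each patient is represented by the imputed,
  normalized feature vector at their event/censoring hour (last
  observation). Time-varying-covariate partial likelihoods would use more
  data but are beyond a baseline's remit.
* **Features**: the 34 clinical variables plus Age and Gender by default;
  preprocessing is forward-fill within patient, then the training
  population mean for never-observed features, then z-scoring with training
  statistics (`fit_feature_state()` / `impute_and_normalize()`).
* **Risk**: `risk(t) = 1 - exp(-(H0(t + w) - H0(t)) exp(β'x_t))`, the
  probability of onset in the next `w = 6` h (the earliest
  optimally-rewarded lead) given survival to `t`.
* **Threshold**: chosen on the training cohort to maximize normalized
  utility over a 25-point risk-quantile grid, because the utility score —
  not accuracy — is the evaluation objective.

`tidy()` and `glance()` expose the fit in the usual model-summary shapes,
and `write_weibull_cox()` serializes the whole decision rule (parameters plus
imputation/normalization state) as flat JSON.

## Numerical and testing notes

* Problem sizes in the test suite — cohorts of 15-500 patients, simulation
  studies at n = 2000 with 2 covariates — were chosen so each property is
  sharply testable at interactive runtimes; parameter-recovery checks
  compare against both the planted truth and an independent accelerated-
  failure-time reparameterization fit.
* AUROC uses mid-ranks, so exact ties contribute 0.5 concordance; AUPRC
  integrates precision over recall steps at tie-group boundaries. Both are
  checked against brute-force pair enumeration and an external ROC
  implementation.
* All generator randomness flows from `cohort_config(seed = )`; the
  generator saves and restores the caller's RNG state, and identical seeds
  yield byte-identical cohorts.
* Degenerate inputs fail loudly with classed conditions: empty PSV bodies,
  unknown schema columns, negative observation timestamps, single-class
  AUROC, zero rank variance in the Spearman correlation, all-nonseptic
  normalization.

## Limitations

* Synthetic realism is first-order only (see above); do not read utility or
  AUROC magnitudes on synthetic cohorts as forecasts of real-data
  performance.
* The SOFA table simplifies cardiovascular and renal scoring and does not
  infer ventilation status.
* No bootstrap uncertainty on scores and no formal comparison machinery for
  competing algorithms; the score report is a point summary.
* The labeler's rolling-minimum SOFA baseline and the tie conventions for
  simultaneous antibiotic/culture timestamps are documented choices;
  datasets labeled under other conventions will disagree near boundaries.
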
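---
title: "Five-minute-ahead intraoperative hypotension prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-minute-ahead intraoperative hypotension prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Intraoperative hypotension — a mean arterial pressure (MAP) below
65 mmHg sustained during surgery — is associated with kidney and
myocardial injury. This package implements a short-term event
prediction pipeline (STEP-OP) that forecasts hypotension five minutes
ahead from nothing but a 20-second window of the invasive arterial
blood pressure (ABP) waveform sampled at 100 Hz.

The pipeline's stages are:

1. **Canonicalization** (`read_record()`, `resample_to_100hz()`):
   records arrive at 100 or 500 Hz; 500 Hz traces are decimated by
   keeping every 5th sample.
2. **Artifact screening** (`check_segment()`): a segment is excluded if
   it contains a missing value, any pressure over 200 mmHg or under
   20 mmHg, a max-minus-min range under 20 mmHg, or an
   adjacent-sample difference over 30 mmHg (3000 mmHg/s at 100 Hz).
   All four thresholds are *strict* inequalities, following the
   wording "over"/"under"; boundary behavior cannot be resolved
   empirically, so the convention is fixed and documented here.
   Segments are never edited — only kept or excluded.
3. **Labeling** (`detect_events()`, `extract_segment_pairs()`): the
   2-second trailing moving average of pressure defines events. A
   hypotensive event is a maximal run of the moving average under
   65 mmHg lasting at least 60 s; a nonhypotensive (negative) stretch
   keeps it over 75 mmHg for at least 60 s. Each 60-s outcome window
   is paired with the 20-s input segment that *ends* 300 s before the
   window *starts*.
4. **Beat preprocessing** (`detect_beats()`, `normalize_beat()`,
   `build_beat_matrix()`, `scale_values()`): the 20-s input is sliced
   into foot-to-foot cardiac cycles, each cycle is linearly
   interpolated to 100 samples, and the most recent 30 cycles are
   stacked into a 30 x 100 matrix (pre-padded with zero rows when
   fewer than 30 beats are present, pre-truncated when more). All
   pressures are mapped to [0, 1] by the fixed affine map
   x' = (x - 20)/(200 - 20).
5. **Models** (`train_cnn()`, `train_rnn()`, `train_logistic()`): a
   1-D CNN on the scaled length-2000 array, a stacked bidirectional
   LSTM on the beat matrix, and a ridge logistic baseline on 12
   waveform features.
6. **Ensemble and evaluation** (`optimize_alpha()`, `eval_report()`):
   the final score is P(alpha) = alpha * P_RNN + (1 - alpha) * P_CNN
   with alpha chosen to maximize AUPRC on an inner tuning split;
   evaluation reports AUPRC, AUROC and precision at sensitivity
   0.6/0.7/0.8 with subsampling-bootstrap 95% CIs.

`stepop()` runs all stages and returns a classed fit with `print`,
`summary`, `predict` (sliding-window prediction over a record),
`plot` and `coef` methods.

## Design choices where the procedure was open

Several details of the published recipe are under-determined; the
package fixes each one explicitly:

* **Moving-average alignment.** The 2-s moving average is *trailing*
  (causal): the value aligned to sample *i* averages samples
  *i*-199..*i*. A centred window would peek 1 s into the future and
  could not run in real time.
* **Horizon anchoring.** "Five minutes previously" is read
  end-to-start: the input segment ends 300 s before the outcome
  window begins, so a positive prediction is a genuine 5-minute
  warning. Start-to-start anchoring would shorten the effective
  warning to 4 min 40 s.
* **Window enumeration.** Candidate outcome windows are enumerated on
  a configurable stride (default 20 s, non-overlapping inputs) plus
  every detected event onset. Windows that are neither fully under
  65 mmHg nor fully over 75 mmHg, or that touch undefined
  moving-average values, are *indeterminate*: retained in the
  manifest, excluded from model data. Only the two extreme classes
  are defined by the labeling rule; everything else is ambiguous by
  construction.
* **Maximal runs.** One event per contiguous qualifying run, so a
  200-s hypotensive stretch is one event, not 140 overlapping ones.
* **Beat slicing.** Peaks are local maxima with a 0.3-s refractory
  distance and 10 mmHg minimum topographic prominence; cycle
  boundaries sit at the diastolic minimum (foot) between consecutive
  peaks, because systolic time and beat area need a foot-to-foot
  convention. Partial edge cycles are discarded. Both parameters are
  config knobs; no specific peak detector is prescribed by the
  method.
* **Waveform scaling.** Fixed min-max anchored at the screening
  bounds (20-200 mmHg) rather than per-segment scaling: per-segment
  scaling would erase the absolute pressure level, which is the
  single most informative quantity for this task.
* **Pre-truncation.** When a segment holds more than 30 beats the
  *oldest* are dropped: "pre"-truncation removes leading time steps,
  matching the pre-padding side.
* **Robust scaling.** The feature map is x' = (x - Q2)/(Q3 - Q1) with
  linear-interpolation quartiles (R type 7), fitted on the training
  fold only; a degenerate feature (Q3 = Q1) scales to 0. The printed
  formula is parenthesis-free; the standard median/IQR grouping is
  used.
* **AUPRC estimator.** Average precision (step integration) with tied
  scores grouped into one step — not trapezoidal PR interpolation,
  which is biased optimistic. Precision at a sensitivity target uses
  the highest threshold whose sensitivity reaches the target, with no
  interpolation.
* **Bootstrap.** "Resampling 50% of the dataset 1000 times" is
  implemented as subsampling *without* replacement at the segment
  level (a with-replacement flag exists). Single-class resamples are
  redrawn and counted.
* **Alpha grid.** Step 0.01 over [0, 1]; ties break toward the
  smallest alpha. Because the grid contains both endpoints, the tuned
  ensemble can never score below either single model on the tuning
  set — an invariant asserted in the tests.

## Optimization details

Both deep models train with AdamW (beta1 = 0.9, beta2 = 0.99, learning
rate 1e-4, decoupled weight decay 0.01) on class-weighted binary cross
entropy with weights 1 (negative) and 20 (positive); probabilities are
clipped at 1e-7 inside the loss. Training runs on 90% of training
*patients*; after every epoch the checkpoint is scored by AUPRC on the
held-out 10%, and the best checkpoint is kept. Both models share the
same inner split so the ensemble weight can be tuned on predictions
for the same segments. The LSTM applies a global gradient-norm clip of
5 for stability. All stochastic pieces (initialization, shuffling,
dropout) draw from R's RNG, so a single seed reproduces a run
bit-for-bit; the networks are implemented in compiled code
(RcppArmadillo) with exact forward/backward passes rather than through
an external deep-learning runtime, keeping training deterministic and
dependency-free.

Layer shapes are not part of the published recipe and are config
defaults: CNN blocks of kernel 7/5/3 with 16/32/64 filters, batch
normalization, ReLU and max-pool 4, global average pooling and a
sigmoid head; LSTM with 3 bidirectional layers of hidden size 64 per
direction, the final forward and backward states concatenated into the
head. Epochs and batch size are likewise free knobs: the desk-scale
configuration (below) uses smaller networks and more LSTM epochs,
because the recurrent model converges more slowly than the CNN at the
shared 1e-4 learning rate.

The logistic baseline is ridge-penalized (`glmnet`, alpha = 0) with
the penalty chosen by patient-grouped 5-fold cross-validation over a
logarithmic grid, then refit on all training rows. Grouping folds by
patient avoids the within-patient correlation leak that ungrouped CV
would introduce. If every feature is constant the model degrades to
intercept-only and predicts the prevalence.

## The synthetic cohort

No patient data ships with the package; a waveform simulator
(`simulate_record()`, `simulate_cohort()`) generates records with
known ground truth so every stage is testable. Per record:

* a per-patient baseline MAP is drawn from 85-100 mmHg (negative
  segments in real cohorts centre near 90 mmHg) with a slow +/-2 mmHg
  sinusoidal wander;
* scheduled hypotensive dips follow a **two-phase pre-onset drift**
  over `predrift_s` = 420 s: a slow decline to just above the
  threshold over the first 40%, then a steadier descent reaching
  65 mmHg exactly at the scheduled onset, a quick final drop to the
  target (48-60 mmHg), a plateau, and a 180-s linear recovery. A
  single linear ramp was tried first and rejected: it leaves the
  pressure 5 minutes before onset still at baseline, contradicting
  the near-hypotensive pre-event levels (MAP ~64 vs ~90 mmHg)
  reported for real cohorts, and makes the 5-minute task carry almost
  no signal. Random schedules place each dip near the end of its
  block so a long stable baseline precedes it, the typical
  presentation of a slow intraoperative decline;
* beats are synthesized foot-to-foot from a template (asymmetric
  systolic bump, dicrotic wave, linear diastolic runoff), anchored so
  each beat's mean equals the MAP envelope at its foot; heart rate
  follows an AR(1) process around a per-patient base rate, pulse
  pressure is modulated by a 5-s respiratory oscillation;
* falling MAP triggers a compensatory response — heart rate rises,
  mean pulse pressure falls slightly, and respiratory pulse-pressure
  modulation deepens — reproducing the class-conditional feature
  ordering of real data (positives: lower MAP, shorter beats, higher
  PPV);
* Gaussian noise (default 1 mmHg) is added, and artifacts of all four
  exclusion classes can be injected at a configurable rate with a
  position log.

What the simulator does **not** emulate: reflected-wave morphology
changes, arrhythmias, drug boluses, measurement drift, damped
catheter dynamics, or any validated hemodynamic model. Passing tests
on this cohort demonstrate that the pipeline's machinery is correct
and that the models can learn a 5-minute-ahead signal when one exists;
they say nothing about clinical performance on real waveforms, and the
published cohort-level numbers are not reproducible without the
original repository data.

## Problem sizes and numerical conventions

The desk-scale configuration `small_pipeline_config()` — used by the
worked examples and the acceptance script — simulates 50 patients of
30 minutes each with one dip per record, enumerates windows at a 30-s
stride (about 1700 modeled segments), and trains an 8/16/32-filter CNN
for 12 epochs and a hidden-32 LSTM for 35 epochs at batch size 16,
with 500 bootstrap resamples. These sizes were chosen once so a full
run fits in a few minutes on one CPU while leaving every contract
testable; all published constants (thresholds, horizon, optimizer,
class weights, 70/30 split, alpha grid) keep their exact values.

Conventions worth knowing when extending the package: indices are
1-based with half-open `[start, end)` windows; time of sample *i* is
`t0 + (i - 1)/100` s; the missing-value sentinel is `NA_real_`; batch
normalization uses batch statistics in training and running moments
(momentum 0.1) at inference; quartiles and bootstrap percentiles use R
quantile type 7; `detect_events()` reports onsets at the record index
to which the first qualifying moving-average sample is aligned, which
trails the true envelope crossing by up to the averaging window plus
the pulsatile ripple (a few seconds — visible in tests comparing
against simulator ground truth).

## Known limitations

* The simulator's dips are stylized; real hypotension onsets vary in
  shape, and real artifacts are messier than the four injected
  classes.
* Records in a cohort are independent; there is no shared-surgeon or
  shared-procedure correlation structure.
* The beat slicer assumes a single dominant systolic peak per cycle;
  heavily damped or double-peaked waveforms would need tuned peak
  parameters.
* `predict_over_record()` recomputes preprocessing per window; it is
  meant for record-level inspection, not high-throughput streaming.

```{r example}
library(stepop)
fit <- stepop(small_pipeline_config(seed = 1))
summary(fit)
plot(fit, "alpha")
```
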
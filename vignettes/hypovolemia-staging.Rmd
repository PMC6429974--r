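---
title: "Staging central hypovolemia from pulse-wave morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging central hypovolemia from pulse-wave morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the design decisions and the numerical
conventions behind `pulsestage`, in the spirit of a methods section: what the
pipeline assumes, which knobs matter, what the synthetic cohort does and does
not emulate, and what the tests consequently do and do not show.

## The staging problem

Lower-body negative pressure (LBNP) pools blood in the legs and drains the
central compartment, reproducing the hemodynamics of hemorrhage without blood
loss. Because the baroreflex defends arterial pressure until decompensation,
mean pressure is a poor index of how far a subject has progressed; the shape
of the arterial pulse carries earlier information (narrowing pulse pressure,
attenuation of the dicrotic wave, rising heart rate). The pipeline stages
every heartbeat into four ordinal classes — 0 for supine baseline
(normovolemia), and 1 to 3 for the first, second and third time-tertile of
the LBNP phase — so that a *continuous* severity trace can be read from the
smoothed, model-averaged class predictions.

The central assumptions are:

* morphology drifts monotonically with the (unobserved) severity of central
  hypovolemia, so time-tertile labels are a usable ordinal proxy;
* beats resampled to a fixed 33-point grid are comparable across heart
  rates — duration itself is deliberately discarded as a feature;
* a linear decision function on a handful of principal-component scores is
  expressive enough, because the morphological drift is close to a
  low-dimensional, monotone deformation.

## The model

Each detected beat (foot-to-foot) is resampled to exactly 33 samples by
monotone cubic Hermite interpolation and kept in mmHg — amplitude is
informative and is not normalized. The `n x 33` beat matrix is centered and
decomposed by covariance PCA (all columns share units); beats become scores
on the first `k` components. A soft-margin linear SVM with one binary
separator per unordered class pair stages each beat; a one-vs-one majority
vote with ties broken toward the *lower* (less severe) class gives the
discrete prediction.

Evaluation is leave-one-subject-out with bootstrap model averaging: with one
subject held out, 10 independent random subsamples of 10% of the pooled
remaining training beats are drawn (without replacement within a draw; a
`with_replacement` switch restores the classical bootstrap), 10 models are
trained, each model's discrete trace on the held-out recording is smoothed
with a 20-beat trailing moving average, and the 10 smoothed traces are
averaged. Since the smoother is linear, smoothing-then-averaging equals
averaging-then-smoothing; the tests assert this. Subjects who tolerate the
full LBNP phase are never used for training (their labels are uncertain) but
are always evaluated, as a false-positive check.

Reported metrics: per-class accuracy (percentage of beats whose *rounded*
averaged trace equals the true class) and per-class MSE (squared deviation of
the *continuous* averaged trace from the true class — the continuous reading
is what makes fractional per-class errors possible), aggregated as
median [IQR] across subjects; and Cohen's kappa computed once on the pooled
confusion matrix (not a mean of per-subject kappas), because a pooled single
number is the natural cohort summary of chance-corrected agreement.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_samples` | 33 | samples/beat | fixed-length shape vector; includes both beat endpoints |
| `k_components` | 5 | — | past ~5 components the evaluation metrics saturate on low-dimensional morphology drift |
| `C` | 0.01 | — | larger C follows the training labels more strictly, producing a stepwise, overfit trace; 0.01 is the knee |
| `C_grid` | 0.001…100 | — | six decades for the sensitivity sweep |
| `n_bootstrap`, `subsample_fraction` | 10, 0.10 | — | bounds training cost while averaging out subsample noise |
| `smooth_window_beats` | 20 | beats | ~15–20 s of beats: suppresses beat-to-beat prediction chatter without hiding stage transitions |
| beat validity band | 0.25–2.5 | s | physiologic beat durations (24–240 bpm); out-of-band segments are artifacts |
| minimum pulse pressure | 10 | mmHg | rejects calibration remnants and flat-line stretches |
| stop criteria | 80; 25/15; 15 | mmHg; mmHg/min; bpm/min | the protocol's presyncope thresholds: SAP floor, SAP/DAP decline, HR decline over a trailing 60-s window |
| `trend_delta`, `trend_tail_fraction` | 0.5 classes, 0.10 | — | a trace must rise at least half a class into its terminal tenth to count as still progressing |

Decline criteria are evaluated as the maximum of the series within the
trailing 60-s window minus the current value — a total decline per window,
robust to beat noise, rather than an instantaneous derivative. The criteria
combine *disjunctively* (any one suffices), the usual convention for safety
stop rules. Beats with less than a full window of history evaluate only the
absolute SAP floor.

## The severity-trend call

The cohort phenotypes to reproduce are: presyncope subjects whose averaged
trace keeps rising into collapse, and tolerated subjects whose trace levels
off early (no further progression — a true negative). `severity_trend()`
therefore compares the mean trace over the final `trend_tail_fraction` of
the LBNP segment against the mean over the 40–60% mid-LBNP window, calling
"increase" iff the tail exceeds the reference by `trend_delta` classes. A
baseline-referenced rule was considered and rejected: any monotone
severity-to-class mapping places a sub-critical plateau well above baseline,
so a baseline reference could never classify a plateaued trace as
stagnation, which is the phenotype of interest.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces, per subject: a supine baseline at latent
severity 0; an LBNP phase in which severity steps to `onset_step_severity`
(default 0.15) at onset — a single-step −50 mmHg protocol pools blood within
seconds, so the waveform responds immediately — and then ramps as
`(elapsed/collapse time)^2` toward 1; beat templates built from a primary
systolic wave, a dicrotic secondary wave whose amplitude falls with severity,
and an exponential diastolic run-off; pulse pressure shrinking by 45% and
heart rate rising by 25 bpm at severity 1; i.i.d. 2% beat-period jitter;
additive 1.5 mmHg sample noise; and periodic 2-s flat-line calibration
artifacts every 70 s. Presyncope subjects enter a terminal vasodepressor
collapse (SAP −40, DAP −20 mmHg/min; HR −20 bpm/min) at a collapse time drawn
from 40–85% of the 30-min LBNP limit, and the recording ends at the first
beat where the stop criteria fire — the generator runs the same detector the
package exports, so generator and detector agree by construction. Tolerated
subjects plateau at severity 0.5 and run the full 30 min.

Default between-subject variability is deliberately small (SAP 120 ± 2,
DAP 70 ± 1.5 mmHg, HR 65 ± 5 bpm): the default cohort is an *idealized,
screened-homogeneous population* on which the recoverable class structure is
strong. Real cohorts vary several-fold more (± 8–12 mmHg is typical of young
healthy volunteers); rerunning the pipeline with
`sap_baseline_mmHg = c(mean = 120, sd = 8), dap_baseline_mmHg = c(mean = 70, sd = 5)`
moves the pooled kappa from the ~0.65–0.75 range down to roughly 0.45–0.5,
because leave-one-subject-out staging from absolute-mmHg features degrades
when a held-out subject's baseline is offset from the training pool. That
sensitivity is a property of the method, not of the implementation, and is
worth keeping in mind when reading the test results: a green suite shows the
pipeline recovers structure the generator put in; it does not show the
method is robust to realistic inter-individual variability, device drift,
arrhythmia, motion artifacts, or morphology changes unrelated to volume
status. The generator also makes no attempt at mechanistic cardiovascular
modelling (no baroreflex dynamics, no Windkessel identification).

A few cohort draws remain hard even under the defaults: an unlucky
combination of baseline offsets and collapse times can push the pooled kappa
of a 15-subject cohort below 0.6 for some seeds. This is inherent sampling
variation at small cohort size, not nondeterminism — every run is exactly
reproducible from its seed.

## Numerical choices

* **Beat detection.** The device that produced the original tracings
  delivered beats; the package needs its own detector. Feet are located as
  the last pressure minimum in a 0.25-s window before each steepest
  upstroke; upstrokes are maxima of the 10 Hz low-pass-filtered first
  difference above 0.35 × its 99th percentile (primary upstrokes are 4–5×
  steeper than dicrotic secondary waves, so this threshold separates them
  across the physiologic range), with a 0.25-s refractory period.
* **Resampling.** Fritsch–Carlson monotone cubic Hermite tangents
  (`splinefun(method = "monoH.FC")`), 33 points including both endpoints, so
  interpolating an already-33-sample beat is the identity and linear
  segments are reproduced exactly. On monotone segments the interpolant
  cannot overshoot the data range.
* **PCA.** Thin SVD of the centered matrix; component signs fixed by making
  each component's largest-magnitude loading positive; explained variances
  are squared singular values over `n − 1`. A zero-variance (all-identical)
  matrix is an error, not a silent degenerate basis.
* **SVM.** libsvm (via e1071) solves each pairwise dual; the package reduces
  every separator to an explicit `(w, b)` oriented so positive decision
  values favor the pair's lower class, and applies its own vote with the
  lower-class tie rule (libsvm's internal tie handling is
  label-order-dependent and is not reproduced). Solver tolerance is 1e-6 for
  model fitting and 1e-4 inside the evaluation loop, where subsample noise
  dominates long before solver error matters.
* **Rounding.** Continuous traces are discretized with halves rounding
  toward the lower class, consistent with the vote tie rule (conservative on
  severity).
* **Quantiles.** Median and IQR use linear interpolation of order statistics
  at plotting positions `k/(n+1)` (type 6), so the IQR of three subjects at
  90/95/100% accuracy is 10 points.
* **Seeds.** One master seed derives per-subject and per-fold streams
  through fixed integer offsets; cohorts, subsample draws and hence entire
  evaluations are bit-reproducible, and sweeps over `C` or `k` reuse
  identical draws so they are controlled comparisons.
* **Degenerate inputs.** Flat signals yield zero beats with a warning;
  recordings whose beats all fall inside calibration intervals are excluded
  from the cohort matrix with a warning; subsamples containing fewer than
  two classes are redrawn (at most 100 times, then an error); an empty
  confusion matrix, an empty trace, or a missing baseline segment are
  errors.

## Open design choices, resolved

* **PCA fitting scope.** Fitting one PCA on all data leaks the held-out
  subject into the basis. Default is per-fold fitting (`pca_scope = "fold"`,
  with an internal assertion that the held-out subject is absent);
  `pca_scope = "global"` reproduces the single-basis variant for
  comparison.
* **Class tertile convention.** Right-closed tertiles with `f = 0` mapped to
  class 1, so every LBNP beat gets an LBNP class and the monotonicity of
  labels in time is exact.
* **Tolerated subjects' labels** are computed against the protocol end (the
  tolerance limit), used only for evaluation, never for training.
* **Subsampling interpretation.** Repeated 10% subsampling without
  replacement (a `with_replacement` switch restores classical bootstrap
  resampling); subsample sizes round up.

## Problem sizes used by the tests

The end-to-end suite evaluates the default cohort — 15 subjects
(12 presyncope), roughly 20,000–27,000 labeled beats — once, plus an
8-subject noise-free cohort for the component-saturation check and a
5-subject short-protocol cohort for the protocol-mechanics tests; these
sizes keep the whole suite in the low minutes while leaving every cohort
large enough for stable pooled metrics. The oracle tests (kappa against
expanded-pair recomputation, PCA against a covariance eigendecomposition,
the SVM against an exact active-set dual enumeration) run on small matrices
and ≤ 8-point toys where the oracles are exact.

## Known limitations

Absolute-mmHg features make leave-one-subject-out staging sensitive to
between-subject baseline offsets (see above). The class scheme assumes
progression is monotone in time, which the tolerated phenotype already
violates — those subjects are deliberately excluded from training. The beat
detector targets clean finger-plethysmography-like tracings; it has no
arrhythmia handling. The stop-criteria detector evaluates beat-wise series
and cannot see symptoms (sweating, nausea) that terminate real protocols
early; synthetic collapse is therefore always criteria-terminated.
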
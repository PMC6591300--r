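---
title: "Methods: the OPTICAL fusion predictor for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the OPTICAL fusion predictor for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Motor imagery modulates the power of the sensorimotor mu (8–12 Hz) and
beta (13–30 Hz) rhythms contralaterally to the imagined hand. The
predictor implemented here classifies a two-second EEG epoch by fusing two
scalar features, each derived from common spatial pattern (CSP)
filtering, with a radial-basis-function SVM.

**Preprocessing.** Epochs are taken 0.5 s after the visual cue and last
2 s. Each epoch is common-average-referenced (the instantaneous channel
mean is subtracted, making the per-sample channel mean exactly zero) and
band-pass filtered 7–30 Hz with a Butterworth filter. The filter order (4)
and zero-phase application (forward–backward with odd-reflection edge
padding, channel mean removed first) are this package's choices —
standard EEG practice that avoids phase distortion on short epochs; both
are configurable through `bandpass_spec()`.

**CSP.** Each trial contributes a trace-normalized covariance
`C = E Eᵀ / tr(E Eᵀ)`; trace normalization makes the filters invariant to
global amplitude rescaling. With class means `C̄₁, C̄₂`, the generalized
eigenproblem `C̄₁ w = λ (C̄₁ + C̄₂) w` is solved by whitening `C̄₁ + C̄₂`
and eigendecomposing the whitened `C̄₁`. Eigenvalues sorted descending; the
bank keeps the 3 leading and 3 trailing eigenvectors (six filters, the
convention used throughout). Eigenvalues of the two class problems are
complementary (`λ` and `1 − λ`), which the tests assert.

**LDA path.** The six whole-trial log-variance features
`y_i = log(var(Z_i))` (sample variance, divisor n−1) are projected to one
scalar by Fisher LDA, `w ∝ S_w⁻¹(μ₁ − μ₂)`, normalized to unit length,
offset so the midpoint of the class means projects to zero.

**LSTM path.** Each trial is segmented into windows of length
`l = round(0.25 S)` with overlap `t = round(0.05 S)` (round half up). A
second CSP bank is learned from the pooled training windows (never test
windows), and the per-window features form an `N × 6` sequence consumed in
time order by a regression LSTM: two layers (100 and 20 hidden units),
standard gated recurrence (sigmoid input/forget/output gates, tanh cell
candidate, zero initial state), a fully connected readout of the last
hidden state. Training minimizes mean squared error against targets ±1
(symmetric encoding of the two classes) by mini-batch SGD with momentum
0.9, batch size 16, 100 epochs, L2 penalty on weights only. Weights are
Glorot-uniform (input), orthogonal (recurrent), biases zero except the
forget gate at 1 — all seeded, so training is bit-reproducible.

**Fusion.** The two scalars are z-scored with training statistics (their
raw scales are incommensurate) and classified by an RBF SVM with C = 1 and
γ = 1/(2 · d · mean feature variance), d = 2 — a robust default for a
two-dimensional feature space; the underlying fit is `e1071::svm`.

## Hyper-parameter optimization

The LSTM's initial learning rate and L2 penalty are searched over
[1e-4, 1e-1] × [1e-5, 1e-3] in log10 space (the ranges span three
decades). The optimizer is a Gaussian process (squared-exponential kernel
on the unit box, lengthscale chosen by marginal likelihood over a small
grid, standardized observations, nugget 1e-6) with expected-improvement
acquisition maximized over 2000 random candidates per iteration, after a
5-point Latin-hypercube initial design. The default budget is 30
evaluations. Candidates are scored by stratified 10-fold cross-validation
on the training split; by default the objective is the deployed fused
predictor's misclassification ("optimize what you deploy"), with a
cheaper LSTM-only objective available (`hyper_objective = "lstm"`).
Without optimization the defaults are learn rate 1e-2 and L2 1e-4.

## Three-class cascade

For the real-time setting with a non-task class (blinks, eye movement,
rest), two one-vs-rest stages are trained, each a full fusion predictor
with its own spatial filters: stage 1 separates non-task from pooled MI
(with the non-task trials randomly subsampled to the MI trial count to
avoid imbalance; the draw is re-seeded per cross-validation repetition),
stage 2 separates left from right and never sees non-task data. A trial
labeled non-task by stage 1 keeps that label; otherwise stage 2 decides.

## Evaluation

Stratified 10-fold cross-validation repeated 10 times; every model
component (both CSP banks, LDA, LSTM, standardization, SVM,
hyper-parameters) is fit inside the training folds only. Per-fold
misclassification `(FP+FN)/total`, sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)` and Cohen's kappa `(p_a − p_e)/(1 − p_e)` are averaged over
the 100 folds (fold-mean, not count-pooling; the positive class defaults
to the first class in dataset order). Method comparisons use the
classical paired t-test on per-subject (or per-fold) rates; constant
differences have zero variance and are reported as a degenerate-input
error rather than a p-value.

## The synthetic study

The generator emulates the statistical skeleton of lateralized MI: two
latent sources carry amplitude-modulated sinusoids with random phase and
carrier frequency inside 8–12 Hz; the favoured-class source has
`power_ratio` (default 4) times the band power of the suppressed one,
mirrored between classes. Sources are mixed into all channels by a random
orthogonal matrix (QR of a Gaussian matrix) on top of per-channel 1/f
Gaussian noise; `snr` (default 5) is the suppressed-source-to-noise power
ratio. Non-task trials superimpose 1–3 Gaussian-shaped low-frequency bumps
with 4× the source amplitude — an eye-blink surrogate that survives 7–30 Hz
filtering only partially, so the non-task class is separable but not
trivially so. Defaults were fixed once as a plausible desk-scale analogue
of a responsive BCI subject.

What the generator does **not** emulate: volume conduction from a head
model, non-stationarity across a session, correlated noise between
channels, realistic artifact morphology, or between-subject variability.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability of a planted contrast, not clinical-grade performance on
real EEG — on the synthetic defaults the fused predictor reaches
essentially zero cross-validated error, far below what real recordings
allow.

## Numerical choices and degenerate inputs

* **Rank-deficient covariances.** Common average referencing removes the
  constant channel direction, so the composite covariance is always
  singular by one. The CSP solver whitens in the principal subspace of
  `C̄₁ + C̄₂` (eigenvalues above 1e-10 of the largest), with a warning.
  A diagonal ridge was considered instead but rejected: it hands the null
  direction eigenvalue ≈ ½, which can still land among the selected
  trailing filters and produce a degenerate constant feature.
* **Variance floor.** Log-variance features floor the variance at 1e-12
  (with a warning) so the log stays finite on degenerate rows.
* **LDA shrinkage.** The pooled within-class scatter is shrunk toward its
  diagonal just enough to keep its condition number below 1e8 (training
  folds are small relative to the feature count).
* **Sign conventions and ties.** CSP eigenvector signs are fixed by
  making the largest-magnitude component positive; eigenvalue ties keep
  the solver's stable order; the LDA sign makes class 1 project high.
  These make retraining bit-reproducible.
* **Windowing.** With `S = 200`, `l = 50`, `t = 10` the fixed step
  `l − t = 40` cannot tile the trial exactly, so the last window is
  re-anchored to end at `S` (starts 0, 40, 80, 120, 150): every sample is
  used, no padding, deterministic `N`.
* **Divergence.** A non-finite training loss aborts LSTM training with an
  error naming the learning rate rather than returning garbage.
* **"100 iterations".** Training length is interpreted as 100 epochs
  (full passes), the stricter reading.

## Problem sizes

The bundled tests and the acceptance script run the full study at desk
scale, chosen as the package's own study conditions: 8 channels at 100 Hz,
2-s trials, 100 trials per class for the 10×10-fold cross-validated
two-class study, 20 MI trials per class plus 40 non-task trials for the
cascade, budget 25 for the optimizer benchmark, five seeds for the
ablation comparison. The compiled LSTM core fits one model (two layers,
100/20 units, 180 trials, 100 epochs) in roughly 2–3 s on one CPU.

## Known limitations

* Only the two-class (plus cascaded three-class) setting is implemented;
  joint multi-class CSP variants are out of scope.
* The LSTM architecture is fixed at two layers (100/20 units) — per-subject
  network-size search is deliberately not performed.
* Window length and overlap are not optimized per subject.
* The EDF writer/reader covers the plain continuous/epoch layout used
  here (16-bit quantization, labels in a reserved header field), not the
  full EDF+ annotation model.
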
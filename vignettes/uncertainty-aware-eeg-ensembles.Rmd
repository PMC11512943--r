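---
title: "Deep ensembles and uncertainty-aware epoch rejection for EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep ensembles and uncertainty-aware epoch rejection for EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegensemble)
```

## The problem

Subject-level binary classification from resting-state EEG — here phrased as
sex classification, with class 1 standing for "female" and class 0 for
"male" — is a convenient benchmark for EEG deep learning because the label is
binary and unambiguous. The pipeline this package implements runs from raw
multi-channel recordings to a cross-validated subject-level decision:

1. **Cleaning**: channels whose amplitude standard deviation exceeds
   75&nbsp;µV, or that show no amplitude variation at all, are excluded
   (`qc_channels()`, applied iteratively until a pass excludes nothing);
   recordings lose more than 30% of their channels are dropped outright
   (`reject_recording()`); surviving holes are filled by inverse-distance
   interpolation from the six nearest kept electrodes
   (`interpolate_channels()`); and a 1–45&nbsp;Hz zero-phase band-pass is
   applied (`bandpass()`).
2. **Segmentation**: the first 30&nbsp;s of each recording are discarded and
   role-dependent windows are cut into non-overlapping 2-second epochs
   (`segment_epochs()`); every other training epoch is removed to reduce the
   correlation between successive training instances
   (`thin_training_epochs()`).
3. **Models**: compact Inception-style and EEGNet-style convolutional
   networks (`model_spec()`, `build_model()`) are trained with Adam on
   binary cross-entropy for up to 50 iterations, with early stopping
   (patience 15 on the validation loss), a learning-rate scheduler (halving
   after 5 non-improving iterations from an initial 0.005), and retention of
   the minimum-validation-loss checkpoint (`train_model()`).
4. **Ensembles**: five construction strategies
   (`build_weight_ensemble()`, `build_depth_ensemble()`, `mcd_predict()`,
   `pool_models()`, `build_frequency_ensemble()`) produce a members × epochs
   probability tensor.
5. **Evaluation**: per-epoch accuracy, per-subject majority voting, the two
   ensemble aggregation orders (Ensemble-Subject: vote per member, then
   across members; Ensemble-Epoch: average per epoch across members, then
   vote), rank-based AUC, and five-fold stratified cross-validation with
   Student-t 95% confidence intervals (`make_folds()`, `rotations()`,
   `evaluate_tensor()`, `summarize_cv()`).
6. **Uncertainty**: the population variance of the member probabilities for
   each epoch scores the ensemble's disagreement; removing the p% most
   uncertain epochs and re-voting yields a rejection curve, and accuracy
   changes are summarized as relative error decreases
   (`epoch_variance()`, `reject_uncertain()`, `rejection_curve()`,
   `error_decrease()`, `summarize_error_decrease()`).

All tabular results are tibbles; fitted models support `tidy()`, `glance()`
and `autoplot()`.

## The synthetic cohort

No subject data ships with the package. `cohort_spec()` /
`generate_cohort()` produce a cohort whose class signal is spectrally
localized, which is exactly the structure the classifier stack is meant to
exploit:

* Each channel is a sum of six band-limited stochastic oscillations, one per
  canonical band (delta 0.5–4, theta 4–8, alpha 8–12, low-beta 12–20,
  high-beta 20–30, gamma 30–45&nbsp;Hz). An oscillation is white noise
  shaped into its band in the Fourier domain — random phase, flat in-band
  spectrum — and scaled to an exact target RMS. This keeps epochs
  stochastic (a pure tone would make the task trivial) while making the
  injected effect size exact.
* The RMS of band *b* for a subject of class *c* is
  `base_amplitudes[b] * band_effects[[b]][c + 1] * subject_factor`. Default
  base amplitudes fall from 20&nbsp;µV (delta) to 5&nbsp;µV (gamma),
  mimicking the 1/f-like decline of resting EEG and keeping clean channels
  well below the 75&nbsp;µV QC threshold once 5&nbsp;µV of broadband noise
  is added.
* The subject factor is log-normal with sigma 0.2 — enough between-subject
  amplitude variability that single epochs are not trivially separable, while
  a class multiplier of 1.5 remains recoverable at a 200-subject scale.
* A small fraction of channels (2% each by default) is flat (constant zero)
  or carries an extra 100&nbsp;µV of broadband noise, so the QC, rejection
  and interpolation rules have real work to do.
* Electrode positions are a Fibonacci lattice on the unit sphere: the real
  montage's exact coordinates are irrelevant to inverse-distance
  interpolation, only plausible relative distances matter.

What the generator deliberately does **not** model: ocular and muscle
artifacts, mains-line interference, volume conduction (channels are
independent), non-stationarity, and diagnostic heterogeneity. Passing tests
therefore demonstrate that the pipeline recovers spectrally localized class
structure under realistic amplitude variability and noise — not that any
particular accuracy would transfer to clinical recordings.

Cohorts round-trip to disk as EDF (one file per subject, 16-bit physical
scaling, verified against an independent EDF reader) or plain CSV, plus a
JSON sidecar and a `manifest.csv`.

## Numerical choices

* **Filtering.** The band-pass is a 6th-order Butterworth realized as
  analytically designed second-order sections and applied forward-backward
  (zero phase, so epoch boundaries suffer no phase distortion). Two
  non-obvious choices are deliberate. First, the transfer-function
  polynomial form is numerically unstable for narrow low bands (the delta
  band at 500 Hz has all 12 poles clustered near z = 1; expanding the
  polynomial produces NaNs), so poles are band-transformed and
  bilinear-mapped one conjugate pair at a time and never expanded. Second,
  order 6 rather than the more conventional order 4: a 60 Hz mains tone
  must fall below 5% RMS after the 1–45 Hz filter, and an order-4 zero-phase
  design only reaches ~7%. Edge transients are controlled by odd-reflection
  padding (up to 1000 samples per end).
* **Input scaling.** Microvolt-scale inputs saturate a Glorot-initialized
  network. Each trained model stores one global scale factor (the standard
  deviation of its training set) and divides all inputs by it; a single
  global constant preserves between-epoch amplitude differences, which are
  the class signal — per-epoch standardization would erase them.
* **Compact widths.** Default widths (8 filters per inception branch; an
  EEGNet stage of 4 temporal × 2 spatial filters) are deliberately small so
  the full cross-validated experiment runs on one CPU; width, depth, kernel
  lengths and the EEGNet block sizes are all configurable upward. Inception
  kernel lengths must be odd so the fused multi-kernel convolution aligns
  all branches on a common centre.
* **Determinism.** Everything stochastic — weight draws, minibatch order,
  dropout masks, fold assignment, cohort synthesis — flows from explicit
  integer seeds; rerunning any experiment with the same configuration
  reproduces its outputs bit for bit (single-threaded).
* **Ties.** Votes at exactly 0.5 go to class 1; tied majorities resolve by
  the mean probability against 0.5, then class 1. Variance ties during
  rejection keep the earlier epoch. Tied validation scores during
  frequency-band selection resolve in canonical band order.

## Design decisions on open points

* **"Iterative" channel QC** re-evaluates the exclusion rule until a pass
  excludes nothing. Because exclusion does not alter the surviving signals,
  this converges after one pass; the loop exists so the procedure matches
  its description and reports its iteration count.
* **Interpolation** is inverse-distance weighting over the k = 6 nearest
  kept electrodes rather than spherical splines. It preserves the
  properties the pipeline relies on — identity on kept channels, convexity
  (interpolated samples lie within the envelope of their donors), exact
  symmetry for equidistant donors — at a fraction of the complexity.
* **Rejection scope** is per subject by default: each subject loses its own
  p% most uncertain epochs, so subject-level voting always has that
  subject's most certain epochs to work with (`floor(p/100 * n)` removals
  can never empty a subject). Pooled ranking across the test set is
  available (`pooled = TRUE`); only pooled mode can empty a subject, in
  which case the subject falls back to its full-epoch prediction and is
  counted in `n_fallback`.
* **Frequency-ensemble inputs.** Members specialize on one band each, so at
  prediction time each member receives the test epochs filtered to its own
  band by default; `broadband_input = TRUE` gives every member the
  unfiltered epochs instead. Band selection uses validation per-subject
  majority-vote accuracy, the pipeline's headline metric.
* **AUC granularity** is epoch-level (scores pooled over the test fold);
  subject-level AUC can be computed by applying `auc_score()` to per-subject
  mean probabilities.
* **A caveat on the uncertainty procedure.** When ensemble disagreement is
  statistically independent of correctness, removing high-variance epochs
  leaves expected *per-epoch* accuracy unchanged — the property tests assert
  exactly that. Per-subject majority accuracy is *not* invariant even under
  label-agnostic removal: halving each subject's epoch count changes the
  majority vote's sampling error (a pure sample-size effect, easily verified
  with binomial tail sums). Rejection-curve improvements should therefore be
  read against the `p = 0` baseline of the same epoch budget with this in
  mind.

## Problem sizes used in the shipped experiments

The package's own verification runs are scaled to desk hardware and are
stated here as the package's reference conditions:

* Band recovery: 200 subjects, 8 channels at 100&nbsp;Hz, 70&nbsp;s per
  recording; class multipliers of 1.5 on alpha and low-beta; 20/20/40&nbsp;s
  train/validation/test extraction after the 30&nbsp;s discard (training
  thinned to 5 epochs per subject); depth-2 inception models with 2 filters
  per branch, kernels 7/15/31; up to 20 iterations at an initial rate of
  0.01, batch 256. Under these conditions band-restricted models on the
  informative bands reach ~80% per-subject accuracy while a zero-effect
  cohort stays statistically at 50%.
* The full-size protocol (129 channels at 500&nbsp;Hz, 1780 subjects,
  120/60/80&nbsp;s extraction, depth-4 models, 50 iterations at 0.005) is
  expressible with the same configuration objects and is spelled out in
  `?experiment_config`; it is not run by the shipped tests.

## Known limitations

* The conv-net engine is CPU-only, single-threaded R + BLAS; it is meant
  for compact models at desk scale, not for full-size replication.
* Channels are synthesized independently; spatial structure beyond electrode
  geometry is absent, so spatial filters (EEGNet's depthwise stage) have
  less to exploit than on real EEG.
* EDF export quantizes to 16 bits over each channel's observed range
  (relative error ~3 × 10⁻⁵), which is far below the noise floor but not
  bit-lossless; the CSV dialect is lossless to printed double precision.
* Only the variance of member probabilities is implemented as an
  uncertainty score; predictive entropy, mutual information and
  aleatoric/epistemic decompositions are out of scope.
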
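---
title: "Continuous wrist velocity decoding from surface EMG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous wrist velocity decoding from surface EMG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A multi-degree-of-freedom prosthetic wrist needs a continuous control
signal, not a menu of discrete gestures.  `wristvel` implements a
regression controller that maps a short window of 8-channel surface
electromyography (sEMG) directly to the instantaneous angular velocity of
one wrist degree of freedom — pronation–supination (PS; bulb twisting,
screwdriving) or the oblique dart-throwing motion (DTM; hammering,
drinking from a cup).  Velocities are in deg/s throughout; positive sign
follows the task's angle convention.

Because the controller must serve a *new* wearer quickly — and keep
working when electrodes shift, muscles fatigue or skin conditions change —
the package also implements a two-stage training protocol: a cohort-level
pre-training pass and a short per-subject adaptation ("quick training")
on a single trial of the new user.

## Signal path

1. **Envelope extraction.** Raw sEMG (2000 Hz) is full-wave rectified and
   low-pass filtered with a causal first-order Butterworth filter at 1 Hz
   (bilinear discretisation, zero initial state, unit DC gain).  Two
   choices deserve comment:
   * *Rectification first.* A 1 Hz low-pass applied to zero-mean raw sEMG
     would annihilate the signal; rectification before smoothing is the
     standard envelope construction, so it is the default, with
     `rectify = FALSE` available for literal filtering of the raw signal.
   * *Causal filtering.* The controller targets real-time use, so the
     filter is forward-only; no zero-phase (forward–backward) pass is
     offered in the pipeline.
2. **Standardisation.** A per-channel scaler (mean / standard deviation)
   is fitted on the *pre-training group only* and then frozen: the
   model-selection, quick-training and test groups are transformed with
   the same statistics.  Fitting is pooled across the pre-training
   subjects rather than per subject; with a single cohort-level model a
   single cohort-level scaler is the consistent choice.
3. **Windowing.** The envelope is cut into windows of 250 samples
   (125 ms) with an overlap of 240 samples (stride 10), giving features
   of shape (250, 8).  Each window is labelled with the joint velocity at
   its **final** sample: a causal convention — the controller outputs the
   velocity "now" from the preceding 125 ms — chosen because the
   alternative (window centre) would require future samples at run time.

## Kinematic labels

Joint angles are measured between two marker-defined 3-D vectors,
optionally projected onto a plane, signed by a reference direction, and
differentiated (central differences, one-sided at the ends) to deg/s.
Because marker conventions differ between laboratories, the vector pairs
are fully configurable (`vector_pair_spec()`); the shipped presets
`ps_default` and `dtm_default` follow the synthetic five-marker convention
written by the cohort generator and are documented as conventions, not as
facts about any particular capture setup.  Velocities can optionally be
smoothed with a causal first-order low-pass (raw differencing of
interpolated motion capture amplifies noise); the synthetic pipeline does
not need it and leaves it off.  Labels are linearly resampled from the
motion-capture rate (100 Hz by default; always carried explicitly because
capture rates vary) to the sEMG rate before windowing.

## The regressor

The network is an inception-block 1-D convolutional regressor.  Each
block applies, to a pointwise *bottleneck* projection of its input, three
parallel convolutions with distinct kernel lengths, plus a
max-pool-then-pointwise branch on the unprojected input; the four branches
are concatenated, batch-normalised and rectified.  A linear shortcut
(pointwise convolution + batch norm) joins the trunk every
`residual_period` blocks (default 3).  Global average pooling over time
feeds a linear dense head of size one; the training objective is mean
squared error.  Convolutions use "same" padding, which makes the network
length-agnostic; the published window length of 250 samples is the
deployment contract, not an architectural constraint.

Task-tuned configurations are shipped as presets: bulb — depth 5, kernels
(64, 16, 4), 128 filters, 30 pre-training epochs; screw — depth 8, same
kernels, 40 epochs; hammer — depth 4, 30 epochs; cup — depth 3, kernels
(128, 32, 8), 30 epochs; quick training is 30 epochs for every task.
Where the block internals are not pinned down by those parameters
(bottleneck width 32, residual period 3, batch-norm epsilon 1e-3), the
defaults follow the inception-time family of time-series models from
which the architecture derives.

### Numerical choices

* **Optimisation.** Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7), initial
  learning rate 1e-3, halved every 10 epochs.  Batch size 64 (not a
  protocol constant; 64 balances gradient noise against step count on
  cohort-scale window counts).
* **Label standardisation.** Targets are standardised (mean / sd of the
  *pre-training* labels, frozen thereafter) for optimisation and
  de-standardised inside `predict()`.  Velocities reach hundreds of
  deg/s; training the MSE objective on raw units forces the final dense
  layer to grow large weights through many small Adam steps, which shows
  up as systematic amplitude shrinkage (high correlation, poor RMSE).
  Standardising the target removes that artefact without changing the
  reported units.
* **Batch normalisation momentum 0.9.** Running statistics must
  re-estimate within the 30 short epochs of quick training on a new
  subject; the common 0.99 would leave them dominated by the pre-training
  cohort.
* **Model selection.** After every pre-training epoch the Pearson
  correlation on the model-selection trials is recorded and the
  parameters are snapshotted; the best-correlation snapshot (ties:
  earliest epoch) is the selected model.
* **Quick training.** All layers are fine-tuned (nothing frozen), with a
  fresh Adam state and the decay schedule restarted at 1e-3.  Restarting
  is a deliberate choice: carrying over the fully decayed rate would make
  30 adaptation epochs nearly inert.  Adam moments are reset for the same
  reason.
* **Weight initialisation.** Fan-in-scaled Gaussian initialisation with a
  caller-supplied seed; fixed seed plus fixed data reproduces the loss
  trajectory exactly.

## Evaluation

RMSE (deg/s) and Pearson correlation are the primary metrics; NRMSE and
R² are provided for cross-study comparison.  NRMSE has no universal
normaliser, so it is configurable (measured range — the default — mean,
or standard deviation) and reports must state the convention.  Per
subject, the two test trials are pooled into a single prediction series
(one RMSE/PC per subject); cohort averages are unweighted means over the
subjects present under each condition, and a subject missing under one
condition is excluded from that condition's average.  The comparison
report prints per-task averages under both conditions, the per-task
percent change of each average, and the cross-task mean percent change.

## The synthetic cohort

The study's human recordings are not publicly deposited, so the package
ships a generator that reproduces the *statistical structure* the method
relies on, at desk scale:

* **Kinematics.** PS trials are raised-cosine velocity pulses of
  alternating sign (twist and untwist; defaults 150 deg/s peak, 0.5 Hz);
  DTM trials are bipolar sine pulses (strike and return; 60 deg/s peak,
  1 Hz).  The PS velocity range deliberately exceeds the DTM range,
  mirroring the two task families' ranges of motion.  Angles are obtained
  from the closed-form integral of the velocity, so labels and kinematics
  are exactly consistent.
* **Muscle drives.** Two latent drives — agonist for positive velocity,
  antagonist for negative — lead the velocity by an electromechanical
  delay, and are mixed into 8 channels by a subject-specific 8×2 matrix
  (rectified-cosine tuning around the forearm plus a small crosstalk
  floor).  Two drives are the minimal structure that makes the channel
  pattern informative about *signed* velocity.  The lead defaults to
  100 ms, at the upper end of the physiological electromechanical-delay
  range; together with the ~160 ms group delay of the 1 Hz envelope
  filter this keeps the envelope approximately synchronous with the
  velocity it encodes, which is what makes a static (memoryless) decoder
  a meaningful recoverability oracle for the generator.
* **sEMG synthesis.** The latent envelopes amplitude-modulate band-limited
  (20–450 Hz) carrier noise, plus additive sensor noise (sd 0.05 on
  O(1) envelopes) and a per-trial lognormal vigour jitter (sd 0.05).
  Modulated carrier noise — rather than emitting envelopes directly —
  ensures the rectify + low-pass stage is genuinely exercised.
* **Domain shift.** Cohort subjects are drawn around a population
  template with dispersion proportional to `shift_severity`; subjects
  designated "new" additionally receive an electrode rotation of
  `round(2·severity)` channel positions, multiplicative gain jitter and
  an additive mixing perturbation.  Severity 0 is the identity.

What the generator does *not* emulate: motor-unit physiology, fatigue
dynamics within a trial, postural crosstalk, or the absolute error
magnitudes of real recordings.  Passing tests on synthetic cohorts show
that the pipeline, architecture and adaptation protocol behave as
designed under the stated statistical structure — not that any particular
RMSE would be attained on human data.

## Problem sizes used in the shipped experiments

The adaptation benchmark (`run_adaptation_benchmark()`) is a scaled-down
study chosen to keep a full three-seed replication at desk scale: 10
cohort subjects (9 fully pre-training, the 10th contributing trial 1,
with trials 2–3 as the model-selection group) plus 4 domain-shifted new
subjects at severity 0.5; PS trials of 2 repetitions (5 s); window stride
200 instead of the deployment stride 10 (overlapping windows are highly
redundant for training); a depth-2, 16-filter regressor with kernels
(16, 8, 4); 30 pre-training and 30 quick-training epochs; quick-training
batch size 16 so that a single short trial still yields several
optimisation steps per epoch.  Under these conditions quick training
reliably cuts the new-subject RMSE by well over the 15% margin asserted
in the test suite and raises the Pearson correlation.

## Known limitations

* The inception regressor is implemented natively (R with compiled
  convolution kernels); it is single-threaded BLAS-bound and sized for
  desk-scale experiments, not for GPU-scale cohorts.
* One model per task and per degree of freedom; no task classifier
  routes between them, and simultaneous multi-DoF output, while available
  through `output_dim`, is untested beyond the single-output default.
* Window sets and model checkpoints are stored as RDS containers (a
  single-file binary container native to R) rather than HDF5.
* The marker presets assume the generator's synthetic marker set; real
  capture sessions must supply their own `vector_pair_spec()`.
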
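---
title: "Methods: estimating valence and arousal from facial action units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating valence and arousal from facial action units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Dimensional models of affect describe emotional states as coordinates on
two continuous axes — valence (pleasant vs. unpleasant) and arousal (calm
vs. excited) — rather than as discrete categories. Facial muscle movements,
coded as FACS action units (AUs), carry systematic information about both
axes. `affectau` implements a pipeline that learns this mapping directly
from rated facial data: per-frame AU intensities, as produced by an
automated tracker in the OpenFace CSV dialect, are condensed into
one-second windows and fed to a recurrent regressor that outputs a rating
per second.

The pipeline has five parts: data ingestion and windowing (`read_au_table()`,
`select_peak_segment()`, `extract_window()`), separate GRU regressors for
valence and arousal (`build_estimator()`, `train_estimator()`,
`predict_rating()`), leave-one-participant-out evaluation with Fisher-z
inference (`run_loocv()`), drop-column feature importance
(`drop_column_importance()`), and a category/AU-based dimensional baseline
(`baseline_valence()`, `baseline_arousal()`). A seeded synthetic-data module
(`generator_spec()`, `generate_rated_episodes()`, `generate_session_like()`)
provides data with known ground truth so every stage is testable without
access to restricted recordings.

## Input representation

The model consumes 17 AU intensity features per frame (AUs 1, 2, 4, 5, 6,
7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 45, on the tracker's 0–5
intensity scale), always in ascending AU-id column order — a fixed order is
required for reproducible weights. Intensities are used raw; no
normalisation is applied by default, since the 0–5 scale is already
bounded and shared across features.

Each training or inference unit is one second of video reduced to five
frames sampled at equal intervals — target times `start + {0, 0.25, 0.5,
0.75, 1}` s, inclusive at both ends. Each target time is filled by the
nearest available frame, with ties going to the earlier frame. We sample
rather than interpolate: sampled rows keep authentic tracker outputs,
whereas interpolated AU values are combinations the tracker never
produced. Linear interpolation would be a reasonable alternative at low
frame rates. A target time with no frame within one median inter-frame
interval raises an insufficient-coverage error rather than silently
extrapolating.

For rated episodes that contain a neutral-to-expression-and-back
trajectory, the one-second training segment is the sliding window that
maximises the mean total AU intensity (the 17-AU sum averaged over frames
in the window), with ties broken toward the earliest start. "Most
prominently expressed" has no canonical operationalisation; total AU
intensity is the simplest monotone proxy for expression magnitude, and the
tie-break makes the choice deterministic. On the synthetic episode shape
(1 s onset ramp, 2 s hold, 1 s offset) any window inside the hold phase is
optimal and the earliest is returned.

Episode ratings live on an ordinal 1–5 scale; continuous sessions use real
ratings on 1–9. The affine conversion I' = 2I − 1 maps the former onto the
latter exactly (1→1, 3→5, 5→9) and is applied to training labels whenever
an estimator is built with `output_scale = "nine"`; its inverse
I = (I' + 1)/2 is exact, so the choice of training scale loses nothing.

## The regressors

Valence and arousal are estimated by two separately trained networks of
identical shape: a single GRU layer over the 5×17 input sequence followed
by one linear output unit, trained under a mean absolute error loss with
an Adam optimiser. The engine is implemented in compiled code
(`src/gru.cpp`) with a pure-R reference implementation kept in
`R/gru.R`; the test suite holds the two equal to machine precision and
verifies the analytic gradients against central finite differences.

Specific choices, where the published description is silent or ambiguous:

* **GRU variant.** The classic (v1) formulation with a single bias per
  gate; the parameter count is `3(dh + h² + h) + h + 1` for `d` inputs and
  `h` hidden units. The alternative `reset_after` convention differs only
  in a second bias vector and is immaterial at this scale.
* **Hidden width.** The published table of hyperparameters does not
  include the layer width. The default is 32 units, one layer: wide enough
  for 17-feature windows, small enough that a full leave-one-out
  evaluation runs on a desktop.
* **"Activation: none".** Interpreted as a linear (identity) candidate
  activation; the update and reset gates remain sigmoid, since replacing
  gate nonlinearities would break the gating semantics entirely. The
  valence model uses ReLU on the candidate, per its published setting.
* **Dropout semantics.** Inverted dropout with one input mask and one
  recurrent-state mask per sequence per minibatch, shared across the five
  time steps; the recurrent mask applies to the state as seen by the
  gates, never to the carry path.
* **Optimiser.** Adam with the configured learning rate and standard
  moment constants (0.9/0.999); the published description names a
  Keras-style stack with "default settings" for everything beyond the
  printed table.
* **Output clipping.** Predictions are clipped to the output scale's
  bounds (1–5 or 1–9) after inference. Whether the original model clipped
  is unstated; clipping only ever moves a prediction toward the attainable
  label range.
* **Determinism.** A training call is a pure function of (data, config,
  seed): initialisation, shuffling and dropout masks are all drawn from
  the seed, and inference uses no randomness.

The per-target default hyperparameters are the published optima (valence:
ReLU, dropout 0.530, recurrent dropout 0.266, learning rate 1.23e-5,
batch 48; arousal: linear, 0.680, 0.301, 1.01e-5, batch 32; both 100
epochs, MAE loss). One practical caveat is documented here deliberately:
an Adam-family update moves each parameter by at most roughly the learning
rate per step, so a learning rate of ~1e-5 displaces a freshly initialised
network by at most a few thousandths over a few hundred minibatch updates.
The desk-scale experiments in this package (hundreds of episodes, tens of
epochs) therefore use an experiment-level learning rate of 1e-2 with 30
epochs — chosen from that bound a priori, not tuned — while keeping the
published architecture, dropout rates and batch sizes. The published rates
remain the package defaults for full-scale runs.

## Evaluation

Evaluation is leave-one-participant-out: for each fold, both regressors
are retrained from scratch on all other participants (the fold seed is
`seed + fold_index`, so folds are independent yet reproducible) and the
held-out participant's episodes are predicted. Per participant we report
the Pearson correlation between actual and predicted ratings, pooling all
of that participant's episodes. Correlations are Fisher-z transformed
(`z = atanh r`) and tested against zero with a one-sample t-test
(`t = mean/(sd/√n)`, `df = n − 1`, Cohen's `d = mean/sd`); p-values are
two-sided, the conservative choice when sidedness is unreported. Paired
comparisons between two estimators reduce to the one-sample test on
element-wise z differences. A participant whose actual ratings are
constant has no defined correlation; such participants are flagged with a
warning and excluded from inference rather than being assigned r = 0,
which would bias the group mean toward zero.

## Drop-column importance

The contribution of each AU is measured by retraining the model without
that column — true removal, input width 16, not zero-masking — and
comparing mean absolute prediction error with the full model's under an
identical protocol and seed policy. The reported score is the relative
fluctuation rate `(error_without − error_full) / error_full`: positive
means removal hurts (the AU is informative), negative means removal helps
(the AU behaves as noise), and magnitudes are comparable across targets
because the normalisation removes the error scale. Scores are a total map
over the 17 AUs and are deliberately not normalised to sum to one.

Error can be measured by full LOOCV (faithful, 18× training cost) or by a
participant-level holdout split (default fraction 0.25), the documented
fast protocol. Because single retrainings of near-uninformative columns
fluctuate by a few percent, the importance runs average errors over
several seeds (five in the recovery experiments) before normalising;
whether the original analysis retrained once or averaged is unknowable
from its description, and averaging is the variance-reducing choice.

## The dimensional baseline

The comparison baseline converts the outputs of category-based expression
analysis into dimensional scores. Valence of a frame is the intensity of
*happy* minus the intensity of the strongest negative category among
*sad*, *angry*, *scared* and *disgusted* (0.8 happy against a strongest
negative of 0.3 gives 0.5); *surprised* and *neutral* are treated as
valence-neutral, exactly the four negatives of the published worked
example. Arousal uses a 19-item activation set (AUs 1–27 as enumerated,
plus one minus the AU 43 eye-closure activation, all on [0, 1]): each
activation is corrected by subtracting its mean over the trailing 60 s —
over all history while fewer than 60 s have elapsed — and arousal is the
mean of the five highest corrected values. The description of this scheme
says "20 AU values" but enumerates 19; the enumerated 19 are implemented.
The rolling window is time-based and half-open, `(t − 60, t]`, at the
series' native sampling rate; no clamping is applied to arousal, leaving
that to consumers. Corrected activations are exactly invariant to constant
shifts of the input over a constant-shifted window, and at the first frame
the correction is identically zero — both properties are asserted in the
tests.

## Synthetic data

The generator emulates the structure of the two study designs without
modelling faces. Rated episodes: each participant contributes exactly 25
four-second episodes covering every combination of valence and arousal
levels 1–5; an episode's AU trajectory is
`baseline + ramp(t)·(E·(v−3, a−3) + participant_effect) + noise`,
where `ramp` rises linearly over the first second, holds at one for two
seconds and falls over the last second, `E` is a 17×2 effect matrix,
`participant_effect` is a per-participant per-AU normal offset, and
`noise` is i.i.d. Gaussian per frame. Negative intensities are truncated
at zero (resampling would distort the noise distribution more); at the
default noise level the induced bias is small and is accepted. Continuous
sessions: smooth latent valence/arousal trajectories on 1–9 (three
low-frequency sinusoids around a midpoint of 5) drive the same emission
model through the exact inverse of the rating conversion, with one window
per second and stored ratings equal to the latent value at the window
centre plus Gaussian rating noise, clipped to [1, 9].

Defaults: 24 participants, AU baseline 0.5, frame-level noise sd 0.3,
participant sd 0.2, rating noise sd 0.2, 30 fps. The effect matrix plants
coefficients of magnitude 0.4 on four AUs per target (valence: +AU12,
+AU1, +AU6, −AU4; arousal: +AU4, +AU6, +AU7, +AU17), mirroring the
qualitative pattern of AU contributions recovered from real data, so that
importance-recovery tests have a meaningful planted answer.

What the generator does not emulate: AU co-occurrence constraints of real
facial anatomy, tracker failure modes (dropped frames, confidence dips,
identity swaps), inter-AU noise correlation, and nonlinear or lagged
affect–AU relationships. Passing recovery tests therefore demonstrates
that the pipeline recovers a planted linear mapping under Gaussian noise —
a necessary condition — not that it attains any particular accuracy on
real faces.

## Experiment sizes and numerical choices

The recovery experiments run leave-one-out over 24 participants × 25
episodes (600 windows) with 30-epoch trainings, and the importance
experiments use 12 participants with a 0.25 participant-level holdout and
five retraining seeds per column; both complete on a single CPU core in a
few minutes and give stable verdicts (LOOCV mean r ≈ 0.88–0.95 noisy,
> 0.97 noiseless; planted-column importance ≈ 0.3 against noise columns
≤ 0). Ties in nearest-frame selection and in peak-segment scoring resolve
to the earlier frame/start; timestamp comparisons use a 1e-9 s tolerance;
correlations are refused (not zeroed) for degenerate series; the Fisher
transform rejects |r| ≥ 1.

## Limitations

The package ships no trained weights and makes no claims about accuracy
on real facial data; the restricted datasets the original experiments
used are not included, so reported correlations and t-statistics from
those data are out of reach by design. The GRU width, layer count and
optimiser identity are package choices where the published description is
silent, and the desk-scale learning rate documented above is an
experiment-design choice, not a published value. The baseline module
implements only the dimensional arithmetic; it does not reproduce any
commercial system's category classifiers or face tracking.
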
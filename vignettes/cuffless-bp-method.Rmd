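---
title: "Cuffless blood-pressure estimation with a shallow 1-D U-Net feature extractor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation with a shallow 1-D U-Net feature extractor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Continuous, cuff-free blood-pressure monitoring asks for a mapping from
optically and electrically measurable waveforms — the photoplethysmogram
(PPG) and the electrocardiogram (ECG) — to the arterial blood pressure
(ABP) that only an invasive or cuff-based device observes directly. bpunet
implements a two-stage approach:

1. **Feature extraction.** A shallow one-dimensional U-Net is trained as a
   cross-modality autoencoder: predictor channels in, ABP waveform out.
   Because the target is the pressure waveform itself rather than two
   scalar labels, the encoder is pushed to represent everything about the
   input that matters for pressure. A dense layer inserted at the U-Net
   bottom (after flattening the pooled feature map) is read out as an
   `n_features`-dimensional per-segment feature vector.
2. **Regression.** Classical regressors — an Adam-trained ReLU MLP by
   default; k-NN, SVR, linear SGD, AdaBoost.R2, gradient boosting,
   XGBoost and random forest as alternatives — map those features to
   per-segment systolic and diastolic pressure (SBP/DBP), one model per
   target.

Estimates are scored with the field's standard instruments: mean absolute
error, the British Hypertension Society's cumulative-error grades
(percentage of absolute errors at or below 5/10/15 mmHg; all three
thresholds of a grade must hold), the AAMI compliance rule
(|mean error| <= 5 mmHg, error SD <= 8 mmHg, at least 85 subjects),
least-squares agreement and sample Pearson correlation, and Bland–Altman
95% limits of agreement at mu +/- 1.96 sigma.

## Signal conditioning

Segments are synchronized 1024-sample triplets at 125 Hz (8.192 s). The
front end applies, in order:

* **Baseline-wander removal.** Peaks of the raw trace give the median
  inter-peak distance `d`; a moving minimum with window `d` estimates the
  drifting baseline; a polynomial fit of that estimate is subtracted; the
  result is shifted to minimum 0 and rescaled to the input range. Two
  numerical guards depart deliberately from the naive transcription of
  this recipe: the polynomial order, nominally `round(d)` (which would be
  near 90 for cardiac beats — unusable), is capped at `order_cap = 8` and
  fitted on an orthogonal basis; and a constant segment short-circuits
  with a `degenerate` flag instead of dividing by zero. When fewer than
  two peaks exist, the signal itself is fitted with the fallback order
  (default 6). For the pressure channel the default mode subtracts only
  the zero-mean component of the fitted baseline: the verbatim scheme pins
  the corrected minimum at 0, which would destroy the absolute mmHg level
  that the labels are extracted from.
* **Label extraction.** Per-segment SBP is the mean systolic-peak height
  and DBP the mean diastolic level across inter-beat intervals
  (`"peak-mean"`; `"extrema"` takes the segment max/min). Two estimator
  details keep the labels unbiased under noise: the trace is lightly
  smoothed with a Savitzky–Golay filter (order 3, window 9) before
  delineation, because extrema measured on a noisy trace ride the noise
  excursions; and the diastolic level of each interval is the mean of its
  bottom decile rather than its minimum, because the diastolic phase is a
  plateau whose level an extreme order statistic systematically
  underestimates. MAP is `DBP + (SBP - DBP)/3`.
* **Quality screening.** A segment is rejected if any rule fails, in
  order: blank channel; SBP outside [80, 190]; DBP outside [50, 120];
  pulse pressure outside [20, 120] (all inclusive); peak-height standard
  deviation above 0.10 on the unit-range-normalized signal; peak-interval
  standard deviation above 0.12 after dividing intervals by their median;
  beat count outside [4, 25]. The uniformity thresholds were never
  published — the source study tuned them by eye — so they are calibrated
  here against the synthetic generator: the defaults sit several-fold
  above the clean cohort's upper tail and below the bulk of every
  injected distortion class; the separation achieved (sensitivity and
  specificity on a 500-record draw) is computed by the acceptance
  checks.
* **Derivative channels.** Velocity and acceleration PPG (VPG/APG) are the
  first differences of the normalized PPG (per-sample `dt`), band-pass
  filtered and unit-range normalized. The filter is a linear-phase FIR
  (51 taps, window design, pass band 0.5–10 Hz at 125 Hz) so the group
  delay is exactly 25 samples; VPG is shifted by one delay and APG by two,
  and the PPG is trimmed by two delays, leaving three mutually aligned
  1024-sample channels. Segments are therefore ingested with a margin of
  `2 x 25` samples; an exact-1024 segment can instead be reflection-padded
  (`margin = "reflect"`). The band edges are configurable; the defaults
  pass the cardiac fundamentals and first harmonics while killing
  sub-cardiac drift and differentiation noise.
* **Normalization.** Predictor channels are z-scored then affinely mapped
  to [0, 1] per segment (numerically identical to `(x - min)/range`, and
  tested against that closed form). The pressure target is divided by one
  global constant — the maximum of the training partition's ABP waveforms —
  so segments keep their relative amplitudes; amplitude *is* the pressure
  information. Computing the divisor on the training partition only (rather
  than the whole corpus) avoids test-set leakage; a frozen context can be
  supplied to reproduce the strict whole-corpus convention.

## The network

`unet_config()` spans the architecture grid: depth 1–4, first-level width
32–256, odd kernels 1–11, 1–4 input channels (stacking order PPG, VPG,
APG, ECG), bottleneck sizes up to 2048, ABP or PPG target, and
transpose-conv or nearest+conv upsampling. Blocks use two same-padded
convolutions with ReLU and no batch normalization; pooling halves the
length per level; the decoder mirrors the encoder with skip
concatenation; a linear 1x1 convolution emits the output. The pinned
shallow layout (depth 1, width 128, kernel 3, 4 channels) pools to a
512 x 128 map, prices the 1024-unit feature layer at
512 x 128 x 1024 = 67,108,864 weights, and has a 559,873-parameter
convolutional backbone; `count_parameters()` computes these closed-form
and is tested against the built models.

Two design points were genuinely open:

* **How the decoder resumes after the dense bottleneck.** The flattened
  map goes through `dense(n_features)` and a dense back-projection to the
  pooled shape before the bottom convolution block. The back-projection is
  an acknowledged addition — the quoted bottleneck size prices only the
  first dense layer — so parameter reporting keeps them separate.
* **Whether features are read pre- or post-activation.** The default
  bottleneck is linear (identity activation, features are the dense
  layer's values); `feature_activation = "relu"` gives the rectified
  variant. The rectified bottleneck can die at small training scale: the
  skip connections carry the reconstruction loss, gradient pressure on the
  bottleneck vanishes, and its units fall silent one by one until almost
  none remain. A linear bottleneck cannot die and leaves
  the rest of the architecture unchanged, so it is the default;
  at corpus scale with the rectified variant the monitored behaviour
  should be checked before extracting features.

Training follows the published setup: batch 64, up to 100 epochs,
patience 15, MSE loss, Adam (step size 1e-3, standard moment decays),
validation MAE monitored on a seeded random 20% split, best-epoch weights
restored. A fixed seed pins the split, the He initialization and the batch
order, making reruns bit-reproducible. The engine underneath is written in
R on BLAS matrix primitives: im2col convolutions and explicit,
hand-derived backward passes for every layer. `patience = 0` trains
exactly one epoch.

## The synthetic generator

`generate_segments()` provides ground-truth-labelled PPG/ECG/ABP triplets
so every stage is testable without clinical data. Per record it draws a
heart rate (uniform 50–90 bpm) and truncated-normal labels with the
large-corpus moments (SBP 132.609 +/- 21.703, DBP 63.705 +/- 9.978 mmHg,
truncated to [80, 190] / [50, 120], pulse pressure forced into
[20, 120]), then renders:

* **ABP** as `DBP + PP * shape(phase)` where the single-peaked beta-like
  beat shape is normalized so the waveform extrema hit the drawn labels
  exactly (recovery within 0.5 mmHg at zero noise);
* **PPG** as a morphologically coupled pulse: its amplitude grows strictly
  with pulse pressure, and its shape exponents move with SBP and DBP, so
  pressure information survives per-segment normalization — without such a
  morphology link nothing could be learned from normalized PPG at all;
* **ECG** as an R-spike train with small P/T bumps leading the PPG by a
  0.25 s pulse-transit offset;

plus white noise at 2% of the pulse amplitude, optional sub-cardiac
sinusoidal drift, and, for a configurable fraction of records, a labelled
corruption (double peaks, ±50% per-beat height jitter, ±50% beat-interval
warping, or blanking) emulating the distortion classes the screen must
catch. Segments are 1074 samples (1024 plus the filter margin) at 125 Hz.

What the generator does *not* emulate: real pulse morphology (dicrotic
timing, reflection waves), sensor-specific noise spectra, motion
artifacts, arrhythmias, or genuine inter-subject variability. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that the two-stage pathway transports pressure information end to end —
not that clinical-grade accuracy is attained on real recordings.

## Scaled-down study conditions

The heavy checks run at sizes chosen to finish on a single CPU while
leaving the conclusions readable: the end-to-end check trains the quick
profile (depth 1, width 32, kernel 3, one PPG channel, 128 features) on a
2000-record draw for up to 6 epochs and requires held-out SBP MAE at
least 30% below the predict-the-training-mean baseline; the oracle and
property loops use 500–2000 cases each. The published corpus-scale results
(SBP/DBP MAE of 2.333/0.713 mmHg on ~200k clinical segments after
100-epoch training of the width-128 model) are out of desk-scale reach by
design; the package reproduces the *method*, its worked-example
arithmetic, and the direction and rough magnitude of its behaviour on
synthetic data.

## Numerical choices and degenerate inputs

* Peaks: strict local maxima; a plateau contributes its first sample;
  prominence is height above the higher of the two flanking minima
  (edge-bounded). Beat-peak detection uses a prominence floor of 0.1 of
  the unit range to suppress dicrotic double counting.
* Resampling uses a zero-phase FIR anti-aliasing low-pass (cut at 80% of
  the target Nyquist) before grid decimation/interpolation, so
  down-sampled channels stay phase-synchronized.
* Sample indexing is 1-based throughout, the R convention; timestamps are
  `(index - 1) / fs` seconds.
* Constant inputs: baseline correction returns them unchanged with a
  `degenerate` flag; unit-range normalization refuses them; derivative
  computation returns zero channels and flags the segment, which the
  pipeline routes to rejection.
* Ties in max pooling route the gradient to the first sample, mirroring
  the peak-plateau convention.
* Store round-trips are bit-exact: channel matrices are written as text
  with `%.17g` and parsed with the correctly rounded base reader.

## Known limitations

* The MAT/HDF5 containers used by the clinical corpora are not read
  directly; stores are plain CSV directories (`read_store()`), and
  external corpora are expected to be converted to CSV matrices first.
* The in-R network engine is single-threaded BLAS; it is sized for the
  desk-scale profiles, not for corpus-scale training.
* Non-MLP regressor hyperparameters follow their libraries' defaults,
  recorded in the fitted object for provenance; no hyperparameter search
  is included.
* Five-fold cross-validation and cross-corpus transfer are supported by
  composing `preprocess_segments()` with frozen normalization contexts,
  but no dedicated orchestration beyond the seeded record/subject split is
  shipped.
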
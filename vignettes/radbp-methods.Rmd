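---
title: "Contactless radar blood-pressure estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless radar blood-pressure estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbp)
```

## The problem

A continuous-wave radar pointed at the chest measures sub-millimetre wall
displacement through the phase of its reflected carrier. That displacement
superimposes respiration (millimetres, below ~0.5 Hz), cardiogenic
micro-vibrations (tenths of a millimetre, 0.5–15 Hz) and noise. Because the
cardiac pulse that shakes the chest wall is driven by the arterial pressure
pulse, the micro-vibration waveform carries information about systolic (SBP)
and diastolic (DBP) blood pressure. `radbp` implements a complete
estimation pipeline from raw radar I/Q to clinically graded SBP/DBP
predictions, together with a co-simulator that makes every stage testable
without any external recording.

## Signal model and preprocessing

Displacement is recovered by arctangent demodulation,
`d(t) = unwrap(atan2(Q, I)) * lambda / (4 pi)`. The cardiac band is isolated
with a bidirectional (forward–backward, hence zero-phase) 4th-order
Butterworth band-pass, 0.5–15 Hz, then the series is reduced to 150 Hz for
the learning stages. Within each analysis window a linear trend
`x_i = alpha0 + alpha1 t_i + xi_i` is removed by ordinary least squares,
the second-order central difference
`(y[n+1] - 2 y[n] + y[n-1]) / Ts^2` forms an acceleration-like second
channel (first and third derivatives are available as ablations), and each
channel is L2-normalized. The pipeline order is fixed: demodulate,
band-pass, resample, segment, detrend, derivative, normalize.

Numerical choices worth knowing:

* **Second-order sections.** At a 2000 Hz sampling rate the 0.5 Hz corner
  sits at 2.5e-4 of the sampling rate; expanding the order-4 band-pass into
  a single transfer function is numerically degenerate (its rooted poles
  fall outside the unit circle in double precision). The package therefore
  designs the Butterworth analytically — analog prototype, band transform,
  bilinear transform — and filters as a cascade of biquads. The
  forward–backward pass uses odd-reflection padding of three filter lengths
  at each edge.
* **Resampling.** 2000 to 150 Hz is the non-integer ratio 40/3. The package
  applies a zero-phase order-8 Butterworth anti-alias low-pass at 45% of
  the target rate and evaluates the band-limited series on the target grid
  by interpolation; the band-limited content (≤ 15 Hz against a 2000 Hz
  grid) makes the interpolation error negligible, and a 1 Hz probe tone is
  preserved to well within 2% amplitude.
* **Detrending regressor.** The trend is fit against the sample index; the
  slope's units cancel in the residual, which is all later stages see.
* **Guard interval.** 0.25 s is trimmed from each record edge before
  windowing to discard demodulation and filter transients. The length is a
  package choice, exposed in `prep_config()`.

## Labels, windows and splits

Systolic peaks are detected on the reference pressure waveform as local
maxima with at least 0.33 s separation and 10 mmHg topographic prominence;
the diastolic trough is the minimum between consecutive peaks. Beats with
any value above 180 mmHg or below 40 mmHg are flagged as outliers. Windows
of 2 s are anchored at the first valid systolic peak and tiled without
overlap; a window's label is the mean SBP/DBP of the valid beats whose
peaks fall inside it (means are the least-variance unbiased aggregate for
multi-beat windows), and windows touching an invalid beat, or containing no
complete beat, are dropped. Two seconds of window and no overlap give 30
estimates per minute of usable signal.

The dataset splits 65/15/20 into train/validation/test. The default is a
seeded window-level shuffle; a subject-level mode that keeps each subject's
windows in a single partition is equally supported, because "no overlap
between groups" can legitimately be read either way. Window-level splits
share subjects across partitions and therefore measure within-cohort
accuracy; subject-level splits measure generalization to new subjects and
are the harder task.

## The two-stage regressor

**Stage 1** is a 1D adaptation of an 18-layer residual network: stem
convolution (kernel 7, stride 2), max pooling, four stages of basic blocks
`y = F(x, W) + x` (kernel 3; batch normalization; 1x1 strided projection on
the skip path where shape changes), global average pooling, then two heads.
Each head emits a feature vector (`F_S`, `F_D`; width `feature_dim`) and a
dense preliminary estimate (`y_S`, `y_D`, mmHg). A shared trunk with two
heads is the default (halving compute while keeping the feature sets
distinct); kernel sizes follow the standard 2D design since the source
architecture's 1D kernel sizes are not prescribed anywhere.

**Fusion** exploits the strong systolic–diastolic coupling (the generator's
drift processes are correlated ~0.7 by default, matching clinical
observations): the systolic stage-2 input appends the *diastolic*
preliminary estimate to the systolic features, `X_S = [F_S, y_D/200]`, and
vice versa. The 1/200 scaling brings mmHg values to the magnitude of the
unit-norm features. The no-fusion ablation uses `X_S = F_S`.

**Stage 2** is an encoder–decoder transformer per pressure stream: linear
input embedding, sine–cosine positional encoding, encoder layers of
multi-head self-attention and position-wise feed-forward sublayers with
residual connections and layer normalization, and a decoder with causally
masked self-attention plus cross-attention to the encoder output. The
decoder input is a learned start token followed by the stream's own
embedded preliminary estimates shifted right one position — ground-truth
labels are never fed to the decoder, so no label can leak into prediction.
A linear head emits one refined estimate per position.

Two design points deserve emphasis:

* **Per-stream instances.** One transformer consumes `X_S` sequences and
  predicts SBP; an identically configured one consumes `X_D` and predicts
  DBP. Concatenating both streams into a single network would hand each
  output the other stream's features directly, making the appended cross
  estimate redundant and the fusion ablation meaningless; keeping the
  streams separate makes the cross-coupled estimate the *only* conduit
  between them, which is precisely what the fusion mechanism claims to
  exploit.
* **Sequences.** Stage 2 consumes runs of `sequence_len = 8` consecutive
  same-subject windows, built within each data split (never across split
  boundaries, which would leak). During training the trailing partial run
  is dropped; at prediction time it is padded by repeating the last window
  so every window receives an estimate.

All forward and backward passes are implemented in package code as explicit
matrix operations, and every layer's analytic gradient is verified against
central finite differences in the test suite.

## Training regime

Both stages minimize the Pseudo-Huber loss
`delta^2 (sqrt(1 + (a/delta)^2) - 1)` — quadratic for small errors, linear
for large ones — with `delta = 5` mmHg, the scale of the clinically
tolerated mean error (the scale parameter is a package default, exposed in
`train_config()`). Optimization is Adam with decoupled weight decay 0.002
applied to weight matrices, initial learning rate 0.001 halved whenever the
validation loss fails to improve for 5 consecutive epochs, early stopping
after 10 stalled epochs, at most 60 epochs, batch sizes 32 (stage 1) and 4
(stage 2). The output heads are initialized at the training label means so
optimization starts from an unbiased predictor. Stage-1 weights are frozen
before stage 2 trains, and the test split never touches any fitting or
scheduling decision. Systolic and diastolic loss terms are unweighted.

One scheduler subtlety: the learning rate halves when the count of
consecutive non-improving epochs *reaches* the patience, so a constant
validation stream yields the first halving at the sixth epoch.

## The co-simulator

`simulate_subject()` generates what the pipeline assumes about real data:

* a per-subject baseline heart rate (55–95 beats/min) with a slow random
  walk; beat times snapped to the pressure grid;
* SBP/DBP per-beat processes: bounded random walks (0.5 mmHg/beat) with a
  shared component tuned to a step correlation of 0.7;
* chest displacement = respiration sinusoid (2 mm at 0.25 Hz) + a
  raised-cosine cardiac pulse per beat, width 0.3 of the beat interval,
  amplitude `pulse_amp_gain * (SBP - DBP)` — a strictly increasing map from
  pulse pressure to displacement, which is the link a regressor can
  exploit — + white noise; wrapped into I/Q as `cos/sin(4 pi d / lambda)`
  with a 12.5 mm (24 GHz) carrier;
* a pressure waveform rising linearly to SBP over 15% of each beat and
  decaying exponentially to DBP (time constant one sixth of the decay
  span, so the sampled trough sits within ~0.2 mmHg of the truth);
* scenario labels: apnea zeroes the respiration amplitude; valsalva/tilt
  add a transient ±20 mmHg ramp mid-record. These are labelled emulations
  of maneuver-like excursions, not hemodynamic models.

Because every window is L2-normalized, absolute pulse amplitude survives
only through the pulse-to-noise-floor ratio; the default displacement noise
(0.02 mm at rest; 0.1 mm in the end-to-end training study, against a
strong 0.02 mm/mmHg coupling) keeps that ratio informative. What the
simulator deliberately does **not** model: electromagnetic propagation,
antenna patterns, body-motion artifacts, radar front-end imbalance, CNAP
device artifacts, or any realistic pulse-wave morphology. Consequently,
passing tests demonstrate that the pipeline's mechanics are correct and
that it extracts a planted displacement–pressure link under drift and
noise — they say nothing about accuracy on clinical recordings.

## Validation suite

Reported metrics are `ME = mean(y - yhat)`, `MAE`, `RMSE`,
`MRE = mean(|y - yhat|/y) * 100`, and the sample SD of the error.
BHS grading computes cumulative frequencies of absolute errors strictly
below 5/10/15 mmHg and awards the best grade whose three thresholds
(A: 60/85/95, B: 50/75/90, C: 40/65/85, compared inclusively) are all met.
The AAMI check passes when |ME| ≤ 5 mmHg (inclusive) and SD < 8 mmHg
(exclusive). Bland–Altman limits of agreement are the mean difference
(prediction minus reference) ± 1.96 sample SD. A cumulative-frequency
triple of (51.20, 77.58, 88.93) fails B's 90% requirement and grades C
under these thresholds; the grader never special-cases such rows.

## Study sizes used by the shipped tests

The test suite and the acceptance script run entirely on simulated data at
desk scale: a 10-subject cohort of 5-minute records (~1470 windows) with
strong displacement–pressure coupling, reduced model widths (stem width 8,
feature width 64, transformer width 32) and 10 training epochs, with the
ablation comparison averaged over three seeds. These sizes were chosen as
the smallest study at which the learned pipeline separates cleanly from
the training-mean baseline; accuracy at clinical scale is out of scope for
synthetic data.

## Known limitations

* The simulator's morphology is deliberately simple; models trained on it
  will not transfer to real radar.
* Window-level splitting shares subjects between train and test; use
  subject-level mode for generalization claims.
* The per-beat pressure waveform is piecewise linear/exponential, so beat
  detection on it is easier than on CNAP traces with dicrotic notches.
* Stage-2 sequences are built within splits; with window-level splits the
  "consecutive" windows of a sequence may be non-adjacent in raw time.
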
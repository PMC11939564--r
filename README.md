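# radbp

Contactless blood-pressure estimation from continuous-wave radar chest
micro-vibrations, for researchers in non-contact physiological monitoring
and biomedical signal processing. The package implements the full chain —
radar phase demodulation, cardiac-band preprocessing, pressure-anchored
windowing and labeling, a cascaded deep regressor, and the clinical
validation suite — together with a seeded radar/pressure co-simulator so
that every stage is testable without any external recording.

## The method

**Preprocessing.** Chest displacement is recovered from the radar
quadrature channels by arctangent demodulation,
`d(t) = unwrap(atan2(Q, I)) · λ/(4π)`, band-limited to 0.5–15 Hz with a
bidirectional (zero-phase) 4th-order Butterworth filter, and resampled to
150 Hz. Each 2 s analysis window is detrended by the OLS fit
`x_i = α₀ + α₁ t_i + ξ_i`, augmented with its second-derivative channel
`y″[n] = (y[n+1] − 2y[n] + y[n−1])/Ts²`, and L2-normalized. Windows are
anchored at systolic peaks of the reference pressure wave and labelled with
the mean SBP/DBP of their beats; beats outside 40–180 mmHg are rejected.

**Two-stage regressor.** Stage 1 is a 1D residual network (18-layer
configuration, `y = F(x, {Wᵢ}) + x` basic blocks) producing per-window
feature vectors `F_S`, `F_D` and preliminary estimates `y_S`, `y_D`.
Cross-coupled fusion appends the *diastolic* estimate to the systolic
features (`X_S = {F_S, y_D}`) and vice versa, exploiting the strong
SBP–DBP correlation. Stage 2 is an encoder–decoder transformer per stream
(sine–cosine positional encoding, scaled dot-product multi-head attention
`softmax(QKᵀ/√d_k)V`, position-wise FFN, layer normalization, causally
masked decoder) over sequences of 8 consecutive windows, emitting refined
per-window SBP/DBP. Training minimizes the Pseudo-Huber loss
`δ²(√(1+(a/δ)²) − 1)` with Adam, decoupled weight decay 0.002, plateau LR
scheduling (×0.5 after 5 stalled epochs) and early stopping. All network
forward/backward passes are implemented in package code and
gradient-checked against finite differences in the tests.

**Validation.** ME/MAE/RMSE/SD/MRE, BHS cumulative-frequency grading
(A: 60/85/95% of |errors| under 5/10/15 mmHg; B: 50/75/90; C: 40/65/85),
the AAMI criterion (|ME| ≤ 5 mmHg, SD < 8 mmHg), Bland–Altman limits of
agreement (mean difference ± 1.96 SD), and regression statistics.

## Worked example

```r
library(radbp)

rec <- simulate_subject(sim_config(duration_s = 60, seed = 42))
rec
#> <subject_record> S01: 60 s radar @ 2000 Hz, pressure @ 200 Hz, 93 beats, scenario 'rest', seed 42

pre   <- preprocess_record(rec)
beats <- detect_beats(pre$bp)
seg   <- segment_windows(pre$rcmv, pre$bp, beats, prep_config(),
                         subject_id = "S01")
seg$windows
#> <window_set> 29 windows of length 300, 1 subject(s)
```

A 60 s record yields 29 complete 2 s windows after the first systolic
anchor — one estimate every 2 s, i.e. ~30 readings per minute. Scoring a
predictor (here the true labels plus simulated errors of mean −1, SD 4
mmHg) against the labels:

```r
set.seed(1)
pred  <- seg$windows$sbp + rnorm(n_windows(seg$windows), -1, 4)
rep_s <- validation_report(seg$windows$sbp, pred)
rep_s$metrics
#> ME 0.72  MAE 2.90  RMSE 3.76  SD 3.75 mmHg  MRE 2.69%  (n = 29)
rep_s$bhs$grade        # "A"  (cumulative 82.8 / 100 / 100 %)
rep_s$aami$pass        # TRUE (|ME| <= 5, SD < 8)
rep_s$bland_altman     # LOA [-8.07, 6.64] mmHg
```

`ME` is the signed mean error (reference minus prediction), the BHS grade
follows from the fractions of absolute errors under 5/10/15 mmHg, and the
Bland–Altman limits bracket 95% of prediction–reference differences under
normality.

The full pipeline — cohort simulation, preprocessing, splitting, two-stage
training, evaluation — is wrapped by `cmd_simulate()`, `cmd_preprocess()`,
`cmd_train()` and `cmd_evaluate()`, or from a shell via
`Rscript inst/cli/radbp.R <command> ...`. See the methods vignette
(`vignettes/radbp-methods.Rmd`) for the model, simulator and design
rationale.

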
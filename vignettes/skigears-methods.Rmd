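---
title: "Methods: gear classification from instrumented insoles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gear classification from instrumented insoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In the skating style of cross-country skiing, skiers cycle through
stereotyped sub-techniques ("gears"). This package classifies the three
uphill gears from per-foot instrumented insoles: **G2R** and **G2L**, the
asymmetric gears in which bilateral pole pushes accompany every second ski
push with the poles angled to the right or left, and **G3**, the symmetric
gear with a pole plant on every push. Each insole carries four
piezoresistive pressure sensors — big toe (BT), first metatarsal (1m),
fifth metatarsal (5m), heel (H) — and a 9-DoF IMU (accelerometer in g,
gyroscope in dps, magnetometer in gauss), sampled at 100 Hz, giving 26
channels across both feet.

A note on channel semantics: the hardware list contains one accelerometer
and one gyroscope per foot, so the `G` channels are treated as gyroscope
angular velocity in dps throughout, even though some descriptions of the
feature set gloss them as "gravitational acceleration". There is no second
accelerometer that such a stream could come from.

## The classifier

Windows are classified by a CNN-LSTM operating on a `steps x channels`
block per window:

* four Conv1D layers (16, 32, 64, 128 filters; kernel sizes 2, 3, 2, 3;
  ReLU; same padding, stride 1, no pooling), dropout 0.25 after layers 2
  and 4;
* two LSTM layers of 256 units, the first sequence-returning, dropout 0.25
  after the stack;
* dense layers of 2048 and 1024 units (ReLU) and a 3-class softmax.

Training uses categorical cross-entropy with RMSprop (learning rate 1e-3,
the common default; the source protocol states the optimizer but not the
rate), up to 50 epochs, batch size 64, early stopping on validation loss
with best-weight restoration (patience 10 by default; the patience value is
a package choice, the criterion is not).

Three architecture details were genuinely open and are resolved as follows:

* "kernel sizes of 2 and 3" across four layers is read as the alternation
  (2, 3, 2, 3); it is configurable via `model_spec()`.
* Same padding with stride 1 and no pooling preserves the temporal axis so
  the LSTMs see all 100 steps.
* The class encoding order is fixed to (G2R, G3, G2L), matching the
  confusion-matrix row order used in reporting; argmax ties break toward
  the earlier class.

Because the deployment environment provides no deep-learning framework for
R, the network is implemented directly on BLAS-backed matrix operations:
Conv1D as im2col + GEMM, LSTMs with full backpropagation through time,
inverted dropout, global-gradient-norm clipping (5) for BPTT stability,
Glorot-uniform initialization with LSTM forget-gate bias 1. An
analytic-versus-numeric gradient check in the test suite pins every layer's
backward pass.

## Preprocessing

The chain, in order, with its tunable parameters:

1. **Offset removal** (`remove_offset`): each pressure channel carries a
   piezoresistive baseline. The estimator is the 5th percentile of the
   channel over the run — a proxy for the non-contact phase, which occupies
   `1 - duty` (45% by default) of every cycle — subtracted and clipped at
   zero. The estimator is a package choice; no definition is given at the
   source.
2. **Force-to-pressure** (`force_to_pressure`): readings in kg divide by
   the sensor area `pi * (9.53/20)^2 = 0.7133057` cm² to give kg/cm².
3. **Cleaning** (`clean_recording`): interior missing runs up to 200 ms are
   linearly interpolated; longer gaps split the run (keeping the absolute
   time axis so labels stay aligned); leading/trailing missing samples are
   trimmed; a channel more than 50% missing rejects the run.
4. **Smoothing** (`ema_smooth`): exponential moving average
   `y[t] = alpha x[t] + (1-alpha) y[t-1]`, `alpha = 0.3` by default (no
   value is stated at the source; 0.3 noticeably attenuates sensor noise at
   100 Hz while keeping the ~1.4 s cycle structure intact).
5. **Segmentation** (`segment_windows`): 5000 ms windows advancing every
   50 ms. The phrase "5000-ms intervals with 50-ms overlaps" is read as a
   50 ms *stride* (i.e. 4950 ms shared span): a 4950 ms stride over the
   stated ~45 min of recording could not produce the several-thousand
   window supports of the published per-class tables, while a 50 ms stride
   can. A window is kept only if it lies entirely inside one labeled gear
   interval; windows straddling boundaries or unlabeled (transition) time
   are dropped rather than majority-labeled, which avoids label noise at
   gear changes.
6. **Median features**: each window is reduced to per-subframe (50 ms)
   medians per channel — 100 steps per window. This reconciles "the median
   value is computed for each sensor" with the model's need for a genuine
   temporal axis: the median is computed per 50 ms subframe, not per
   window, so the CNN-LSTM still sees the cycle structure.
7. **Normalization** (`fit_norm` / `apply_norm`): per-channel z-scores with
   mean and standard deviation computed on the *training* windows only and
   applied unchanged to validation data. A min-max scaling is mentioned in
   one place at the source and z-scores in another; the z-score description
   is the more specific one (it names the train-statistics protocol) and is
   used. A zero-variance channel gets sd 1 with a warning.

## The synthetic world

`simulate_recording()` generates labeled recordings whose qualitative
morphology matches what the classifier exploits in real data:

* per-foot gait cycles (1400 ms default) with feet in counter-phase, a
  contact phase occupying `duty = 0.55` of the cycle;
* within contact, raised-cosine pressure bumps with onset lags ordered
  heel (0 ms) < first metatarsal (120 ms) ≈ big toe (140 ms) < fifth
  metatarsal (280 ms), peak 2 kg/cm², site weights (H, 1m, 5m, BT) =
  (1.0, 1.0, 0.8, 0.7);
* for G2R a 1.3x total-pressure surplus on the left (dominant) side; G2L is
  *exactly* the left/right mirror of the G2R generator at the same seed
  (`mirror_recording` swaps R/L channel pairs and flips the lateral axes
  Ay, Gx, Gz, My); G3 is symmetric;
* phase-locked IMU sinusoids plus a gyroscope burst in the late (propulsion)
  contact phase — the external-rotation analogue — and a slowly varying,
  gear-phase-dependent magnetometer (deliberately the weakest channel);
* additive Gaussian noise per modality (pressure 0.05 kg/cm², accelerometer
  0.05 g, gyroscope 5 dps, magnetometer 0.01 gauss), a 0.2 kg/cm² pressure
  baseline offset, and optional missing cells.

`make_dataset()` draws per-participant amplitude (±15%) and cycle-length
(±10%) multipliers from the master seed so that participant-grouped folds
are non-trivial: clones of one skier would make leave-participants-out
validation meaningless.

What the generator does **not** emulate: pole forces, slope and terrain
variation, fatigue drift, real piezoresistive nonlinearity, gear
transitions within a run, and G1/G4 (not classified here). Absolute
amplitudes are free parameters, not calibrated to any published figure. A
green end-to-end test therefore establishes that the pipeline and model are
implemented coherently and can exploit the documented morphology across
synthetic participants — not that real-snow accuracy is reproduced.

## Evaluation protocol

The headline protocol is participant-grouped 2-fold cross-validation: all
windows of a participant lie entirely in one fold; normalization statistics
come from the training fold only; each fold trains its own model with a
fold-derived seed; metrics are averaged across folds. WAA (weighted average
accuracy) is support-weighted recall, identical to overall accuracy
(trace/total) — an identity the test suite checks on random confusion
matrices. Per-class precision/recall/F1/support reports and the 23-cell
ablation grid (six pressure subsets x four inertial subsets, minus the
forbidden empty-empty cell) mirror the published layout. Per-epoch training
times are recorded as diagnostics only; they are hardware-dependent and
excluded from any acceptance quantity.

## Desk-scale budget reductions

Training-based checks must run on one CPU in minutes, not GPU-hours. Two
declared reductions apply to the acceptance run and the heavier tests, and
only to them:

* window stride 500 ms instead of 50 ms — a 10x subsample of windows;
  window length and subframe size are untouched;
* a width-reduced CNN-LSTM (conv filters 8/16/16/32, LSTM 32+32, dense
  64+32) with the identical layer sequence, and at most 20 epochs.

The defaults of `segment_windows()` and `model_spec()` remain the full
published values; nothing in the generator, thresholds or tolerances was
adjusted to these reductions.

## Numerical choices and degenerate inputs

* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* EMA is evaluated by the exact recurrence (`stats::filter`, recursive).
* Subframe medians use a vectorized order-statistic (identical to
  `stats::median` for even and odd subframe sizes) and are invariant to
  permutations within a subframe.
* A window set shorter than one window is returned empty rather than as an
  error; an all-missing channel, overlapping label intervals, unknown
  channel names, or a non-monotone time column are errors — readers
  validate, they do not repair.
* Writers emit 7 significant digits, making write/read a byte-deterministic
  round trip well inside 1e-6.

## Known limitations

* The simulator's waveform family is one of many satisfying the documented
  morphology; results on it do not transfer quantitatively to real
  recordings.
* The pure-R network trains orders of magnitude slower than a GPU
  framework; the full-width architecture is practical only for small
  window counts.
* Only whole-run gear labels are generated synthetically; transition
  labeling (and a "preparation" class) is future work.
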
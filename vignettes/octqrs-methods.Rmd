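---
title: "Methods: octave-convolution fetal QRS detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: octave-convolution fetal QRS detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octqrs)
```

## The detection problem and the model

A non-invasive abdominal recording mixes the maternal ECG, a much weaker
and faster fetal ECG, and noise, on four channels sampled at 1000 Hz in
microvolts. The detector answers, for every 100-ms frame of a 1-second
window, whether that frame contains a fetal QRS complex. Framing the task
per 100-ms frame matches the clinical matching tolerance for fetal R
peaks (a detection within 50 ms of the reference annotation counts as
correct), and gives the network a sequence-labeling structure: ten
decisions per window, each informed by its neighbours.

The architecture is a residual fully-convolutional trunk followed by a
recurrent head:

* **Trunk** — three residual blocks; inside each block three 1-D
  convolutions with kernel lengths 8, 5, 3, all with that block's filter
  count (64/128/128 by default), each followed by batch normalization and
  ReLU. A 1×1 convolution bridges each block's input to its output; the
  bridge is added to the third convolution's BN output before the final
  ReLU. Strides are 1 and padding preserves length, so the trunk maps
  4×1000 to 128×1000.
* **Frame pooling** — the trunk output is cut into ten 128×100 pieces and
  each is averaged over time: a 128-vector per frame.
* **Recurrent head** — a bidirectional GRU (hidden size 32 per direction)
  runs over the ten frame vectors; the two directions are concatenated
  and one shared affine map with softmax produces the per-frame class
  pair.

### Octave convolutions

Every trunk convolution is a 1-D octave convolution: feature channels are
split into a high-frequency group at full temporal resolution and a
low-frequency group stored at half resolution, with `alpha` the fraction
of channels in the low group. Four kernel groups connect the two
resolutions; the cross-resolution paths use average pooling (down) and
nearest-neighbour repetition (up). The split conserves parameters exactly
— the four groups partition the vanilla kernel — while the per-layer
compute falls to `1 − α(1 − α/2)` and feature storage to `1 − α/2` of the
vanilla cost. The first convolution of the network takes `alpha_in = 0`
(the raw signal has no low branch) and the last takes `alpha_out = 0` so
the trunk output is full-resolution; shortcut convolutions use their
block's input/output splits so branch shapes align.

Because of those boundary layers the whole-network compute does not equal
the per-layer ratio exactly; the cost model (`network_cost()`) accounts
layer by layer instead. With the FLOPs convention of one FLOP per
multiply-accumulate, counting the nine convolutions plus all three 1×1
shortcut convolutions and excluding bias/BN/ReLU/resampling bookkeeping,
the default trunk at `alpha = 0` costs 0.5184 GFLOPs — the convention was
chosen because it reproduces that figure; counting the identity-shaped
third shortcut as a convolution (rather than a free identity) is part of
it. The recurrent head costs `2 directions × 10 steps × 3 gates ×
(128·32 + 32²)` plus the shared 64→2 map, about 3.1e-4 GFLOPs.

### Numerical and design choices

* **Padding for even kernels** (k = 8): `k/2 − 1 = 3` zeros left, `k/2 = 4`
  right, so output length equals input length deterministically.
* **Convolution is cross-correlation** (no kernel flip), the usual
  deep-learning convention.
* **Channel split** uses `round(alpha × channels)`; exact for every
  configuration used here (alpha a multiple of 0.25, channels 8–128).
* **Upsampling alignment**: `out[t] = in[t div 2]` (repetition).
* **Bias** is added once per output branch after the two paths sum;
  equivalently it rides along the first contributing path, since nearest
  upsampling preserves per-channel constants.
* **Batch axis**: feature maps are `[channel × time × batch]` arrays
  (column-major R layout puts channels fastest, which lets per-channel
  vectors broadcast by recycling); all contracts are per-instance.
* **Batch normalization**: per-channel statistics over time and batch,
  separately per frequency branch (the branches partition the channels);
  momentum 0.1 on running statistics, variance floor 1e-5. Inference uses
  running statistics, so prediction is deterministic.
* **Dropout** (rate 0.4) is applied at two sites — on the pooled 10×128
  sequence before the GRU and on the 10×64 GRU output before the
  classifier. The rate is a stated training choice; the placement is
  ours, at the head where the parameter density is highest.
* **Bidirectional merge** is concatenation (64 = 2×32).
* **GRU gates** carry one bias vector each; the gate equations are
  reset/update sigmoids and a tanh candidate on the reset-gated state.
* **Initialization** is Glorot-uniform throughout; octave kernel groups
  draw with the full layer fan (`(c_in + c_out) × k`) so the draw scale
  does not depend on alpha.
* **Loss**: weighted binary cross-entropy over the ten frames, positive
  class weighted β = 2 against class imbalance, probabilities clamped at
  1e-7. Written with both error terms penalized — a sign on the
  negative-class term that would reward confident false positives is
  treated as a typo. β = 1 recovers plain BCE (tested).
* **Optimization**: Adam, learning rate 1e-3, β₁ = 0.9, β₂ = 0.999,
  ε = 1e-8, constant schedule, batch 64, model selection by validation
  frame-F1 (the natural reading of "best model on the validation set").
* **Evaluation** is frame-level: predicted class is the frame argmax;
  precision, recall and F1 accumulate TP/FP/FN over all frames. Zero
  denominators yield 0 with a `degenerate` flag.
* **Grad-CAM span**: channel weights average the score gradient over the
  100 samples of the target frame — the region whose pooled feature feeds
  that frame's score; a whole-window mode is available. The target score
  is the pre-softmax logit. The final feature map is full-resolution, so
  the attention trace needs no upsampling.

All gradients are hand-derived and verified against central finite
differences on small networks (relative error ~1e-9 across convolution,
BN, shortcut, GRU and classifier parameters); the test suite keeps a
finite-difference check for the Grad-CAM path.

## The synthetic data generator

PhysioNet's non-invasive fECG recordings cannot ship with the package, so
tests and examples run on a seedable simulator that reproduces the
statistical structure the detector relies on:

* maternal beat train at 60–90 bpm and an independent fetal train at
  110–160 bpm, RR intervals jittered multiplicatively (CV 0.02, truncated
  at ±20 %);
* beat morphology as five Gaussian bumps (P, Q, R, S, T) with fixed
  offsets/widths; the fetal template is the same shape compressed to 60 %
  in time (narrower QRS), scaled to `fetal_amplitude_ratio` (default 0.2)
  of the maternal R amplitude (default 25 µV — abdominal-lead scale);
* per-channel mixing gains drawn uniformly from [0.5, 1] (or supplied),
  plus white Gaussian sensor noise (default SD 1 µV);
* ground-truth fetal R-peak indices attached as annotations.

Separately, `add_gaussian_noise()` reproduces the bounded-noise protocol
(zero-mean Gaussian rescaled to max |4 µV|, multiplied by levels such as
3/6/9 — the "normal yet bounded" wording is contradictory, so the bound
is honored and the shape approximated), and `add_motion_artifact()`
substitutes a synthetic motion model (min-max normalization to [−1, 1],
then random-phase 0.1–1 Hz sinusoids plus sparse step transients) for
motion noise extracted from real ambulatory recordings, which needs
hardware we do not model.

What the simulator does **not** emulate: volume-conduction lead fields,
fetal movement or vernix attenuation, maternal ectopy, electrode motion
coupling, or the heavy-tailed artifacts of real abdominal recordings.
Passing tests on synthetic data therefore demonstrate that the
implementation learns and localizes the pattern class it defines —
dominant slow interference plus weak sharp target — not clinical-grade
performance; the real-data experiment requires the PhysioNet download
and is wired through the same `read_wfdb_record()` / `split_records()`
path (test records a01–a07, validation a08–a13, seven excluded for
unreliable annotations, 55 for training).

## Problem sizes used by the test suite

The suite trains a **reduced preset** (`network_config_reduced()`):
identical topology with 8/16/16 filters, chosen once so that a complete
training study runs in minutes on one CPU core while leaving the
architecture's every element (octave splits, shortcuts, BN, biGRU)
exercised. The standing study is ~2000 one-second windows from 34
synthetic recordings at `fetal_amplitude_ratio = 0.3`, `alpha = 0.25`,
15 epochs, fixed seeds; the trained model typically reaches validation
frame-F1 well above 0.9 and anchors the Grad-CAM localization check.
Because a whole-window attention trace spikes at every fetal QRS it
covers, localization is scored two ways, each with a 70 % bar at the
50-ms matching tolerance: the global attention maximum of a correctly
detected positive frame must fall within 50 ms of a true fetal R peak
(with a control that it is not captured by maternal peaks), and within
the explained frame's own 100-ms span the maximum must fall within
50 ms of that frame's annotated peak. Unit tests use toy configurations
(2×40 windows, 4/6/6 filters) where brute-force oracles are exact.

## Known limitations

* Training the full-width network (0.55 M parameters) on real data is
  CPU-hours scale in this implementation; it exists primarily for cost
  accounting, inference-path testing and the real-data adapter.
* The WFDB reader covers the subset used by the target records (format
  16, one signal file); annotations are read from a plain-text sidecar
  rather than binary annotation files.
* Window export is in-memory / CSV; no HDF5 container.
* Frame-level metrics are the primary evaluation; a 50-ms peak-matched
  evaluation of real annotated data is intentionally out of the automated
  path (it needs the PhysioNet download).
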
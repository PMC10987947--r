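---
title: "Cross-subject finger kinematics from sEMG: model, calibration and synthetic validation"
author: "rofemg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject finger kinematics from sEMG: model, calibration and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rofemg)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of
contracting muscle through the skin. Regressing continuous finger joint
angles from multi-channel forearm sEMG is a central building block of
myoelectric prostheses and other human-machine interfaces. The hard part is
not fitting one user — it is that sEMG is strongly user-specific: electrode
placement, skin impedance, muscle recruitment strategies and amplitude
ranges all differ across people, so a regressor trained on one group of
subjects degrades sharply on a new user.

`rofemg` implements a pipeline for this setting:

1. **Features**: sliding-window RMS envelopes of the raw sEMG, compressed
   with mu-law companding so that the informative low-amplitude range is
   expanded rather than flattened.
2. **Model**: a transformer encoder whose attention uses rotary position
   embedding (RoPE), so attention logits depend on *relative* window
   positions.
3. **Calibration**: an adversarial transfer-learning (ATL) procedure that
   adapts a frozen multi-subject model to a new subject using the new
   subject's small training set plus a domain discriminator, compared
   against head-only fine-tuning (FT) and no transfer at all (noTL).
4. **Validation**: a seeded synthetic cohort simulator with controllable
   inter-subject domain shift, so the entire pipeline is testable without
   any external download.

## Signal preparation

Raw recordings pair an sEMG matrix at `fs_emg` (2 kHz in the reference
acquisition setup) with glove angles in degrees at `fs_angles` (20 Hz).
`compute_rms_windows()` computes the RMS of each channel over a sliding
window (default 100 ms). Windows are indexed 0-based over half-open sample
intervals; the window count is `floor((n - W)/S) + 1`.

The step size deserves a note. The acquisition protocol we follow prints a
step of "0.5 ms", which at 2 kHz is a single sample and implausibly dense
(a 5 s trial would produce ten thousand windows at 99.9 % overlap). We treat
the step as a required parameter with a default of 50 ms — a conventional
half-window hop — and leave any other value, including the literal 1-sample
step, available through `step_ms`.

Labels are linearly resampled from `fs_angles` to the sEMG rate and one
label row is taken per feature window at the window-center timestamp
(symmetric, and consistent with the non-causal model below).

### Mu-law companding

Per channel, features are first divided by the training-set maximum
absolute RMS (the *prescale*, clipped at 1 at test time), then companded:

\[ F(x) = \mathrm{sign}(x)\,\frac{\ln(1 + \mu |x|)}{\ln(1 + \mu)},\qquad
   |x| \le 1. \]

The default \(\mu = 2^{20}\) follows the reference protocol (selected there
by a search from 256 up to \(2^{20}\)). The map is odd, strictly increasing
and exactly invertible (`mu_law_inverse()`); as \(\mu \to 0\) it approaches
the identity. The point of the logarithmic expansion is that much of the
discriminative sEMG information sits near zero amplitude, which a linear
rescaling (or a Z-score, also provided) leaves compressed. All
normalization statistics are fitted on the training split only and frozen
(`fit_normalization()` / `apply_normalization()`); a hash of the spec
travels with features and models so mismatched pipelines fail loudly.

## The rotary-attention regressor

The input series of feature windows is projected by a 1-D convolutional
front layer (kernel 3, stride 1, same padding) to the model width, then
passes through `n_layers` pre-norm encoder layers:

\[ Z'_l = \mathrm{MSA}(\mathrm{LayerNorm}(Z_{l-1})) + Z_{l-1}, \qquad
   Z_l = \mathrm{MLP}(\mathrm{LayerNorm}(Z'_l)) + Z'_l, \]

with a linear–Mish–linear MLP. Each attention head computes
\(\mathrm{softmax}(QK^\top/\sqrt{d_h})\,V\) with **no causal mask**: the
estimator is non-causal by design and attends to future and past windows
alike.

RoPE rotates each coordinate pair \((2i, 2i+1)\) of every query and key row
at position \(m\) by the angle \(m\,\theta_i\), with
\(\theta_i = b^{-2i/d_h}\) (base \(b = 10^4\)). Because rotation is
orthogonal, \(\langle R_m q, R_n k\rangle = \langle q, R_{n-m} k\rangle\):
attention logits depend only on the position *difference*, which is the
property the test suite verifies against an explicit rotation-matrix
oracle. Values are never rotated, so no absolute position information leaks
into the attended content, and the rotation is applied inside **every**
layer's attention rather than once at the input. (The source formulation
can be read as marking the input once; we follow the construction of the
rotary-embedding literature and the stated per-layer semantics, which the
layer-ablation test pins down.)

All five model families share a common head: a linear–Mish feature layer
(width `head_hidden`) followed by a linear output layer to the 10 joints.
The feature layer is "the penultimate fully connected layer" whose
activations feed the domain discriminator during ATL, and it is what
fine-tuning updates — keeping transfer and evaluation code family-agnostic.

### Baselines

* **LSTM** — a stacked LSTM (reference sizes: 5 layers, hidden width 32).
* **TCN** — dilated causal convolutions with residual connections. The
  reference description names five convolutional layers but only four
  channel sizes ("32, 64, 32, and 10"); we use `(32, 64, 64, 32, 10)`, a
  symmetric completion, exposed as `tcn_channels`. Its printed
  "stride and kernel sizes are set to 3 and 1" is read as kernel 3 /
  stride 1 (the conventional pairing; stride 3 with kernel 1 would drop
  samples), and the same front-layer geometry is reused for the attention
  families.
* **Transformer with absolute PE** — identical encoder, with sinusoidal or
  learnable embeddings added once at the input instead of RoPE. For matched
  dimensions the three embedding variants differ *only* in the embedding
  component, which is asserted in the tests; this is the comparison surface
  for position-embedding ablations.
* **CNN-Attention** — three parallel convolution branches (kernels 3, 5, 7),
  average pooling (width 2, the smallest non-trivial reduction; the source
  names only "average pooling"), three attention blocks of three single
  heads each, and nearest-neighbour upsampling back to the input length so
  the family honors the shared forward contract.

Because no deep-learning framework is part of this package's dependency
set, all families run on a small reverse-mode automatic-differentiation
tape written in base R matrix algebra (`R/autodiff.R`). Every pull-back is
validated against central finite differences in the test suite, and the
tape forward of the rotary encoder is additionally checked for exact
agreement with the standalone matrix implementation (`encoder_forward()`).

### Training

`train_regressor()` minimizes the mean squared error over all joints with
Adam (default moments), halving the learning rate from the scheduled epoch
on (reference protocol: batch 64, 400 epochs, halve at 200; initial rates
1e-4 cross-subject / 3e-4 subject-specific; these live in
`paper_profile()`). Trials are chunked into non-overlapping sequences
(`seq_len`, reference default 150 windows) — the attention context at
training time.

One numerical choice matters in practice: labels are standardized
internally (per-joint center, one *shared* scale) before optimization and
the transform is inverted at prediction time. A single shared scale keeps
the relative weighting of joints in the MSE objective exactly as in the
raw-degree formulation; the standardization only reconditions the
optimization (unit-variance targets), which at desk scale cuts the epochs
needed to converge several-fold.

## Adversarial transfer learning

To adapt a cross-subject model to a new subject, three networks interact:
the frozen source network (Multi-s-net), a trainable copy initialized from
it (New-t-net), and a domain discriminator (DD) — a small MLP (two Mish
hidden layers of width 64, sigmoid output) scoring the probability that a
penultimate-layer feature row came from the source domain. Per batch, two
alternating updates:

1. **DD step** minimizes
   \(L_{DD} = \mathbb{E}[-\log DD(F_s)] + \mathbb{E}[-\log(1 - DD(F_t))]\),
   where \(F_s\) are frozen-source features of pooled source batches and
   \(F_t\) are target features from New-t-net (treated as constants here).
2. **Target step** minimizes \(L_{mapping} + L_{subject}\) with
   \(L_{mapping} = \mathbb{E}[-\log DD(F_t)]\) (reward for fooling the DD)
   and \(L_{subject} = w\,\mathbb{E}\big[\sum_{j=1}^{N}(\hat{y}_j - y_j)^2\big]\)
   over the new subject's labeled training windows (N = 10 joints).

The total \(L_{total} = L_{DD} + L_{mapping} + L_{subject}\) is logged per
epoch together with the DD accuracy, and the recomposition identity is
asserted to 1e-9. We use two optimizers in GAN style rather than a
gradient-reversal layer because the two objectives are stated separately;
one DD step per target step (configurable). The weighting coefficient `w`
is never given in the source — we default to 1 and expose it. Probabilities
are clamped at 1e-7 before logarithms, and the expectation is the batch
mean (the alternative per-sample-sum reading only rescales `w`).
Calibration runs 50 epochs at rate 1e-3 (the reference calibration period).

**FT baseline**: copies the source model, freezes everything except the
shared two-layer head, and minimizes MSE on the target training data with
the same budget. **noTL**: the pooled model evaluated as-is; the package
logs trial-level access so tests can assert the target training trials are
never touched on this path.

## Metrics

Per joint over the concatenated test windows of each (subject, movement)
group: Pearson CC; NRMSE, i.e. RMSE divided by the observed range of the
measured trajectory (the reading of "errors scaled to [0, 1] uniformly for
all angles" that actually guarantees that range for in-range predictors);
and \(R^2 = 1 - SS_{res}/SS_{tot}\). Negative \(R^2\) is reported rather
than clipped to the nominal 0–1 range: a worse-than-mean predictor is a
failure mode worth seeing. Whether to average metrics over joints before or
after grouping over movements is not fixed by the reference description;
`evaluate_model()` emits per-joint rows, per-group means and the grand
mean, so either aggregation order can be read off the same report.

## The synthetic cohort generator

The simulator emulates the statistical structure the method assumes, not
the biophysics of motor units:

* **Kinematics**: each movement assigns every joint a target posture
  (20–80°, rest 5°) and — importantly — its own excursion center and
  half-width within the trial, so per-joint trajectories are *not* scaled
  copies of one grasp profile. Trials jitter the global timing and the
  per-joint amplitudes. Because Pearson CC is invariant to amplitude
  scaling, it is exactly this per-joint *timing* diversity that makes the
  metric discriminative: a decoder that cannot tell the channels apart
  predicts the wrong temporal shapes and its CC drops, while amplitude-only
  errors would be invisible.
* **Activations**: each latent muscle (default 10) is recruited primarily
  by one joint with random spill-over, from normalized angles plus absolute
  angular velocity, raised to a per-subject exponent near 1. The
  joint-dominant recruitment keeps the angle-to-envelope map informative
  enough that the task is solvable (the recoverability test below); a
  low-dimensional synergy bottleneck (e.g. 6 muscles for 10 joints) caps
  achievable accuracy well below it.
* **sEMG**: a per-channel band-limited noise carrier (Butterworth band-pass
  20–450 Hz, the standard surface-EMG energy band, at 2 kHz)
  amplitude-modulated by the mixed activations through a channel-by-muscle
  synergy matrix, times a per-channel gain, plus additive sensor noise.
* **Domain shift**: a new subject is the cohort mean perturbed by
  `shift_magnitude`: log-normal jitter of mixing, gains and exponents
  (amplitude idiosyncrasy) *and* interpolation of both the channel routing
  and the recruitment read-outs toward subject-specific random assignments
  (electrode-placement and recruitment idiosyncrasy). At shift 0 the new
  subject equals the cohort mean; at shift 1 the routing is fully
  re-drawn. Within-cohort variability uses the same mechanism at
  `subject_sd` (default 0.08).

What passing tests on this generator do **not** show: robustness to real
sEMG nonstationarity (fatigue, electrode lift-off, sweat), to real
motor-unit interference spectra, or to glove-sensor crosstalk. The
generator defines the *operative* meaning of domain shift for this
package — monotone degradation of uncalibrated cross-subject accuracy —
and the test suite verifies exactly that, plus recoverability: a
subject-specific model at desk scale reaches median held-out-trial CC at
or above 0.8 over five seeds, so the task is neither trivial nor
impossible.

## Scale profiles and problem sizes

`paper_profile()` carries the full-scale protocol (d_model 40, 5 heads, 2
encoder layers, batch 64, 400 epochs, sequence length 150). The reference
text never states the rotary model's depth and head count; we default both
attention families to the baseline transformer's stated sizes (2 layers, 5
heads) and to d_model 40, the smallest width divisible by 5 heads with an
even per-head dimension that matches the scale of the other stated sizes.

`desk_profile()` is the package's own small-scale setting and the default
everywhere: d_model 16, 2 heads, 1 layer, head width 16, sequences of 40
windows, batch 4, 150 epochs at 2e-3 (halved at 110), 50-epoch
calibration. The synthetic study conditions used by the acceptance-style
tests are cohorts of 4 source subjects plus one held-out subject, 2
movements, 6 trials of 4 s — sized so a full simulate-train-calibrate
cycle completes in about a minute on one CPU core and the whole suite in
well under half an hour, while leaving enough headroom between the
subject-specific ceiling and the shifted-subject floor for the transfer
comparison to be meaningful.

## Numerical choices and degenerate inputs

* Softmax with row-max subtraction; LayerNorm epsilon 1e-5.
* Mish via the overflow-safe softplus `max(x,0) + log1p(exp(-|x|))`.
* RoPE requires an even head width (checked at construction).
* A constant channel in Z-score fitting, a constant label series in NRMSE,
  zero-variance inputs to CC/R², signals shorter than one window, and
  non-6 trial sets in the splitter are all hard errors naming the
  offending quantity.
* Silent channels under mu-law prescaling get a unit prescale (they stay
  exactly zero).
* Encoder layers check activations for finiteness and name the layer on
  failure; training aborts on a non-finite loss with the epoch in the
  message.
* All randomness flows through explicit seeds (`with_seed()` restores the
  caller's RNG state), so every experiment, cohort and checkpoint is
  bit-reproducible on one device.

## Known limitations

* The autodiff tape is single-threaded, dense and eager; it is sized for
  the desk-scale models, and the full 400-epoch protocol, while available,
  is slow in this implementation.
* ATL inherits the usual GAN-style caveats: with a pathological learning
  rate the discriminator can collapse (the calibrator aborts on non-finite
  losses and logs per-epoch diagnostics).
* The DB2 reader covers little-endian MAT-level-5 numeric arrays (plain or
  zlib-compressed) — the layout DB2 files use — not the full MAT
  container zoo (cells, structs, v7.3/HDF5).
* The exact movement, glove-channel and subject selections of the
  reference evaluation are not printed there; `db2_selection()` therefore
  requires them as explicit, documented fields with clearly-labeled
  override-me defaults.
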
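# rofemg

Continuous estimation of finger joint angles from multi-channel surface
electromyography (sEMG), with cross-subject models and calibration to new
users.

sEMG is strongly user-specific: electrode placement, muscle recruitment and
amplitude ranges differ between people, so a joint-angle regressor trained
on a pool of subjects degrades sharply on a new one. `rofemg` implements a
full pipeline for this problem:

* **Features** — sliding-window RMS envelopes of the sEMG, normalized by
  mu-law companding
  `F(x) = sign(x) · ln(1 + μ|x|) / ln(1 + μ)` (default `μ = 2^20`), which
  expands the informative low-amplitude range; per-channel Z-scoring is
  available for comparison.
* **Model** — a transformer encoder with rotary position embedding (RoPE):
  every layer's queries and keys are rotated pairwise by
  position-proportional angles `m · base^(-2i/d)`, making the attention
  logits `softmax(QKᵀ/√d_h)V` depend only on *relative* window positions.
  Pre-norm residual blocks with a linear–Mish–linear MLP, a 1-D
  convolutional front layer, and a two-layer head shared by all model
  families. Four baselines (stacked LSTM, dilated TCN, transformer with
  sinusoidal/learnable absolute embeddings, multi-scale CNN-attention)
  expose the identical training, transfer and evaluation surface.
* **Transfer** — adversarial transfer learning (ATL): a frozen
  multi-subject source network, a trainable copy for the new subject, and a
  domain discriminator trained on penultimate-layer features. The
  discriminator minimizes
  `L_DD = E[-log DD(F_s)] + E[-log(1 - DD(F_t))]`; the target network
  minimizes `L_mapping + L_subject` with `L_mapping = E[-log DD(F_t)]` and
  `L_subject = w · E[Σ_j (ŷ_j - y_j)²]` on the new subject's labeled
  windows. Head-only fine-tuning (FT) and no-transfer (noTL) baselines run
  on identical splits.
* **Metrics** — per-joint Pearson CC, range-normalized RMSE and R²,
  aggregated per subject × movement and summarized as mean ± sd tables.
* **Synthetic cohorts** — a seeded simulator of paired sEMG/kinematics
  with controllable inter-subject domain shift, so everything above is
  testable offline; an optional reader maps Ninapro DB2 MATLAB files to the
  same containers.

All five model families are trained by a small reverse-mode autodiff
engine written in base R (gradients verified against finite differences in
the test suite); no deep-learning framework is required.

## Worked example

Simulate a cohort with a strongly shifted held-out subject, train a
cross-subject rotary-transformer model on the four source subjects, and
compare no transfer, fine-tuning and adversarial calibration on the new
subject (about two minutes on one CPU core):

```r
library(rofemg)

coh <- generate_cohort(
  cohort_spec(n_subjects = 4, n_movements = 2, trial_duration_s = 4,
              shift_magnitude = 1.0),
  master_seed = 101)

res <- run_transfer(coh, profile = desk_profile(1), seed = 1)
res$table
```

```
  condition   cc_mean cc_sd nrmse_mean nrmse_sd   r2_mean r2_sd n
1      noTL 0.7180322    NA  0.2703499       NA 0.3468902    NA 1
2        FT 0.7939496    NA  0.2114036       NA 0.5772994    NA 1
3       ATL 0.8812454    NA  0.1750459       NA 0.7111052    NA 1
```

Reading: evaluated on the held-out subject's two test trials per movement,
the uncalibrated cross-subject model reaches an average per-joint
correlation of 0.72 — well below the ~0.85 a model trained on that subject
alone achieves — because the new subject's channel routing differs from
the cohort's. Fine-tuning the output head on the subject's four training
trials recovers part of the gap (CC 0.79); the adversarial calibration,
which also aligns the feature distributions and updates the whole target
network, recovers most of it (CC 0.88, NRMSE 0.18, R² 0.71). The same
object carries per-joint tables (`res$reports$ATL$per_joint`), the
discriminator's per-epoch losses (`res$calibrated$ATL$calibration_log`),
and an access log proving the noTL path never touched the target training
trials.

A command-line front end with `simulate`, `preprocess`, `train`,
`evaluate`, `transfer` and `report` verbs lives at
`inst/cli/rofemg-cli.R`:

```sh
Rscript inst/cli/rofemg-cli.R transfer --seed 1 --out runs/demo --profile desk
```

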
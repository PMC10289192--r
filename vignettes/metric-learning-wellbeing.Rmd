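---
title: "Personalized metric learning for daily well-being estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized metric learning for daily well-being estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambumetric)
```

## The model

`ambumetric` estimates daily self-reported well-being constructs — anxiety
and stress (1–5), positive affect (5–25), negative affect (5–24) — from 69
daily ambulatory features recorded by three wearable device families
(activity/sleep, vocal acoustics, physiology). Ambulatory features carry
strong person-specific location and scale signatures, so a pooled regressor
mostly encodes identity. The core model is a Siamese regressor that learns a
shared embedding $f_W$ and a single-node head $g_V$ jointly:

- **Feature (metric) loss.** For two samples $m \ne m'$ of the *same*
  participant $n$,
  $l_F = \big|\, \lVert f_W(x_{nm}) - f_W(x_{nm'}) \rVert_2 -
  \lvert \hat y_{nm} - \hat y_{nm'} \rvert \,\big|$,
  where $\hat y$ is the participant's $\ell_2$-normalized label. Distances
  in the embedding are pushed toward distances in label space, so variance
  irrelevant to the construct (including identity) is discarded.
- **Regression loss.** $l_R = (g_V(f_W(x_{nm})) - y_{nm})^2$ on the raw
  label supervises the same embedding for absolute prediction.
- **Total loss.** $l_F + \lambda\, l_R$, with $\lambda = 1$ by default. The
  reference protocol trains on both losses but states no mixing weight;
  $\lambda$ is exposed in `model_config()`.

Pairs are enumerated exhaustively within participant (all unordered pairs of
labeled days; unordered because $l_F$ is symmetric), flagged *similar* when
$|y_a - y_b| \le 1$ and dissimilar otherwise — one threshold for all four
constructs, which the source protocol found insensitive in the range 1–5 —
and weighted inversely to class frequency, normalized to mean weight 1, so
the smaller class carries equal total mass.

### Architecture and optimization

The shared stack has 3–5 dense ReLU layers of 64 units ($\ell_2$ penalty
$10^{-4}$ on every weight matrix, inverted dropout 0.1–0.3 between layers),
and the head is one linear node; with 3 layers and 69 inputs this is exactly
12,865 trainable parameters. Training is mini-batch SGD (batch 128/256/512,
learning rate 0.01 by default — unspecified upstream, exposed in config)
with early stopping on the validation Pearson correlation (patience 3/5/10)
and best-epoch weight restoration. The network, backprop and SGD are
implemented in base R matrix code: at ~12k parameters BLAS-backed dense
algebra is entirely adequate and keeps the package dependency-free here.

Numerical choices worth noting:

- The gradient of $l_F$ divides by the embedding distance; a floor of
  $10^{-8}$ guards the coincident-embedding case.
- The regression head is applied to **both** branches during training (each
  pair contributes two $l_R$ terms); inference uses a single branch. The
  reference schematic shows one head output; the symmetric choice uses all
  labels and is the package's decision.
- Imbalance weights multiply both loss terms, matching the upstream
  description of weighting "the loss function" without restriction.
- Non-finite training loss aborts with diagnostics rather than continuing.

### Preprocessing

Missing feature values (about 10% of cells in the motivating study) are
linearly interpolated per participant and feature across the day series;
leading/trailing gaps take the nearest observed value (the upstream rule
covers only interior gaps; nearest-value fill is the minimal
order-preserving extension). Sub-daily records are averaged per
participant-day. Features are min-max normalized with extremes computed from
*training participants only*, refit inside every fold; held-out values
outside the training range are clipped to $[0,1]$ (the trained input range),
and constant features map to 0.

Label normalization for $l_F$ is per participant, over that participant's
training labels: pairs are strictly within-participant, so only
same-participant normalized labels are ever compared. The upstream text does
not fix the normalization scope; per-participant is this package's decision.
The regression target $y$ stays raw — Pearson evaluation is scale-free, so
the choice is immaterial to the reported metric.

## Personalization variants

- **ML-AT** duplicates the participant's 14 trait scores onto every daily
  record as extra input columns. For positive/negative affect the trait
  versions of both affect scales are dropped first (12 traits remain), so
  the model cannot shortcut through the trait form of its own target.
- **ML-C** fits PCA (3 components, on min-max-scaled traits; the pre-PCA
  scaling is unstated upstream and the package reuses its feature
  convention) and K-means (10 seeded restarts, best inertia) on training
  participants, then trains one ML-AT model per cluster; held-out
  participants are routed to the nearest fitted centroid, never refit.
  K defaults to 4. The elbow diagnostic implements the kneedle rule — the K
  at maximal distance below the chord of the normalized inertia curve — not
  a raw second-difference rule: on ideal well-separated clusters the second
  difference peaks one K too early, while the chord rule recovers the true
  count. A maximal chord distance under 0.25 is declared "no clear elbow"
  and falls back to the configured default, mirroring the upstream
  experience that real trait data shows no clean elbow and K is set
  empirically.
- **Fine-tuning** moves $\lfloor \text{fraction} \cdot m \rfloor$ of each
  test participant's $m$ days (uniformly at random, seeded) into the
  training pool; the pair set is rebuilt afterwards so target-participant
  pairs are within-participant too, and the moved days are removed from the
  test fold.

## Baselines

**FNN** uses the identical stack (layers, width, dropout, $\ell_2$, early
stopping, fine-tuning protocol) trained on plain feature-to-label MSE.
Because the Siamese branches share weights, FNN and Siamese counts are
equal by construction; `check_parameter_parity()` enforces the ±5% contract
anyway.

**SMIDA** treats each participant as a domain: with linear kernels it finds
an orthonormal projection maximizing
$\text{variance} + \gamma\,\mathrm{HSIC}(\text{proj}, y_{\text{observed}})
- \mu\,\mathrm{HSIC}(\text{proj}, \text{domains})$
as a symmetric eigenproblem, with test labels masked (semi-supervised), then
fits OLS on the projected labeled samples. Upstream fixes only the linear
kernel; $\mu = \gamma = 1$ and subspace dimension $\min(30, p)$ are package
defaults. Fine-tuning for SMIDA is realized by unmasking the moved samples'
labels (they enter the training pool), the package's interpretation of an
undescribed step. Domain indicators are appended to the feature block before
projection (the standard formulation; `augment = FALSE` recovers plain PCA
at $\mu = \gamma = 0$, which the tests exploit as an oracle).

## Evaluation protocol

Participants are stratified by mean construct label into blocks and
distributed across 10 folds (seeded); per test fold the validation fold is
the next one cyclically — the rotation rule and the stratification variable
are package decisions, upstream fixes only "stratified, participant-
independent, one fold validation, one fold test". Leakage is audited twice:
fold sets must be disjoint and partition participants, and no
participant-day may appear in both the (augmented) training pool and the
reduced test set; violations are hard errors, not warnings.

Scores are Pearson correlations between predictions and raw labels on the
reduced test fold, repeated over restarts with derived seeds; undefined
correlations from constant predictions are recorded as missing and excluded
from aggregates with a count. Variants are compared with one-tailed paired
t-tests over restart-mean scores (no multiple-comparison correction, as in
the reference analysis; noted in report metadata). Hyperparameters are
searched with a Gaussian-process loop (RBF kernel on the unit-encoded
space, fixed length-scale 0.3, nugget $10^{-6}$, expected-improvement
acquisition over a random-plus-incumbent-mutation candidate pool, seeded,
default 200 calls) — a self-contained equivalent of the usual GP minimizer,
since none is available as a dependency. The person-identification probe is
a multinomial ridge-logistic classifier (`glmnet`; the classical multinomial
implementation is not available in the environment) under a stratified
70/30 sample split per restart; the split protocol is a package decision.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method assumes,
not sensor physics:

- traits from a mixture of 4 isotropic Gaussians (centers SD 3, unit
  within-cluster SD — well separated, as the recovered real clusters are);
- a daily latent state $s = b_p + \tau\,\mathrm{proj}_p + e_{pd}$
  (participant baseline SD 0.5, standardized trait projection, day noise
  SD 1);
- features = shared loading × state + per-participant offset vector
  (SD `subject_shift_scale`) + per-participant scale × unit noise, truncated
  to $[-15, 15]$;
- labels by monotone discretization: the logistic transform of the
  standardized state raised to a per-construct skew power and binned into
  the label range. The packaged powers (anxiety 3, stress 1.5, positive
  affect 1, negative affect 10) were calibrated once so the marginals match
  the reported distributions (>50% of anxiety labels at 1, ~80% of
  negative-affect labels at the minimum) and are not revisited;
- `missing_rate` (default 0.10) of feature cells blanked completely at
  random — the upstream remedy (unconditional interpolation) implies no
  structured mechanism;
- defaults 139 participants × 21 days mirror the motivating cohort
  (139 retained participants, ~3 weeks of labeled days each).

One deliberate deviation from a literal reading of the stated generative
recipe: `trait_feature_leak` (default 0.5) expresses only half of the trait
contribution to the latent state in the *features*, while the *labels*
follow the full state. If traits were fully mediated through the features,
trait augmentation could not add information and the ML-AT > ML-A property
would be vacuous; substantively, self-reports carry trait-driven reporting
bias that physiology and acoustics only partially reflect.

What a green test does **not** establish: the generator has no temporal
autocorrelation (samples are treated as independent over time, as upstream),
no structured missingness, no sensor artifacts, and Gaussian feature noise;
absolute correlation levels on synthetic cohorts are far higher than on real
ambulatory data, so only *directions* (ML-AT > ML-A > FNN, fine-tuning
trend, probe accuracy drop) and *mechanics* (losses, pairing, leakage,
counts) transfer.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_shared_layers` | 3 (range 3–5) | depth of $f_W$ |
| `dropout` | 0.2 (0.1–0.3) | between shared layers |
| `l2_penalty` | $10^{-4}$ | on every weight matrix |
| `patience` | 5 (3/5/10) | early-stopping epochs on validation $r$ |
| `batch_size` | 128 (128/256/512) | pairs per SGD step |
| `lambda` | 1 | regression-loss mix |
| `learning_rate` | 0.01 | SGD step size |
| pair `threshold` | 1 | similar iff $|y_a-y_b| \le$ threshold |
| `min_labeled_days` | 13 | participant inclusion filter |
| ML-C `k` | 4 | trait clusters |

## Known limitations

- Training is CPU-bound base R; fine for ~12k-parameter models and desk-
  scale cohorts, not for larger encoders.
- SMIDA restarts are deterministic, so its restart dimension is degenerate
  (scores repeat); recorded as such for protocol symmetry.
- The GP tuner assumes a deterministic objective per seed; noisy objectives
  work but convergence claims are only tested on deterministic surfaces.
- Multiple same-day survey responses are assumed resolved upstream to at
  most one label per participant-day; `daily_average()` errors on
  conflicting same-day labels rather than guessing.
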
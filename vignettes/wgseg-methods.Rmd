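---
title: "Adversarial multi-organ segmentation with a Wasserstein critic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial multi-organ segmentation with a Wasserstein critic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgseg)
```

## The problem

Chest radiographs are low-contrast projections in which the lung fields
and the cardiac silhouette overlap and share blurred borders. Delineating
the left lung field, right lung field, and heart in one pass gives a
clinician the relative positions and sizes of the organs at a glance
(cardiothoracic ratio, mediastinal shift), which is why multi-organ
segmentation is preferred over three independent binary problems.

`wgseg` implements an adversarially trained segmentation model for this
task. A U-shaped fully convolutional generator proposes a per-pixel label
distribution; a convolutional critic scores (image, mask) pairs with an
unbounded real number; training alternates between improving the critic's
ability to separate ground-truth masks from generated ones and improving
the generator against both a supervised overlap objective and the critic's
score. Everything runs at desk scale on one CPU against a built-in
synthetic thorax phantom, so the full pipeline — data, training,
evaluation — is testable without any external imaging data.

## The generator

The generator is a four-level encoder-decoder. Each level's block is

1. two 3x3 same-padded convolutions with rectifier nonlinearities,
2. a squeeze-and-excitation (SE) gate: channels are global-average-pooled
   to a descriptor, passed through a bottleneck MLP
   (`C -> max(1, C/se_reduction) -> C`) ending in a sigmoid, and each
   channel is rescaled by its gate in (0, 1),
3. a residual shortcut: the block input, projected by a 1x1 convolution to
   the block's width, is added to the gated features.

Encoder levels carry `base_filters * 2^level` channels and end in 2x2 max
pooling; decoder levels start with nearest-neighbor 2x upsampling followed
by a 3x3 convolution (avoiding the checkerboard artifacts of strided
transpose convolutions), concatenate the matching encoder skip, and apply
the same block. The head adds a 1x1 projection of the *input image* to the
last decoder features, applies the rectifier, and maps to `num_labels`
logits with a 1x1 convolution; a per-pixel softmax yields probability
maps. The head could equally add the raw input image instead of a
projected feature map; the projected form is adopted because it keeps
channel arithmetic valid for any `base_filters`.

Input sides must be divisible by `2^depth` (default 16). Defaults:
`base_filters = 64` for full-scale fidelity; the desk-scale configuration
used throughout the tests is `base_filters = 16` at 64 x 64.

## The critic

The critic follows the conventional four-stage layout: per stage, two 3x3
convolutions each followed by normalization and a leaky rectifier (slope
0.2), then 2x2 max pooling; after the last stage the features are
flattened into a single fully connected unit. There is deliberately **no
sigmoid and no log** anywhere in its objective: the critic approximates a
Wasserstein-distance witness, not a class probability, and its score is
unbounded.

Two design points were genuinely open:

* **Conditioning.** The critic scores the image and the mask jointly
  (channels concatenated), the standard choice for segmentation GANs; a
  mask-only mode is available (`conditional = FALSE`).
* **Normalization.** Adversarial discriminators conventionally use batch
  normalization, but batch statistics couple the samples of a batch,
  which contradicts the *per-sample* gradient penalty. The default is
  therefore layer normalization (per-sample statistics, learned
  per-channel gain/bias); `norm_kind = "batch"` remains available for
  comparisons, and `"none"` for fixtures.

`stages = 0` degenerates the critic to a single linear unit on the
flattened input. That configuration exists purely as a test fixture: a
linear critic has a constant input gradient equal to its weight vector, so
the gradient penalty has the closed form `(||w|| - 1)^2`, which the
acceptance tests pin exactly.

## Objectives

With critic scores `D(.)`, real pairs `(x, y)` and generated pairs
`(x, G(x))`:

* critic loss: `mean D(fake) - mean D(real) + lambda_gp * GP`,
* generator adversarial loss: `-mean D(fake)`,
* supervised loss: per-pixel cross-entropy plus soft Dice
  (`1 - mean` over non-background labels of
  `(2*sum(pq) + s) / (sum(p) + sum(q) + s)`, smoothing `s = 1e-6`, sums
  pooled over the batch); the generator minimizes
  `lambda_seg * supervised + lambda_adv * adversarial`.

`mean D(real) - mean D(fake)` is recorded every step as the empirical
Wasserstein estimate — the training-progress indicator that standard GAN
losses lack. An optional `adv_variant = "gan"` provides the standard
sigmoid/log losses for baseline comparisons; the Wasserstein objectives
themselves never touch a sigmoid or a log.

**Gradient penalty.** For each sample a uniform `u` mixes the real and
fake critic inputs; the penalty is `mean((||grad_x D(xhat)||_2 - 1)^2)`
over all concatenated input channels. This soft 1-Lipschitz constraint
replaces weight clipping entirely — requesting clipping is a configuration
error, by design. The penalty *value* uses the exact analytic input
gradient. Its *parameter gradient* is second-order; rather than
implementing full double backpropagation, the package computes the
Hessian-vector product with a Pearlmutter-style central difference (two
extra backward passes at inputs displaced by `+-h` along the scaled
gradient direction, `h = 1e-4 / max ||v||`). The tests verify this against
a brute-force finite-difference derivative of the penalty with respect to
every parameter of a small critic (relative error below 1e-4).

**Instance noise.** Gaussian noise (`sigma = 0.05` by default) perturbs
the mask channels of both real and generated critic inputs
(`noise_targets = "fake_only"` restricts it to the generated side). Real masks enter one-hot, so
noise also prevents the critic from keying on exact {0,1} values. Noise on
critic-update inputs and on the generator-update path is left unclipped:
an additive perturbation passes gradients through unchanged, whereas
clipping would zero them at saturated pixels.

## Training loop

Per outer step: `n_critic` critic updates (each on its own batch;
real/fake scored in one combined forward pass), then one generator update
that reuses the last batch's cached generator forward pass. The optimizer
is adaptive-moment estimation with step size 2e-4 and moment coefficients
(0.5, 0.9) — standard WGAN-GP practice. One history record per outer step
stores the critic loss, generator loss, penalty, Wasserstein estimate, and
supervised loss; the identity `critic_loss = -w_estimate + lambda_gp * gp`
holds exactly at every step and is asserted in the acceptance tests.

`n_critic` defaults to **1**, a deliberate deviation from the classical
WGAN recipe of 5. Two reasons: (i) the generator objective here is
dominated by the supervised term (`lambda_seg = 1` vs `lambda_adv = 0.1`),
the conditional regime in which image-to-image adversarial models
conventionally use a single discriminator step; (ii) five critic updates
per step put the package's own scaled-down learning check far outside its
single-CPU time budget. The classical value is one configuration key away
(`train.n_critic=5`).

Every random draw — weight initialization, shuffling, interpolation mixes,
instance noise, phantom jitter, augmentation — derives from a global seed
through a documented 31-bit hash (`child_seed(seed, tag, index)`), so
independent stages have decoupled streams and identical runs are
bit-identical in single-threaded BLAS mode.

## The phantom generator

The synthetic data module emulates the features of a preprocessed chest
radiograph that matter to this architecture, with exact ground truth:

* a low-intensity background (base 0.25) under a smooth vertical
  illumination gradient (amplitude 0.08),
* two bright elliptical lung fields (contrast offset +0.35) — bright
  interiors, as in contrast-enhanced radiograph pipelines,
* a heart ellipse (offset +0.25) overlapping the medial-inferior zone of
  the left lung; where ellipses overlap the heart occludes the lung in
  both intensity and label (single-valued masks, matching disjoint
  color-region ground truth),
* optional faint horizontal rib bands (off by default),
* additive Gaussian pixel noise (sigma 0.03) and clipping to [0, 1].

Dataset generation jitters centers, semi-axes, and contrasts uniformly by
up to a configurable fraction per sample (rejection-sampling the rare
draws that break the heart-lung overlap invariant), with per-sample seed
substreams. The default desk-scale resolution is 64 x 64 (clinical
radiograph pipelines conventionally work at 512 x 512; all geometry
scales proportionally via the CLI's `--resolution`).

What the phantom does **not** emulate: projected rib cages and clavicles,
pathology, scatter, exposure variation, detector noise statistics, or
anatomical shape variability beyond affine jitter. A green learning check
therefore establishes that the architecture, losses, gradients, and loop
are implemented correctly and can fit a multi-organ segmentation task —
not that the model reaches clinical-grade accuracy on real radiographs,
which would require clinical cohorts and GPU-scale training.

## Preprocessing

* **CLAHE** (clip limit 2.0 on the 0-255 histogram scale, 8 x 8 tiles —
  the de-facto standard defaults): tile histograms are clipped, the excess
  redistributed uniformly, and per-pixel mappings blended bilinearly
  between the four surrounding tile transfer functions. Tiles partition
  the image evenly (no empty edge tiles). A constant image maps to a
  constant image. At near-identity clip limits the 8-bit requantization
  can shave histogram entropy slightly; the entropy-increase property is
  asserted at an effective clip limit (8).
* **Resizing**: bilinear for images, nearest-neighbor for masks (labels
  are never blended), half-pixel-center coordinate convention. The
  contract rejects sides below 8.
* **Augmentation**: one affine transform (rotation +-15 degrees,
  translation +-10%, isotropic scale 0.9-1.1) applied identically to
  image (bilinear) and mask (nearest-neighbor), background fill outside
  the canvas. Horizontal flips default to probability 0: the left and
  right lung are distinct labels and a flip would silently swap them.
* **CLAHE order**: applied before resizing, at native resolution —
  enhancing first preserves the native histogram structure.

## Metrics

All five reported measures are pure functions of one-vs-rest pixel
confusion counts: Dice `2TP/(FP+FN+2TP)`, IoU `TP/(TP+FP+FN)`, recall
`TP/(TP+FN)`, precision `TP/(TP+FP)`, F1 `2TP/((TP+FN)+(TP+FP))`. Dice and
F1 are algebraically identical and `Dice = 2*IoU/(1+IoU)`; both identities
are asserted over random inputs as a cross-check of the implementations.
Test-set evaluation pools counts over samples per label (micro-averaging)
before computing metrics; macro-averaging is a flag. The reported mean
covers non-background labels only. Degenerate denominators follow the
both-empty convention: a label absent from both masks scores 1 (perfect
agreement on absence), any other empty denominator scores 0.

## Numerical choices and edge cases

* Probability maps sum to 1 within 1e-6 per pixel (softmax in double
  precision); argmax prediction breaks ties toward the lowest label
  index, so a uniform pixel is background.
* Soft-Dice smoothing 1e-6; cross-entropy guards `log` with a 1e-12
  floor.
* Gradient-penalty direction norms below 1e-12 contribute zero to the
  Hessian-vector product (the penalty gradient vanishes there anyway).
* Any non-finite loss aborts training with the offending step index
  rather than continuing silently.
* Mask colors are exact saturated RGB values; decoding tolerates no
  deviation, so anti-aliased masks must be cleaned upstream. Fully
  saturated pure RGB is this artifact's convention for the legend
  colors.
* The 70/30 split takes `floor(0.7 * n)` training records (862 -> 603 +
  259), a deterministic convention the tests pin.

## Known limitations

* Pure-R + small C++ kernels on one CPU: full-scale (512 x 512,
  `base_filters = 64`) training is out of reach; the package is sized for
  method verification, teaching, and small-data experiments.
* The Pearlmutter finite difference introduces O(h^2) error in the
  penalty's parameter gradient — negligible for training, but the exact
  double-backward is not implemented.
* Batch-norm critics update running statistics during training and score
  deterministically at inference, but persisting those statistics through
  a JSON sidecar round-trips at double-precision text fidelity.
* The PNG codec (hand-rolled because the runtime stack has no PNG
  package) supports 8/16-bit grayscale and 8-bit RGB(A), non-interlaced;
  palette images are rejected with a clear error.
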
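---
title: "Progressive adversarial lesion synthesis: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive adversarial lesion synthesis: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Thermal-ablation lesions (for example after laser interstitial thermal
therapy of the mesial temporal lobe) are scarce in imaging archives, which
starves segmentation networks of training data.  `lesionsynth` implements a
two-stage *progressive adversarial variational auto-encoder* that expands a
small cohort by synthesizing new lesions: first a new binary lesion **mask**
is generated under a lesion-size condition, then a new lesion **intensity
cube** is generated under the guidance of that mask.  Decomposing the task
keeps each generator simple and lets the mask control shape while an
independent latent controls intensity texture.

## Model

Both stages share one backbone.  A 3D convolutional encoder (3x3x3 kernels,
stride-2 downsampling, instance normalization, leaky rectification) maps a
`side^3` cube to a diagonal Gaussian posterior `q(z|x) = N(mu, diag(exp(logvar)))`;
a draw `z = mu + exp(logvar/2) * eps` feeds a decoder that mirrors the
encoder with nearest-neighbour upsampling followed by 3x3x3 convolutions,
ending in a sigmoid so outputs live in `(0, 1)`.

The stages differ only in how the decoder's normalization layers are
modulated:

* **Mask stage - condition embedding block (CEB).**  The lesion-size
  condition `c = log(V) / log(side^3)` (normalized log-volume, 0 for a
  single voxel, 1 for a full cube) passes through a small stack of linear
  layers producing per-channel scale and bias; features are instance
  normalized and transformed as `out = norm(x) * (1 + gamma(c)) + beta(c)`.
* **Lesion stage - mask embedding block (MEB).**  The guiding mask is
  nearest-neighbour resized to the feature resolution; a shared 3x3x3
  convolution followed by two parallel 3x3x3 convolution heads produces
  *voxel-wise* scale and bias fields (spatially adaptive normalization in
  the SPADE style), so the mask imprints shape at every decoder level.

The `(1 + gamma)` form makes zero-initialized heads an exact identity on
the normalized features, which is both a stable starting point and a sharp
unit-test oracle.

A Wasserstein critic (stride-2 convolution stack, leaky rectification,
global mean pooling, linear head) scores each stage's outputs.  The critic
deliberately contains **no normalization layers**: the gradient penalty
constrains per-sample input gradients, and batch-coupled or per-sample
statistics would distort that constraint.

### Losses

With `x_r` real and `x_g` generated samples:

* reconstruction: `L_rec = sum_i ||x_g(i) - x_r(i)||^2` (mean squared error
  summed over voxels within a sample),
* latent prior: `L_kl = sum_i KL[q(z|x_r(i)) || N(0, I)]`, evaluated in
  closed form for diagonal Gaussians,
* critic: `L_D = E[D(x_g)] - E[D(x_r)] + lambda * E[(||grad_xhat D(xhat)||_2 - 1)^2]`
  with `xhat = u*x_r + (1-u)*x_g`, `u ~ U(0,1)` per sample and `lambda = 10`,
* generator: `L_G = -E[D(x_g)]`, combined as
  `w_adv * L_G + w_rec * L_rec + w_kl * L_kl`.

The sums over the mini-batch are averaged by default (`reduce = "mean"`)
so loss magnitudes do not depend on batch size; `reduce = "sum"` restores
the raw sums.  The relative weights are not dictated by the model itself;
the full-scale defaults are `w_rec = 1`, `w_kl = 1e-3`, `w_adv = 1e-2`
(reconstruction-dominated early training), and they are exposed in every
configuration surface.

### Differentiation engine

No automatic-differentiation framework for R is available to this package,
so the networks run on a small reverse-mode tape (`R/tape.R`).  Primitives
(GEMM, patch gather/scatter for convolutions, permutations, elementwise
maps) define backward rules that themselves build tape nodes, so a gradient
is an ordinary graph and can be differentiated again.  The WGAN-GP critic
update exploits exactly this: the penalty is a function of
`d D(xhat) / d xhat`, and its parameter gradient is obtained by a second
backward pass through the first.  Correctness is pinned by
finite-difference tests at every level (single ops, encoder/decoder stacks,
and the penalty itself) and by closed-form oracles (a linear critic with
weight norm `w` must incur penalty `lambda * (w - 1)^2` exactly).

Instance normalization is implemented as a fused primitive with a
hand-derived first-order adjoint (`gx = (g - mean(g) - xhat * mean(g*xhat)) / sigma`);
since normalization layers never occur inside the critic, second-order
differentiability is not needed on that path.

### Conditioning the posterior

An early design conditioned only the decoder (CEB on its normalization
layers) and left the encoder unconditional.  That variant reconstructs
well but fails at *sampling time*: the posterior latent already encodes
lesion size, so decoder and encoder can settle on a solution in which the
condition input is ignored or even inverted - at inference, where `z` is
drawn from the prior independently of `c`, the generated volume then does
not track the condition (Spearman correlations near zero or negative
across a wide range of KL weights).  The package therefore uses the
standard conditional-VAE arrangement: the condition is appended to the
encoder bottleneck, making the posterior `q(z | x, c)`.  Under KL pressure
the encoder can drop the size information that `c` supplies for free, and
the decoder must then take size from `c`, which restores a positive
condition-volume relationship when sampling from the prior.

## Synthetic phantoms

The phantom generator supplies the statistical structure the model
assumes, with no external data: a lesion mask built from 1-3 overlapping
random ellipsoids (guaranteed 26-connected; volume held inside a requested
range by hard rejection), a smooth brain-like background (Gaussian-blurred
random field rescaled to `[0.3, 0.7]`), and a lesion interior shifted by a
`texture_contrast` offset carrying multiplicative speckle.  Everything is
reproducible bitwise from the spec's seed, and per-item seeds for datasets
derive from a master seed.

What the phantoms do *not* emulate: MR physics (bias fields, noise
statistics, partial-volume effects), anatomy (ventricles, cortical
structure), multi-class lesions, or scanner variability.  Tests passing on
phantoms therefore demonstrate that the machinery - conditioning, guidance,
adversarial optimization, reproducibility - works as specified; they are
not evidence about clinical image fidelity.

## The desk-scale study (`toy_protocol()`)

All behavioural guarantees are exercised at a scale a single CPU handles
in minutes: 200 phantoms of side 16 (lesion volumes 20-1200 voxels, 1-2
lobes, texture contrast 0.3), networks with 2 levels, 3 base channels and
latent dimension 32, batch size 20, one critic step per generator step, 50
epochs per stage.  The wide lesion-volume range is itself part of the
design: a study of *size conditioning* needs the conditioned variable to
span a real dynamic range (here the condition `c` spans roughly
0.36-0.85), otherwise the condition pathway's gradient is buried in
prior-sample variance.  For the same reason the raw condition, which
naturally lives in a narrow band around 0.5, is centred and spread
(`(c - 0.5) * 4`) before entering the embedding stacks.  Two further
deliberate departures from the full-scale protocol are part of the toy
conditions:

* learning rate `2e-3` instead of `5e-5`: Adam moves each parameter by at
  most `lr` per step, so the full-scale rate over 50 toy epochs (about
  500 updates) could change weights by at most ~0.025 - far too little to
  measure learning; `2e-3` is a conventional Adam rate for networks of
  this size;
* mask-stage KL weight `5` (lesion stage `0.1`) instead of `1e-3`: with
  voxel-summed reconstruction the KL term must carry real weight for the
  information-bottleneck mechanism above to push size out of the latent at
  this scale; a sweep over {0.5, 1, 5} showed the bottleneck only binds
  at the top of that range.

The full-scale defaults (`5e-5`, 1000 epochs, batch 13, `w_kl = 1e-3`,
side 64, 4 levels, latent 128) remain the package defaults everywhere else.

The study's measured quantities (recomputed by `scripts/acceptance.R`) are
the per-voxel reconstruction MSE at the first and last epoch of each
stage, the Dice overlap between held-out guiding masks and the Otsu-based
high-contrast support of lesions synthesized under them, the Spearman
correlation between the size condition and generated mask volume over 50
prior samples, reconstruction PSNR/SSIM/NMSE under real masks, and the
wall time of a 100-item cohort.

## Numerical choices

* Cube extraction centres on the mask centroid (rounded), zero-pads at
  volume borders, and min-max normalizes with the window stored for exact
  inversion; a degenerate window (constant cube) maps to zeros.
* Coordinates are 0-based, cube origins are inclusive lower corners,
  ranges half-open.  Normalization is per cube (per-volume normalization
  is a caller choice; the window is recorded either way).
* Paste-back replaces intensities inside the new mask with de-normalized
  generated values, optionally feathered by a Gaussian-blurred alpha mask
  (default sigma 1 voxel); `blend_sigma = 0` is exact replacement, the
  contract used in round-trip tests.
* Mask binarization threshold 0.5; raw sigmoid masks may carry speckle, so
  the largest 26-connected component is kept (an extension beyond the
  two-stage model itself; it can be disabled).  Empty post-threshold masks
  are flagged, not raised, so cohort synthesis can resample (bounded
  retries, then flagged).
* SSIM uses Gaussian-weighted local statistics (sigma 1.5), window 7 for
  sides up to 32 and 11 otherwise; with window 11 the implementation
  matches scikit-image's 3D `structural_similarity` to 1e-6 (verified in
  the test suite against that reference).  NMSE is reported in percent of
  the reference image's energy.
* Surface distances (ASD, 95th-percentile Hausdorff) use 6-neighbour
  boundary voxels and exact pairwise distances, in voxel units by default
  with optional anisotropic spacing.
* Instance-norm epsilon 1e-5; Adam betas (0.5, 0.9); leaky-slope 0.2;
  upsampling is nearest-neighbour + convolution (avoids checkerboard
  artifacts of transposed convolutions).

## Known limitations

* The tape is CPU-only and single-threaded beyond BLAS; full-scale (side
  64) training is possible but slow - the design target here is method
  correctness at desk scale, not throughput.
* "Progressive" refers to the mask-to-lesion cascade, not to progressive
  resolution growth; no 2D variants or multi-channel inputs.
* Condition sampling at inference defaults to uniform over the training
  condition range; nothing constrains extrapolation beyond it.
* The critic-based losses make training non-monotone; only the
  reconstruction trend, not per-epoch decrease, is guaranteed by the
  tests.
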
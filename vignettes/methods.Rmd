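---
title: "Hybrid classical and GAN-derived features for thyroid nodule classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid classical and GAN-derived features for thyroid nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thyrocad)
```

## The problem and the method

Thyroid nodules are routinely triaged on B-mode ultrasound, where a handful
of sonographic cues carry most of the diagnostic signal: malignant nodules
tend to be taller than wide, hypoechoic (darker than the surrounding
parenchyma), blur-margined, solid and peppered with microcalcifications;
benign nodules tend to be round or wide, hyperechoic, sharply marginated and
often cystic. thyrocad implements a computer-aided diagnosis pipeline that
classifies nodule images as benign or malignant by fusing two feature
families:

* **classical features** — histograms of oriented gradients (HOG),
  uniform local binary patterns (LBP), and local keypoint descriptors
  (difference-of-Gaussians and box-filter-Hessian detectors) encoded as
  bag-of-visual-words histograms over a k-means vocabulary;
* **a deep feature** — the 960-dimensional vector obtained from the
  discriminator of a class-conditional residual GAN by global-average
  pooling the output of the last residual module at each distinct channel
  width (64, 128, 256, 512) and concatenating the pooled vectors in
  increasing-width order.

The fused feature feeds an ensemble classifier (random forest by default,
AdaBoost as the alternative), evaluated by stratified k-fold
cross-validation with accuracy, specificity and sensitivity computed from
pooled confusion counts, malignant being the positive class.

## The discriminator and the 960-dimensional feature

The discriminator is fixed by design: a 7x7 stride-2 convolution with 64
channels and batch normalization, a 2x2 max-pool, then six 3x3 residual
modules with channel widths 64, 64, 128, 128, 256 and 512 (ResNet-v1 basic
blocks; stride 2 and a projected shortcut at each width increase), global
average pooling, and two fully connected heads: a 1-unit sigmoid
authenticity head (real vs generated) and a 2-unit softmax benign/malignant
head. The six widths sum to 1152, but the deep feature is spliced from the
**distinct** widths only — taps sit after the *last* module of each width
group — giving 64 + 128 + 256 + 512 = 960 dimensions. This is the only
placement consistent with a feature "composed of the output features of the
residual modules with different numbers of channels" whose total is 960.
The final 512-wide pooled vector feeds both heads and doubles as the last
tap.

The generator is class-conditional: a latent vector concatenated with a
one-hot class label is projected to a 4x4 map and upsampled through
residual blocks (nearest-neighbor x2, 3x3 convolution + batch norm, 1x1
shortcut) to the target resolution, ending in a sigmoid so pixels live in
(0, 1). Training follows the auxiliary-classifier convention: the
discriminator minimizes adversarial binary cross-entropy on its
authenticity head (both real and generated inputs corrupted by Gaussian
pixel noise) plus class cross-entropy on real images and on generated
images with their conditioning labels; the generator minimizes the
adversarial term with flipped targets plus the class term. Both use Adam
(learning rate 2e-4, beta1 0.5 — the standard DCGAN setting; the
discriminator's rate and the class-loss weight are exposed and are raised
in the package's own experiments, see below). The input noise has standard
deviation 0.05 on [0, 1]-scaled pixels at the first epoch and anneals
linearly to zero, a common stabilizer; the noise level is otherwise
unspecified by the method and is exposed as a parameter.

Because no deep-learning framework is available to R in this environment,
the network core is implemented in the package itself: compiled
im2col/col2im kernels (channel-first layout) plus BLAS matrix multiplies,
with hand-derived backpropagation for every layer. The test suite verifies
each gradient against central finite differences to about 1e-9 relative
error; the whole GAN stands on that check.

### Extraction resolution

The GAN trains at a reduced resolution (64x64 by default) to stay
desk-scale, but the deep feature is extracted at the common analysis
resolution of the classical features (128 by default). Global average
pooling makes the architecture resolution-agnostic, and extracting at
native resolution lets the early taps pool speckle-scale texture
statistics that a downsampled input destroys; in the package's synthetic
experiments this single choice moves deep-feature-only held-out accuracy
from about 0.90 to about 1.0 at no training cost.

## Image enhancement

Four monotone-or-local transforms are provided, each with an exact
per-pixel contract and a brute-force oracle in the tests:

* histogram equalization: `round(255 * CDF(v))`, `CDF(v) = #{pixels <= v}/N`,
  half-up rounding (the textbook discrete form; the method itself gives no
  formula);
* logarithm transform: `255 * (log(H+1) - min) / (max - min)` — the base
  cancels; constant images raise a typed degenerate-range error rather than
  dividing by zero;
* gamma correction: `255 * (H / max H)^(1/gamma)`, gamma > 0;
* Laplacian sharpening: the 3x3 mask `[[0,1,0],[1,-4,1],[0,1,0]]`
  (positive polarity; the negative operator is its negation), edge
  replication at the border, sharpened image = input minus the
  positive-polarity response, clipped. Both polarities therefore sharpen
  identically and differ only in the sign of the reported response.

All rounding is half-up; outputs are clipped to [0, 255].

The selective-application **policy** reflects an empirical finding of the
underlying method: equalizing *all* training images hurts, equalizing only
the malignant training images helps, presumably because it normalizes the
hypoechoic class without destroying the echogenicity contrast that
separates the classes. `apply_policy()` therefore supports `none`,
`malignant_train_only` and `all_train`; test images are never modified
under any policy, and policy and transform are orthogonal settings.

## Classical features

All per-image features are computed after resizing to a common square side
(128 by default) so feature lengths are dataset-constant.

**HOG** — central-difference gradients, unsigned orientations on [0, 180),
9 bins, gradient magnitude hard-assigned to its orientation bin, cells of
8x8 pixels, blocks of 1x1 cells strided by one cell (the best-performing
setting of the method's sweep), L2-hys block normalization (L2, clip 0.2,
renormalize, zero-guard). Only gradients enter, so the feature is exactly
invariant to global additive intensity offsets.

**LBP** — radius 2, 16 circularly sampled neighbors (the swept setting),
`neighbor >= center` sets the bit, uniform-pattern binning (patterns with
at most two circular transitions get their own bin, the rest share one:
59 bins for n = 8, 243 for n = 16), L1-normalized histogram. Off-grid
neighbors are bilinearly interpolated by default. One subtlety is
documented rather than hidden: bilinear interpolation mixes intensity
values *before* the threshold comparison, so exact invariance under
arbitrary monotone intensity remappings holds only for the
nearest-neighbor sampling variant (`lbp_config(interpolate = FALSE)`);
under bilinear sampling the exact invariance group is affine. The tests
assert exactly that split.

**Keypoints** — two self-contained detectors behind one contract, both
upright (no dominant-orientation normalization; probes impose a roughly
fixed orientation and the augmentation stage covers the right-angle
rotation group):

* `sift_like`: Gaussian scale pyramid (scale step 2^(1/3), base sigma 1.6,
  a standard "-1 octave" upsampling so speckle-scale blobs survive the
  base smoothing), 3x3x3 extrema of the DoG stack above a contrast
  threshold, 128-dimensional 4x4x8 gradient-orientation descriptors.
* `surf_like`: integral-image box-filter approximation of the Hessian
  determinant, `Dxx*Dyy - (0.9*Dxy)^2` with area-normalized filters of
  sizes 9, 15, 21, 27; 3x3x3 extrema across the scale stack; 64-dimensional
  4x4 Haar-response descriptors (sum dx, sum |dx|, sum dy, sum |dy|).

Detector thresholds default to values that yield a few dozen keypoints on
speckled phantom images (about 40 for the DoG detector, about 70 for the
Hessian detector on a 128 phantom) — enough to populate a vocabulary
without flooding it.

**Bag of visual words** — seeded k-means++ initialization followed by at
most `iterations` full Lloyd passes; the iteration budget mirrors the
method's "Iter" parameter and one pass is the default. Assignment ties go
to the lowest centroid index; a centroid whose cluster empties keeps its
position; vocabularies default to k = 1000. Pools larger than
`bow_max_descriptors` (4000 by default) are subsampled with a seed before
clustering — the usual practice for visual vocabularies; encoding always
uses every descriptor. Encoding is a k-length nearest-centroid count
histogram, optionally L1-normalized; an empty descriptor set encodes to
the zero vector.

## Fusion, classifiers, evaluation

Feature blocks are fused by concatenation in the fixed order
[conventional, deep], each block standardized column-wise with
training-split statistics first, so the 960-dimensional block cannot
numerically dominate a short classical one; constant columns become zeros
rather than NaN. The random forest is a 500-tree probability forest with
sqrt(d) candidate features per split (ranger backend, single-threaded,
seeded); AdaBoost is discrete SAMME over depth-1 rpart stumps, 200 rounds,
implemented in-package since no AdaBoost package is available here. The
decision threshold is 0.5 on the malignant probability and exact ties go
to benign (the 0 label).

Evaluation is stratified k-fold cross-validation (5 folds by default).
Everything fitted — enhancement targets, codebooks, standardization
statistics, the GAN, the classifier — sees only the fold's training
portion; a digest-based leakage guard asserts that no held-out image
appears among fit-time inputs. Accuracy, specificity and sensitivity
follow the standard confusion-count definitions with malignant positive;
pooled metrics are recomputed from summed per-fold counts, and a
denominator of zero yields a flagged NA, never a silent zero. The
identity accuracy = (P·sensitivity + N·specificity)/(P + N) is asserted on
every report. `augment_training()` implements the rotate-and-flip
augmentation (rotations 90/180/270 plus horizontal flip, an eightfold
training-split expansion); the reading of the original description's
"slip" as "flip" is the only sensible interpretation and is confined to
this one function.

## The synthetic phantom generator

Real thyroid ultrasound collections cannot ship with a package, so every
stage is exercised on seeded synthetic phantoms whose class-dependent
morphology encodes the classic sonographic cues:

| parameter | benign preset | malignant preset | cue |
|---|---|---|---|
| aspect_ratio (h/w) | 0.8 | 1.5 | taller-than-wide |
| margin_blur_sigma (px) | 0.5 | 4 | sharp vs blurred margin |
| echogenicity_offset | +40 | -40 | hyper- vs hypoechoic |
| calcification_count | 0 | 6 | microcalcifications |
| interior_texture_sigma (px) | 1.5 | 0 | cystic vs solid interior |

A phantom is a smooth low-frequency background (about intensity 110,
amplitude 12) holding one ellipse of the given aspect ratio placed
uniformly at random but at least 10% of the image side away from every
border, softened by the margin blur, shifted by the echogenicity offset,
and dotted with bright specks; multiplicative speckle
(gamma-distributed, unit mean, shape 16) is applied last, then clipping
and 8-bit quantization. The interior-texture parameter spatially smooths
the speckle field inside the nodule (renormalized to unit mean) — benign
interiors are coarse and homogeneous, malignant ones keep the fine grain.
This cue matters for testability: HOG is offset-invariant and LBP is
order-invariant, so neither can see echogenicity; margin, calcification
and texture cues are what make *every* classical feature separate the
default presets, which the test suite requires. The hard pre-noise ellipse
mask rides along as an attribute so tests can measure the generator's own
geometry.

What the phantoms do **not** emulate: anatomy around the nodule, beam
attenuation and shadowing, probe-dependent point-spread functions, cystic
fluid level artifacts, or multiple nodules. Passing tests therefore show
pipeline correctness and qualitative orderings (e.g., fusion not hurting),
not clinical performance.

## Problem sizes and numerical choices

The test suite runs everything at deliberately small scale, chosen as the
package's own compromise between statistical resolution and a desk-scale
run: the standard synthetic study is 100 benign + 100 malignant phantoms
of side 128; classical-arm cross-validation uses 5 stratified folds; the
GAN trains at 64x64 on a class-stratified subsample of at most 64 training
images for 4 epochs (batch 16, discriminator learning rate 1e-3, class
loss weight 2, input noise 0.02) and deep features are extracted at 128;
the fusion comparison across feature arms uses five independent
stratified 80/20 holdouts rather than nested 5x5-fold cross-validation.
Smoke tests use 16-32 images at 32x32 with 1-2 epochs.

Other numerical choices: half-up rounding everywhere an 8-bit intensity is
produced; degenerate inputs (constant images for range-normalizing
transforms, all-zero confusion tables, empty descriptor pools smaller than
k) raise typed errors instead of propagating NaN; batch-norm epsilon 1e-5
and momentum 0.1; Adam epsilon 1e-8; assignment and pooling ties broken
deterministically (lowest index / first maximum). All randomness descends
from one integer seed through a documented stage-name hash
(`derive_seed()`), so identical configuration and seed reproduce every
artifact bit for bit on a single-threaded CPU.

## Known limitations

* The phantom generator is a testing instrument, not an ultrasound
  simulator; accuracies on it say nothing quantitative about clinical data.
* The hand-written network runs on one CPU; at clinical scale (hundreds of
  images, hundreds of epochs) a framework-backed reimplementation of the
  same architecture would be required.
* The keypoint detectors are upright variants; images with arbitrary
  rotation would need dominant-orientation estimation.
* AdaBoost uses stumps only, and no probability calibration is attempted.
* The fixed train/test split recorded in a manifest is advisory once
  cross-validation is requested; the fold assignment governs, which is the
  only leakage-safe reading of a protocol that states both.
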
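---
title: "Standardizing and segmenting multi-station Dixon abdominal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing and segmenting multi-station Dixon abdominal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-body MRI in epidemiological imaging acquires the abdomen in several
overlapping table stations, each reconstructed in the four contrasts of a
two-point Dixon sequence: water, fat, in-phase (proportional to water +
fat) and opposed-phase (proportional to |water − fat|). Field of view,
resolution, station count and intensity scale differ between scanners and
protocols, and smooth multiplicative coil inhomogeneity ("bias field")
modulates all contrasts. Cross-cohort analysis of abdominal organs
therefore needs (i) a standardization pipeline that turns heterogeneous
station stacks into one comparable volume set and (ii) a segmentation
model for the eight organs of interest: liver, spleen, the two kidneys,
the two adrenal glands, pancreas and gallbladder.

`abdomenseg` implements both, plus the phantom generator, training loop,
multi-view inference and evaluation metrics around them.

## Standardization pipeline

`preprocess_study()` composes, in order: reorientation to RAS → (optional
per-station bias correction) → stitching → bias correction → resampling →
ROI crop → (optional intensity normalization). Each step records its
parameters in a provenance list. Choices that were genuinely open:

* **Station blending.** Overlap intensities are blended with a logistic
  profile centred at the overlap midpoint, so slices near a station
  boundary — the most artifact-prone — get little weight, and the two
  stations' weights sum to exactly one everywhere. The steepness default
  is chosen per overlap so the profile reaches 0.05/0.95 at the overlap
  edges; a fixed steepness can be configured. Chains of more than two
  stations are folded left to right in table order, which is deterministic
  and matches acquisition order.
* **Bias-field correction.** The field is estimated from the in-phase
  contrast only and divided out of all four contrasts, which keeps the
  Dixon relations intact. The estimator fits a 3D polynomial (total degree
  4 by default) to the log intensities inside a foreground mask, with a
  few trimming iterations that drop voxels deviating strongly from the
  smooth model — organ tissue whose intrinsic brightness differs from the
  dominant tissue class would otherwise leak anatomy into the field. The
  field is normalized to unit geometric mean so global intensity scale is
  preserved. Degree, mask threshold and trimming are configuration
  entries. Per-station correction before stitching exists but is off by
  default; the post-stitch correction is the primary one.
* **Geometry.** Output resolution defaults to 2 × 2 × 3 mm. The crop box
  is half-open `[min, max)` in standardized mm coordinates, so boundary
  voxels are counted once and all subjects land on identical grids. The
  ROI is a required per-dataset configuration value (the shipped phantom
  configs carry matching boxes); automatic ROI localization is out of
  scope.
* **Intensity normalization** defaults to `none`; histogram matching
  (quantile-landmark mapping against a configured reference scan) and a
  linear min/max transform are available but not part of the default
  path.

Label maps follow the same geometric path (reorientation,
nearest-neighbour resampling, identical crop) via
`preprocess_labelmap()`, so labels can never acquire interpolated values.

## The network

`build_abdomennet()` constructs a 2D encoder/decoder: three encoder
blocks, a bottleneck, three decoder blocks, and a 1 × 1 convolution +
softmax classifier. Every block is a *dense block* of three
BN → PReLU → convolution units whose third unit consumes the channel
concatenation of the first two units' outputs; each unit outputs
`filters` channels (64 by default, 5 × 5 kernels). Dropout (0.2) closes
each block. A CSSE module — channel squeeze-and-excitation (global average
pool → two-layer gate → per-channel sigmoid) plus spatial
squeeze-and-excitation (1 × 1 convolution → per-pixel sigmoid) — follows
every block; the two recalibrated maps are combined by addition, with a
channel-reduction ratio of 2. Encoders end in 2 × 2 max pooling whose
argmax indices are passed through the skip connections and reused by the
matching decoder's un-pooling, so upsampled activations return to their
exact pre-pooling positions.

All convolutions except those of the first encoder and last decoder are
*octave convolutions*: channels are split by a fraction α (0.5 by
default) into a full-resolution and a half-resolution branch, and each
layer computes four paths (high→high; high→low via average pooling then
convolution; low→low; low→high via convolution then nearest upsampling),
summing per output branch. With α = 0 every layer degenerates to a plain
convolution, which the test suite exploits as an architectural oracle
against an independently composed plain-convolution twin.

Decisions the architecture left open, resolved here:

* Both octave branches are max-pooled with their own indices, and both are
  index-unpooled in the decoders, preserving exact spatial mappings for
  the low branch too.
* The octave merge back to a single map happens in the last unit of
  decoder 2 (α_out = 0), so decoder 1 and the classifier are plain.
* The bottleneck carries a CSSE module like every other block; the
  classifier has neither CSSE nor dropout.
* Odd spatial sizes are padded to even before pooling and cropped after
  un-pooling, so grids need not be powers of two.
* PReLU has one learnable slope per channel, initialized at 0.25; weights
  are initialized uniformly in ±1/√fan-in from the model seed, making
  builds bit-reproducible.

There is no deep-learning framework underneath: forward and backward
passes are written in this package, with the convolution, pooling and
normalization inner loops as RcppArmadillo kernels. The convolution uses
an implicit-GEMM scheme (one padded copy of each sample; the K² kernel
taps become K² accumulated GEMMs on constant-offset views) and runs its
GEMMs in single precision, which is ample for unit-scale image features
and SGD gradients; everything else is double precision. Gradient
correctness is pinned by exact small-case references and
finite-difference checks in the test suite.

## Loss, weight maps and training

The loss is a weighted logistic term plus a smoothed Dice term:

$$\mathcal{L} = -\sum_x \omega(x)\, g_l(x) \log p_l(x)
  \;-\; \operatorname{mean}_l
  \frac{2\sum_x p_l(x) g_l(x) + 1}{\sum_x p_l(x) + \sum_x g_l(x) + 1}.$$

The +1 smoothing makes an absent class contribute its maximal value 1
instead of a penalty — essential for 2D slices where most organs are
missing from most slices; empty-organ slices are kept in training. The
Dice term is aggregated as the mean over all classes (background
included), so a perfect prediction scores exactly −1. The written form of
the logistic term is a sum over pixels; the optimizer uses the pixel-mean
form (`pixel_reduction = "mean"`) so the usable learning rate does not
depend on slice size — `combined_loss()` exposes both. Probabilities are
clamped at 10⁻⁷ inside the logarithm. Weight maps are
`ω(x) = 1 + w_class·c(label(x)) + w_edge·boundary(x)` with
median-frequency class weights `c` estimated over the training set and a
boundary indicator marking pixels whose label differs from a
4-neighbour; both coefficients default to 1.

Training (`train_view()`) runs SGD with momentum 0.9 at `base_lr` (0.01)
until `swa_start_epoch`, then switches to a constant `swa_lr` and takes an
equal average of the weights after every epoch — stochastic weight
averaging. Defaults follow the full-scale protocol: 100 epochs, batch 10,
SWA from epoch 75, SWA learning rate 0.05. The averaged weights get their
batch-norm statistics recalibrated by one pass over the training data
(exact data moments), since averaged weights have no matching running
statistics. The model with the highest validation Dice is checkpointed
separately; inference defaults to the SWA weights.

## Multi-view inference

Three networks (axial, coronal, sagittal) each predict slice-wise softmax
probabilities, restacked into probability volumes on the study grid and
averaged with equal weights; the argmax (ties to the lowest class index,
i.e. background first) yields the label map. Because voxels are
anisotropic, coronal and sagittal slices are non-square in mm; they are
fed at native voxel resolution without per-view resampling. `segment()`
accepts any non-empty subset of views and renormalizes the mean by the
number provided, so single-view segmentation works unchanged.

## Metrics

`dice_score()` is 2|P∩G|/(|P|+|G|); a class absent from both volumes is
reported as `NA` ("undefined") and excluded from means, absent from
exactly one as 0. `assd()` extracts surfaces as mask voxels with a
face-adjacent (6-connectivity) background neighbour — array boundaries
count as background — measures voxel-centre distances in mm under the
anisotropic spacing, and averages the two directed mean distances
weighted by surface size. An exhaustive all-pairs oracle in the test
suite pins the implementation to 10⁻⁹.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a body-shaped ellipsoid containing eight
ellipsoidal organs (one liver-sized, one spleen-sized, paired kidneys,
paired tiny adrenals, an elongated pancreas, a small gallbladder), each
with a water fraction chosen from typical soft-tissue Dixon behaviour
(e.g. 0.70 liver, 0.92 gallbladder), jittered per subject in position,
size and signal. Water and fat maps generate the four contrasts exactly
(in-phase = water + fat, opposed-phase = |water − fat|); one smooth
multiplicative bias field — a separable low-frequency cosine product
bounded in [1 − a, 1 + a] — is applied identically to all contrasts,
emulating correctable coil inhomogeneity without modelling coil physics;
Gaussian noise is added after the bias, since measurement noise is
post-gain. The volume is split into overlapping stations (crops, not
re-renders) whose affines encode the table offsets. Organs may not
overlap; a contested voxel goes to the earlier-listed label. Layout
defaults live in `inst/extdata/phantom_default.yaml` (and a reduced
`phantom_small.yaml`).

The phantom deliberately omits T1/T2 relaxation, chemical shift,
breathing motion, inter-station intensity jumps and anatomical texture.
Passing tests on phantoms therefore demonstrate that the pipeline's
geometry, contrast handling, optimization and metrics are correct — not
that cohort-level accuracy transfers; the reported cross-cohort accuracy
of the original protocol requires restricted cohort data and is out of
scope here.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run a scaled-down version of
the full protocol, chosen as the smallest configuration that still
exercises every mechanism: the reduced 64 × 64 × 44 phantom grid
(64 × 64 × 35 voxels after standardization), 16 convolutional filters,
10–12 epochs with SWA over the last 3–4, batch size 10, and an SWA
learning rate of 0.005 matched to the reduced schedule (the full-scale
default of 0.05 belongs with the 100-epoch protocol). Under these
conditions an axial network reaches validation Dice ≈ 0.93 and held-out
Dice ≈ 0.95 on the three largest synthetic organs; the adrenal-sized
organs remain hardest, mirroring the behaviour expected on real data.
Cross-validation splitting (`split_into_folds()`) is provided, but the
shipped experiments use a single fixed split.

## Known limitations

* The bias-field estimator is a global polynomial with robust trimming;
  fields with spatial frequency beyond the configured degree are only
  partially removed.
* The ROI crop is a fixed per-dataset box; subjects whose organs fall
  outside it are silently truncated.
* Training is single-threaded CPU; the implementation targets
  correctness and reproducibility at phantom scale, not cohort-scale
  throughput.
* Histogram matching uses a single configured reference scan and is not
  auto-selected.
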
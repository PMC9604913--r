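---
title: "SIFT images as CNN inputs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SIFT images as CNN inputs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The representation

A convolutional classifier normally consumes raw intensities. `siftcnn`
instead feeds it a *SIFT image*: for every pixel of a single-channel image,
a dense SIFT descriptor is computed over the `N x N` neighborhood of that
pixel, and the resulting `M = 128` histogram values become the channel
vector at that spatial position. An `H x W` image therefore becomes an
`H x W x 128` tensor with unchanged spatial size. Each descriptor is a
4 x 4 grid of cells, each holding an 8-bin histogram of gradient
orientations weighted by gradient magnitude, L2-normalized with the classic
clip-renormalize step. The network then learns spatial relations between
local gradient-orientation statistics rather than between raw intensities,
which is what makes the scheme robust when *sub-regions* of an image rotate
independently (fluorescence cell textures, cloud fields, mouth regions in
lip reading — tasks where local rotation must not change the label).

```{r, eval = FALSE}
library(siftcnn)
img <- analytic_fixtures()$checkerboard
S <- compute_sift_image(img)      # 16 x 16 x 128
dim(S)
```

## Descriptor conventions

The neighborhood size defaults to `N = 8`, the *dominant scale*: in the
source workflow it is estimated as the arithmetic mean of the scale values
a keypoint detector reports over training images
(`estimate_dominant_scale()`); the detector itself is out of scope here.
Every choice the classical descriptor leaves open is fixed and documented:

* **Window.** For even `N`, the window of pixel `(r, c)` covers rows and
  columns `r - N/2 .. r + N/2 - 1`; its geometric center is the half-pixel
  `(r - 0.5, c - 0.5)`.
* **Gradients.** Central differences; orientation `atan2(dy, dx)` over the
  signed range `[0, 2*pi)`, so the 8 bins are 45 degrees wide with centers
  at `k * 45` degrees. Pixels with zero magnitude carry no mass.
* **Boundaries.** The image is half-sample-symmetric padded (`reflect`,
  default) or zero padded by `N/2`, so border pixels get descriptors and
  the output keeps the input's spatial size.
* **Binning.** Soft by default: each sample splits linearly between its two
  nearest orientation bins and bilinearly between neighboring cells
  (`soft_binning = FALSE` switches both to nearest assignment). No Gaussian
  window over the patch, following common dense-SIFT practice.
* **Normalization.** `l2_clip`: L2-normalize, clip entries at 0.2,
  renormalize; an epsilon of 1e-12 keeps all-zero descriptors (constant
  regions) exactly zero. After the final renormalization individual entries
  may exceed 0.2 — that is inherent to clip-then-renormalize.
* **Orientation normalization** (rotating each descriptor to its dominant
  orientation) is off by default, as in dense-SIFT practice. A light
  variant — a cyclic shift of the orientation bins to the window's dominant
  bin — is available behind `orientation_normalized = TRUE`. It shifts bins
  only; it does not resample the spatial grid, so it is not a full
  rotation normalization. The dominant bin is chosen as the lowest index
  within a 1e-9 relative tolerance of the maximum so that exact ties
  (which mirror padding produces at borders) resolve identically in every
  code path.
* **Dynamic range.** The SIFT image is fed to the CNN as-is (values in
  `[0, 1]`); no per-channel standardization.

Two independent code paths compute the descriptor: `descriptor_at()` is a
deliberately simple nested loop over window samples, and
`compute_sift_image()` is the vectorized production path. The test suite
holds them equal elementwise within 1e-10 over an analytic fixture battery
(constant, ramps, step edge, checkerboard, seeded noise images).

## Exact equivariances

Because gradients rotate with the image, rotating the input by a quarter
turn permutes descriptor channels deterministically: the 4 x 4 cell grid
turns by 90 degrees and every orientation bin shifts by `bins/4`.
`rot90_channel_permutation()` returns that permutation;
`flip_channel_permutation()` gives the horizontal-flip analogue
(cell-column mirror, bin reflection `b -> (bins/2 - b) mod bins`). One
geometric subtlety: with the even-sized window anchored at
`r - N/2 .. r + N/2 - 1`, the descriptor grid of the rotated image lines up
with the original grid one pixel off a plain spatial quarter-turn (the
window center sits at a half-pixel, and quarter-turning the pixel lattice
moves that center by one pixel along one axis). On that alignment —
implemented in `sift_rot90_residual()` and `sift_flip_residual()` — the
equivariance is *exact* (residuals at machine precision) away from an
8-pixel boundary margin, with default descriptors (no orientation
normalization). Photometric invariance is exact as well: any `a * I + b`
with `a > 0` rescales all magnitudes uniformly, which normalization
removes.

These identities double as strong correctness tests: they are properties of
the mathematics, not of the implementation, and any binning or indexing
slip breaks them at the first decimal.

## The classifiers

No deep-learning framework is assumed: the package carries a compact CNN
engine in vectorized R on top of BLAS (im2col convolution, batch
normalization, ReLU, max pooling, residual blocks, global average pooling,
softmax cross-entropy, SGD with momentum and weight decay). Backward passes
are exact gradients; they are validated against numerical differentiation
in development and by overfit/gradient-flow tests in the suite.

`build_backbone()` offers two topologies with one contract (features from
global average pooling, then a linear classifier):

* `resnet18` — the standard 18-layer residual network, 512-dimensional
  features; pixel and SIFT variants differ only in the first convolution
  (1 vs 128 input channels).
* `tiny` — two conv-BN-ReLU stages (stride 2, 16 then 32 channels) with
  global average pooling; 32-dimensional features. This is the desk-scale
  profile used by the package's own benchmark and tests, where full
  ResNet-18 training would add nothing but runtime; shape and forward-pass
  behavior of `resnet18` are tested directly.

For image sequences, `build_reduction_stem()` implements the
channel-reduction stem: 3x3 convolutions with strides 2, 2, 1 and padding
1 mapping 128 -> 64 -> 64 -> 64 channels, each followed by batch
normalization and ReLU (the activation scheme is this package's choice;
only kernel/stride/padding/channels are prescribed). An 88 x 88 x 128 SIFT
image becomes 22 x 22 x 64 — a spatial downscale by four. Frames are
encoded independently (`sequence_to_sift()`, `build_sequence_backbone()`)
and aggregated by `temporal_aggregate()`, whose default is temporal mean
pooling; any stronger sequence encoder (e.g. a temporal convolutional
network) can be substituted behind the same signature and is deliberately
out of scope.

**Late fusion.** A pixel backbone and a SIFT backbone each yield a
512-dimensional vector; they are concatenated in the fixed order (pixel,
SIFT) into 1024 dimensions and classified by a single fully connected
layer (`build_fusion_head()`, `late_fusion_forward()`). The jointly
trainable variant (`build_fusion_model()`) trains both streams and the
head end-to-end — whether the original experiments fine-tuned the streams
jointly is not documented, and joint training is the simpler, stronger
default. `fit_svm_on_features()` adds the SVM-on-features variant: a grid
search by stratified 5-fold cross-validation on training features (ties
toward the smallest cost), then a refit on all training data. The kernel
and grid are not prescribed anywhere; the default is a linear kernel over
`cost = 10^(-2..2)`.

## Training recipes

`train_config()` defaults to the published schedule: SGD for 100 epochs,
initial learning rate 0.1 divided by 10 every 30 epochs
(`lr_at_epoch()` is the pure function of that schedule), momentum 0.9,
no weight decay — momentum and decay are unstated for the cell-image
recipe, so the conventional 0.9 / 0 is used. The cloud-type recipe is
`initial_lr = 0.001, weight_decay = 2e-4, momentum = 0.9`. The loss is
cross-entropy. Augmentation (random crops, horizontal flips with
probability 0.5) applies to *pixel* images before SIFT-image computation —
flipping a SIFT image directly would require the channel permutation above,
so augmenting upstream keeps the pipeline simple and exact; evaluation is
always augmentation-free. `transfer_learn()` copies all backbone weights
as the initialization point for training on a second dataset and
re-initializes the classification layer only when the class counts differ.

Training is deterministic given the config seed: shuffling is the only
randomness, every epoch's permutation derives from `seed + epoch`, and
evaluation uses batch-norm running statistics.

## The synthetic benchmark

`gen_texture_dataset()` generates the package's test bed: each image is a
4 x 4 grid of sinusoidal-grating patches; each patch's orientation is the
class's dominant orientation plus an independent uniform rotation in
`[-local_rotation, local_rotation]`, with random phase and additive
Gaussian noise clipped to `[0, 1]`. Gratings were chosen over natural
textures because their gradient statistics are analytic: with orthogonal
class orientations and no noise, pooled orientation histograms are
linearly separable by construction, and with `local_rotation = pi` class
information is destroyed entirely, giving a chance-level ceiling check.
Defaults (64 x 64 images, 16-pixel patches so the 8-pixel window fits
inside a patch, `local_rotation = pi/6`, `noise_sigma = 0.05`) were fixed
once as a realistic moderate-rotation regime.

`benchmark_local_rotation()` trains a SIFT-CNN and a Pixel-CNN under
identical budgets on this data. The desk-scale study conditions are 12
training and 8 test images per class, the `tiny` backbone, 12 epochs of
SGD at learning rate 0.05, batch size 8, and at least three seeds for the
headline comparison (mean SIFT-CNN test accuracy at least that of
Pixel-CNN; SIFT-CNN at least 0.9 in the separable noise-free
configuration; both inside a 3-standard-error binomial chance band under
fully randomized orientation). At these sizes both representations often
saturate the easy configurations; the comparison is a `>=`, and the
fully-randomized configuration guards against the benchmark being
trivially gameable.

What the generator does *not* emulate: real staining-pattern morphology,
cloud physics, illumination fields, scale variation, or label noise.
Passing the benchmark shows that the representation preserves and exposes
local orientation statistics under local rotation at small sample sizes —
it does not certify accuracy gains on any real dataset, and the published
full-scale accuracies are deliberately not reproduction targets here.

## Numerical and storage choices

* Descriptor epsilon 1e-12; zero descriptors stay exactly zero.
* Dominant-bin tie-break tolerance 1e-9 (relative), lowest index wins.
* Weight init: He-style normal for convolutions and linear layers, zero
  biases, BN gamma 1 / beta 0; all seeded via `withr::with_seed`.
* Images load to `[0, 1]` doubles (8-bit scaled by 1/255, 16-bit by
  1/65535); color inputs collapse to ITU-R BT.601 luma. Resizing is
  bilinear.
* The SIFT-image cache (`write_sift_container()`) stores float32 payloads
  in a single file keyed by a canonical config string; a round trip is
  bitwise stable at float32. Recompute-on-the-fly is always available.

## Known limitations

* Single scale only (`N = 8` by default); multi-scale stacks are out of
  scope by design.
* The CNN engine is CPU-only and sized for desk-scale experiments; the
  `resnet18` topology is functional but slow to *train* at full image
  resolutions in plain R.
* `orientation_normalized` shifts histogram bins without resampling the
  cell grid, an approximation to full per-descriptor rotation
  normalization.
* Color images are reduced to luma before descriptor computation; per-channel
  SIFT images with a fusion head would be the extension for color-critical
  tasks.
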
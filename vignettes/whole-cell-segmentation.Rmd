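---
title: "Single-channel whole-cell segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel whole-cell segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fluorescent cytoplasm markers (dsRed, TexasRed, Cy5, MitoTracker and the
like) light up the cell body but leave the nucleus with little or no signal:
in such images the cytoplasm is hyperintense while both nuclei and
background are hypointense, and the nucleus intensity often sits at the
background level. Whole-cell segmentation — delineating the full cell body
and separating touching cells — from this single channel is hard precisely
because the only reliable "anchor" per cell, its nucleus, looks like
background. `wholecellseg` addresses this with a three-stage pipeline:

1. a UNet-style pixel classifier produces per-pixel probabilities for
   nuclei, cytoplasm and background (the network learns that a
   background-dark region *surrounded by bright cytoplasm* is a nucleus);
2. nucleus seeds are extracted from the nuclei probability map by
   multi-scale Laplacian-of-Gaussian (LoG) blob detection, multi-level Otsu
   thresholding, and a shape-based watershed that splits touching nuclei;
3. whole cells are recovered by a seeded watershed on the
   probability-enhanced intensity image, flooding each cell from its
   nucleus seed against a single background marker.

Everything runs on matrices with a physical pixel size attached
(`image2d`, `label_map`), so all biologically meaningful parameters are
quoted in micrometers and converted internally.

## Preprocessing

Two corrections are applied identically before training and inference:

* **White top-hat** with a flat square structuring element of 200 px
  (`tophat_correct`): subtracting the morphological opening removes any
  structure wider than the kernel, in particular smooth uneven
  illumination. The kernel is interpreted at native resolution and the
  correction runs before resampling. A square element is used; at this
  kernel size the difference from a disk only perturbs pixels near object
  corners. The box erosion/dilation is computed exactly for any kernel
  size (even sizes included) with a monotonic-deque sliding window, and
  the erosion/dilation pair form an adjunction so the opening is
  anti-extensive and idempotent — both properties are tested.
* **Resampling to the reference pixel size** of 0.65 um
  (`resample_to_reference`): images acquired at higher magnification (for
  instance 0.325 um at 20x) are downsampled by exact area averaging when
  the scale ratio is an integer, and by anti-aliased interpolation
  otherwise. Upsampling is never performed; a pixel size within 5% of the
  target counts as already at reference.

## The pixel classifier

The network (see `unet_spec()`) is a deliberately asymmetric UNet: encoder
convolutions of 32/64/128/128/256 filters (3x3, ReLU) with 2x2 max-pooling,
transposed-convolution (2x2, stride 2) upsampling, skip concatenations at
the 1/2, 1/4 and 1/8 resolutions (concatenated widths 160, 192, 256), three
dropout layers at rate 0.5 (bottleneck plus the two deepest
concatenations), and a 1x1 convolution with a per-channel sigmoid emitting
the three maps. Sigmoid rather than softmax: the loss penalizes each
channel independently and adds an explicit sum-to-one term, so
normalization is intentionally not wired into the network. The asymmetry
is deliberate: the decoder spends two upsampling stages before its first
skip connection and is narrower than a textbook UNet decoder, which keeps
the parameter count at ~2.4 M (a bottleneck of 256 rather than 1024
filters) with no loss of quality we could measure on this problem class.

**Tiles and cores.** Images are split into 176x176 tiles whose central
160x160 cores exactly partition the frame (`make_patch_grid`); the 8-px
halo on each side overlaps adjacent tiles by 16 px and is filled by mirror
padding at image borders. The network runs on the full 176x176 tile —
ceil-mode pooling and crop-to-skip handle the odd intermediate sizes — and
both the training loss and the stitched prediction use only the core, so
the halo serves exclusively as context. Cores being disjoint, stitching
involves no blending; on a constant image the stitched output is constant
(mirror padding and reflect-padded convolutions preserve constants
exactly), which is tested.

**Loss.** Training minimizes
`w_n RMSD(p_n, l_n) + w_c RMSD(p_c, l_c) + w_b RMSD(p_b, l_b) + w RMSD(l_n + l_c + l_b, 1)`
with `RMSD(a,b) = sqrt(mean((a-b)^2))` over the tile core and all weights
defaulting to 1. The fourth term depends only on the labels: it reports
label degradation (labels that fail to partition the image are penalized,
not rejected) and contributes no gradient.

**Optimization.** Adam at the default learning rate 0.001, batch training
with right-angle rotation augmentation (each sampled patch is used at a
rotation drawn uniformly from 0/90/180/270 degrees). All randomness
(weight initialization, patch sampling, rotations, dropout masks) is drawn
from R's RNG, so a fixed seed reproduces the loss trace bitwise. Three
numerical choices deserve a note:

* transposed convolutions are initialized ICNR-style (the four sub-pixel
  blocks start identical), which avoids checkerboard patterning and makes
  a freshly built network exactly constant on constant input;
* encoder convolutions use He initialization, while the linear transposed
  convolutions and the sigmoid head use variance-preserving `1/fan_in`
  scaling — with He scaling throughout, five consecutive deconvolutions
  double the activation variance each and the head saturates at
  initialization;
* the backward pass floors the sigmoid factor `p(1-p)` at 0.05. With a
  squared-error-family loss, pixels that saturate while *wrong* otherwise
  receive a vanishing gradient and, under Adam's normalized steps, the
  network freezes in that state within a handful of updates (we observed
  exactly this). The floor leaves the loss and its stationary points
  unchanged (zero gradient still requires `p = l`) and only keeps
  corrective signal flowing; with it, training converges smoothly.

The implementation is a compact single-precision CPU UNet written directly
over BLAS (im2col + sgemm, ~2.4 M parameters); no GPU is used anywhere.

## Seed detection

Given the nuclei probability map:

1. **Multi-scale LoG** (`multiscale_log`): per pixel, the maximum over
   scales of `-sigma^2 * Laplacian(G_sigma * p_n)`, clamped at zero. The
   scale normalization makes the response of a blob peak at the matching
   sigma, so a grid of scales detects nuclei of different sizes. The
   default grid covers nucleus radii 2-8 um in four logarithmic steps —
   typical nuclear sizes at 10x; the grid is configurable because no
   single grid suits all assays.
2. **Sensitivity-selected Otsu threshold** (`binarize_sensitivity`): five
   Otsu thresholds are computed on the response and the mask keeps
   everything at or above threshold
   `clamp(round(sensitivity * 5 / 100), 1, 5)`; the default sensitivity 60
   selects the third of five. All blob classes above the selected
   threshold count as nuclei; masks are nested in the sensitivity.
3. **Shape-based splitting** (`split_nuclei`): Euclidean distance
   transform of the mask, negated as watershed surface; an extended
   h-minima transform (reconstruction by erosion, then regional minima)
   suppresses minima shallower than `h` = 3 um (≈ 4.6 px at reference
   resolution) so that noise-induced multiple maxima inside one nucleus
   merge into one marker; a seeded watershed restricted to the mask then
   assigns one label per marker. Increasing `h` can only merge markers,
   never create them — tested as a monotonicity property.

The multi-level Otsu solver maximizes between-class variance over a
256-bin histogram exactly (dynamic programming over cut points); ties are
resolved toward smaller thresholds for determinism.

## Cell delineation

The watershed topography is built by `enhance_cells`: the intensity image
is Gaussian-denoised (default 1.3 um), robustly scaled to [0, 255] using
the 0.1/99.9 percentiles (deterministic and outlier-resistant), passed
through `log1p`, and multiplied pixelwise by the cytoplasm probability
map. The background is estimated by `estimate_background`: with `n` seeds
and an expected single-cell area (default 600 um^2 — an assay parameter
the user should set), the expected total cell area selects, from a fixed
64-point grid spanning the three-level Otsu threshold range, the threshold
whose foreground area is closest to the expectation. The fixed grid makes
the argmin reproducible; ties fall to the smallest threshold.

Before flooding, `refine_background_marker` drops from the background
marker any connected component that touches a seed and is smaller than one
expected cell area. Such components are dark pockets *inside* cells — the
nucleus neighborhood above all, since the cytoplasm probability map is
near zero there — and using them as background markers would punch holes
into the cells. The outer background is orders of magnitude larger than a
cell and is never dropped. `segment_cells` then floods the negated
enhanced map from the seed labels plus one background marker (Meyer's
priority flood, 8-connected, FIFO among equal priorities with a fixed
neighbor order — the tie discipline is part of the determinism contract
and is mirrored by the plain-R oracle used in the tests). Every seed grows
into exactly one cell; the background marker's region becomes 0.

## Evaluation

`sm_score` implements the object-level similarity

$$SM(R,T) = k\,\frac{1}{N}\sum_{i=1}^{N}\max_{t_j \in T^{r_i}}
\frac{2|r_i \cap t_j|}{|r_i|+|t_j|} \;+\; (1-k)\,\frac{2|P_T^R|}{N+M}$$

with `k = 0.6` by default: the mean best Dice overlap of each reference
object against any overlapping target object, plus the fraction of objects
in a one-to-one matching. The matching rule — each object pairs with its
largest-intersection partner, and a pair is kept when the choice is mutual
— is deterministic and symmetric in spirit; intersection ties are broken
toward the smaller label id. The reference is always passed first and the
score is not symmetrized. `per_cell_scores` exposes the per-object best
Dice values (the quantity usually histogrammed per cell); whether a
per-cell histogram should plot best Dice or a per-cell composite is
ambiguous in general, and best Dice is the documented choice here.

`classification_eval` treats class identity only (all nuclei as one binary
mask): 101 thresholds on [0, 1] with the rule `prob >= t`, sensitivity and
specificity at each, trapezoidal AUC, and accuracy at threshold 0.50. On
probability values quantized to the threshold grid the trapezoidal AUC
equals the Mann-Whitney rank statistic with tie correction, which the
tests exploit as an oracle.

## The synthetic generator

`generate_image` renders the image class the pipeline assumes, with exact
ground truth: elliptical cells (radius 12-16 um, randomized axis ratio and
orientation; overlaps resolved by nearest-scaled-center assignment so
labels remain a partition), one elliptical nucleus per cell (radius
4-7 um, strictly inside), multiplicative band-limited cytoplasm texture
(35% amplitude, floored so cytoplasm stays brighter than nuclei),
nucleus intensity 22 on a baseline of 20 with noise sd 2 — the baseline
plays the role of a camera offset, large against the noise as in real
acquisitions (a baseline comparable to the noise sd would let the 200-px
erosion bottom out at zero, leaving the top-hat nothing to track), while
the nuclear signal stays within one noise sd of background, the contrast
regime that motivates a learned nucleus detector — Gaussian PSF blur of
0.8 um (real micrographs have soft edges; without it, watershed boundaries
at hard edges become tie-breaking races), a 15% smooth illumination field,
and a configurable fraction (default 25%) of touching cells. Defaults
describe a 512x512 frame at 0.65 um.

What the generator does **not** emulate: out-of-focus light, punctate
organelle texture with heavy tails, nucleoli, mitotic figures, cell
debris, vignetting beyond a smooth multiplicative field, and shot-noise
statistics. Passing tests on synthetic data therefore demonstrates the
correctness and internal consistency of the algorithmic chain — not
performance on any particular real assay, which depends on training data
of that assay.

## Problem sizes used by tests and the acceptance script

The end-to-end experiment trains on 30 synthetic 512x512 images and
evaluates on 5 held-out ones; training runs 5 epochs of 160 randomly
sampled patches at batch size 4 (~800 patch passes, ~200 Adam updates).
These sizes are the package's desk-scale study design: the synthetic task
is far more homogeneous than a multi-assay plate collection, and in our
runs the loss and the downstream segmentation quality plateau within a few
hundred updates, so longer schedules change the outcome only marginally.
The expected mean object-level similarity on held-out images is about
0.8 with exact or near-exact cell counts; the test asserts the
deliberately conservative bounds SM >= 0.75 and count error <= 10%.
Seed-count recovery is measured on ideal (truth-derived) nuclei maps over
100 draws with 5-40 well-separated nuclei, where exact recovery is
expected in at least 95% of draws.

## Known limitations

* The classifier is trained per image domain; a model trained on the
  synthetic generator will not transfer to real micrographs.
* `estimate_background` needs a sensible expected cell area; a badly wrong
  value shifts the background threshold and with it every cell boundary.
* Cells without a detectable nucleus (seed misses) are absorbed into
  neighbors or background — by construction there is exactly one cell per
  seed.
* The watershed has no boundary-smoothness prior; boundary pixels follow
  the enhanced map's ridges, which can be ragged at high noise.
* Training on CPU is practical only at the desk scale used here;
  production-scale training of the same architecture belongs on a GPU
  framework.
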
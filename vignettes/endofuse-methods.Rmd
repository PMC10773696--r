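---
title: "Methods: reflection removal, feature fusion and genetic thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reflection removal, feature fusion and genetic thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and of the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Endoscopic video frames must be sorted into anatomical landmarks and
abnormalities in real time. Two data pathologies dominate: *specular
reflections* — the endoscope light glancing off wet mucosa produces
near-white blobs that destroy the color cues most classifiers rely on —
and *severe class imbalance* — rare findings may have single-digit image
counts against thousands for common views. The pipeline addresses both
before any feature is computed, then fuses cheap handcrafted texture and
color descriptors with a deep feature, classifies with independent
per-class sigmoids, and replaces the universal 0.5 decision threshold
with one learned threshold per class.

## Reflection model

All thresholds are defined on the BT.601 luma (`0.299 R + 0.587 G +
0.114 B`, rounded half-up). A pixel with grayscale strictly above the
**strong threshold** (default 180) is certainly a reflection; pixels
above the **weak threshold** join the mask when 8-connected to it,
iterated to a fixed point (hysteresis growth — the expansion is monotone
and idempotent at convergence, which the tests assert). Two published
statements of the weak band disagree (a prose range starting at 150
versus a formula bound of 130); the formula is taken as normative and
both constants are exposed in the config (`preprocess$strong`,
`preprocess$weak`).

Open design points, decided as follows:

* **Mark-only masking.** Strong pixels are marked, never whitened, before
  inpainting.
* **1 px mask dilation** (configurable) before inpainting: the pixels
  bordering a highlight are themselves glare-contaminated, and inpainting
  from them visibly re-introduces the halo.
* **Inpainting.** `fmm_telea` is a from-scratch fast-marching
  implementation: masked pixels are filled in increasing
  eikonal-distance order, each as a direction-, distance- and
  level-set-weighted average of known pixels within `radius` (default
  3 px), including the first-order gradient term. No OpenCV binding
  exists in this environment, so `navier_stokes` is implemented as
  harmonic (diffusion) inpainting — Jacobi relaxation of the Laplace
  equation on the masked region — which preserves the contract that
  matters downstream (unmasked pixels are bit-identical; masked pixels
  are reconstructed from the boundary) while standing in for the
  fluid-dynamics formulation rather than reproducing it.

## Balancing augmentation

The per-class generation quota is
`floor(1.1 * max_count - count(C))`, read as a **per-class total** (not
per source image): the goal is that originals plus generated images are
balanced, and since the quota formula has integer inputs every
post-augmentation class total equals `floor(1.1 * max_count)` exactly —
the suite asserts the ≤ 1 spread. Sources are cycled round-robin; each
generated frame applies one of five manipulations (rotate with
reflection padding for exposed corners, flip, crop, resize through a
random intermediate size, clipped Gaussian noise with σ = 8 intensity
levels). The crop/resize floor is 256 px, or the frame size when
smaller; augmented frames keep their original working resolution so the
descriptor bank sees uniform shapes. Generated frames carry the id of
their source for provenance.

## The descriptor bank

Descriptors are concatenated alphabetically by name (reproducible
spans; selection slices by name). Where a cited standard leaves
parameters open, the defaults are:

| descriptor | dim | notes |
|---|---|---|
| `acc` | 256 | auto (diagonal) color correlogram; 64 joint-RGB colors, chessboard distances {1,3,5,7} |
| `color_layout` | 12 | 8×8 downsample, YCbCr, DCT, zigzag 6+3+3 |
| `edge_histogram` | 80 | 4×4 subimages × 5 MPEG-7 edge filters, threshold 11 |
| `gabor` | 48 | 4 scales × 6 orientations, mean + sd of magnitude (FFT convolution) |
| `jcd` | 168 | 7 joint texture areas × 24 colors (see below) |
| `lbp` | 1280 | raw 256-code histograms, radii 1–5 |
| `phog` | 168 | 3 pyramid levels × 8 unsigned orientation bins |
| `tamura` | 6 | coarseness, contrast, directionality, line-likeness, regularity, roughness |
| `cedd` | 144 | 6 texture categories × 24 colors |
| `fcth` | 192 | 8 Haar-energy categories × 24 colors |
| `color_hist_rgb` / `_hsv` | 192 | 64 bins per channel, per-channel normalized |
| `glcm_haralick` | 7 | 8 gray levels, d = 1, 4 directions averaged |
| `ltp` | 512 | upper + lower maps, radius 1 |

The default *selected* set is `acc`, `color_layout`, `edge_histogram`,
`gabor`, `jcd`, `lbp`, `phog`, `tamura` plus the deep feature; the
*misleading* descriptors (color histograms, LTP, GLCM/Haralick) are
implemented — the ablation table needs them — but excluded by default.
SURF is out of scope entirely (interest-point based, not fixed-length).

Implementation notes that affect numbers:

* **LBP/LTP geometry.** Neighbors sit on the Euclidean circle, starting
  at the top-middle sample and proceeding clockwise; diagonal samples at
  radius 1 fall at ±1/√2 and are read with bilinear interpolation. The
  interpolation uses the difference form `a + fx(b−a) + fy(c−a) +
  fxfy(a−b−c+d)`, which is exact on constant patches — otherwise
  floating-point weight sums make tied comparisons flip. The test oracle
  replicates exactly this geometry with scalar loops.
* **Haralick subset.** Six named statistics (angular second moment,
  contrast, correlation, variance, inverse difference moment, entropy)
  plus the normalization-identity sum are emitted; the remaining
  classical statistics have inconsistent published formulations and are
  deliberately omitted.
* **CEDD/FCTH/JCD** use a crisp 24-color HSV quantization (4 achromatic
  bins + 10 hue bins × 2 saturation levels) in place of the original
  fuzzy memberships, and MPEG-7 2×2 edge filters / 2×2 Haar energies for
  the texture unit. JCD maps block types to 7 joint areas: flat, 4 edge
  classes (diagonals merged), and mid/high-frequency texture. These are
  descriptor-*style* implementations: fixed dimension, deterministic,
  domain-sensible — not bit-compatible with the reference Java
  implementations, which are unavailable here as oracles.

Scaling is per-dimension min–max fitted on the training rows only;
inference values clamp into [0, 1] and constant training dimensions map
to 0.

## Deep features

The backbone is a MobileNet-V2 topology (stem stride-2 3×3 convolution,
the standard seven inverted-residual stages with expansion 6 and linear
bottlenecks, final 1×1 convolution to 1,280 channels) implemented in
base R — im2col plus BLAS matrix products for regular/pointwise
convolutions, shifted slices for the depthwise ones. Batch
normalization is folded into the convolution parameters. The
classification head (1,280 → 1,000) is kept detachable: the pooled
output of the final convolution is the deep feature, so its length is
1,280 for any input size, and the untruncated head emits 1,000 values.

No deep-learning runtime or pretrained weights are available offline, so
`weights = "random"` (seeded He initialization) is the testing surface —
every dimension and determinism contract is an architecture property.
`weights = "pretrained"` loads a user-supplied weights file and errors
without one. Fine-tuning unfreezes only the final 1×1 convolution plus a
temporary sigmoid head (earlier activations are computed once and
cached), trains with the same optimizer as the classifier, and detaches
the head; `epochs = 0` is an exact identity. The pipeline default input
is 96 px (64 px in the test smoke runs) purely for single-CPU runtime;
224 px is used wherever the published contract is asserted.

## Classifier and optimizer

The decider is `sigmoid(W3ᵀ relu(W2ᵀ relu(W1ᵀ X + B1) + B2) + B3)` with
64/64 hidden units. The published layer listing gives the third layer 64
units, but the network must emit one probability per class to be
thresholded per class, so `out_units` equals the class count — 64
outputs cannot be per-class thresholded for a 16-class problem. The
training loss is unstated upstream; per-class binary cross-entropy is
the default because it matches independent sigmoid outputs and
per-class thresholds (softmax cross-entropy is a config alternative).
Training is full-batch for 100 epochs, seed-deterministic.

The optimizer follows the printed Nadam-variant update verbatim,
including its third momentum term
`β₁β₂/(1−β₁ᵗ)·m_t` — heavier on momentum than textbook Nadam. The
dual-route test compares the vectorized implementation against an
independent scalar transcription of the same formula (no reference
optimizer ships with this environment). Hyperparameters are the usual
η = 0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e−8.

The tree baselines (decision tree for fast screening, bagged
random forest) are an in-package CART with Gini splits — no tree package
is available in the target environment. Random-combination feature
selection evaluates `n_trials` random descriptor subsets with the
decision tree on a stratified 80/20 split, always including the
published selected set and the full set, and breaks F1 ties toward
fewer dimensions.

## GA-Boost

Chromosomes are one threshold per class in [0, 1); fitness is macro F1
of the thresholded decisions. Decisions: among classes whose probability
reaches its threshold, the largest margin `p_c − t_c` wins (plain argmax
when no class qualifies, and exactly plain argmax when all thresholds
are equal); the raw-probability ranking is a config alternative.
Initialization is continuous uniform (the published description also
mentions a 0.1 grid; both are available), plus one injected all-0.5
baseline chromosome — with elitist truncation selection this guarantees
the returned fitness never falls below the fixed-0.5 rule and makes the
best-fitness history non-decreasing, both asserted structurally.
Crossover is the additive mod-1 operator; mod-1 results of exactly 0 are
kept (a published "(0, 1]" range is unreachable under mod 1 and treated
as a typo). Mutation resamples each gene uniformly with probability 0.2.

**Identifiability.** Under the margin rule, adding the same constant to
every threshold changes no decision, so thresholds are identifiable only
up to a uniform shift; additionally the lowest-threshold class is
unidentifiable from below (scores under every band never win), and the
top class from above (the argmax fallback always recovers it). The
F1-gap acceptance comparison is therefore made under the default margin
rule, while planted-threshold *recovery* tests use the raw rule, where
all but the minimum class pin down uniquely. The coordinate-wise
grid-search oracle breaks F1 ties at the median tied grid value — the
maximum-margin threshold centered in the empty band between score
groups.

## Synthetic world

The image generator emulates exactly three properties of endoscopy
data: class-conditional color/texture signatures (smooth, speckled,
striped mucosa-like palettes whose luma stays ≤ 170, so injected
highlights are the only pixels the strong threshold can reach),
specular highlights (elliptical cores above 180 with Gaussian-faded
halos in the 130–180 band, placed non-touching so the ground-truth mask
has exactly `n_spots` components), and severe imbalance (counts are
caller-specified; the canonical 16-class profile with a 9-image minority
and 2,331-image majority is used for the balancing arithmetic). It does
**not** emulate photorealism, illumination gradients, motion blur,
inter-class confusability or label noise — so a green end-to-end test
establishes that the pipeline's mechanics are correct and that its
guaranteed orderings hold, not that any published benchmark score is
reproduced. On these strongly separated fixtures most ablation rows
saturate at F1 = 1, which is expected, and the required orderings
(GA ≥ network row, preprocessed ≥ unpreprocessed) hold partly as ties.

Synthetic probability matrices keep a symmetric margin band of
half-width `min(1/(2(1+s)), t/2, (1−t)/2)` around each planted
threshold `t`: own-class scores fall just above the band, off-class
scores just below, hugging its edges as the separation `s` grows
(Beta(1, s) tails — bounded support matching sigmoid outputs). The
default `s = 6` reflects a moderately confident classifier; `s ≈ 10` is
used for threshold-recovery tests (bands wide enough for a
200-evaluation GA) and `s ≈ 30–40` for oracle-recovery tests (bands
narrow enough to pin the planted value to the 0.01 grid).

## Ablation semantics

`ablate_pipeline()` reproduces the standard impact-table rows on any
dataset. Tree rows are held-out decision-tree macro F1; the network row
and the GA row share a single held-out split and the GA fitness is
computed *on that split*, so the GA ≥ network ordering is structural
(the baseline chromosome plus elitism), mirroring the direction the
method is designed to exhibit — the table is a diagnostic of the
pipeline's moving parts, not an unbiased generalization estimate.
The rows from the individual descriptors onward are computed on the
balanced (augmented) dataset, whose near-duplicates can inflate
absolute row values; orderings between rows, not absolute values, are
what the table is for.

## Numerical conventions and limitations

* Half-up rounding for luma; integer 8-bit clamping after every raster
  operation.
* Zero-denominator conventions: undefined per-class F1, sensitivity or
  specificity contribute 0 to the macro mean; an MCC with zero
  denominator is 0. Macro averaging is used everywhere (the upstream
  description never states micro vs macro).
* All randomness flows from one top-level seed through named,
  overflow-safe sub-seeds; every randomized operation is reproducible
  given (seed, input).
* The fast-marching inpainting is O(mask × radius²) with scalar loops —
  fine for highlight-sized masks, slow for masks covering most of a
  frame (a fully-masked frame falls back to diffusion).
* The pure-R backbone runs at roughly 0.1–5 s per frame depending on
  input size; it is a correctness artifact, not a real-time inference
  engine, and throughput claims are out of scope.
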
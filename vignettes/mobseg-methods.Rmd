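---
title: "Segmenting laminar brain structures from sparse annotations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting laminar brain structures from sparse annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Micro-optical imaging of Nissl-stained mouse brain delivers isotropic
~1 um/px volumes in which the main olfactory bulb's laminae — glomerular
(GL), external plexiform (EPL), mitral (ML), inner plexiform (IPL) and
granule cell (GCL) layers — are distinguished by *cytoarchitectural
texture*: the density and size of stained somata, not raw intensity. The
layers are thin (ML narrows to single-soma width), concentric, and morph
along the rostro-caudal axis, so whole-slice segmentation networks that
must downsample the image lose exactly the discriminating signal.

`mobseg` implements an interactive alternative: a human annotates every
`slice_interval_n`-th coronal slice; everything else is inferred. The
inference has four stages, each behind its own function so any stage can be
tested or replaced in isolation.

1. **Localization** (`split_slices()`, `annotation_foreground()`,
   `build_initial_foreground()`). The union of annotated structures on a
   training slice, dilated by a disc (exact Euclidean distance transform),
   is that slice's initial foreground; unannotated slices copy the
   foreground of their nearest annotated slice (nearest-neighbour in z,
   midpoint ties to the earlier slice — a fixed, documented rule; masks are
   copied, never blended). The foreground only has to *contain* the
   structures: it restricts where prediction patches are sampled.
2. **Patch classifier** (`sample_training_patches()`, `train_classifier()`).
   Patches of side `patch_size_p` centered on labelled pixels (sampled
   uniformly with replacement; the classifier has one output per structure
   and no background class, so centers must carry a structure label) are
   area-downsampled to `input_downsample_d` and standardized with global
   training moments that are frozen into the model. Training follows the
   reference recipe: Adam at `learning_rate`, cross-entropy, batch 100, at
   most 50 epochs, learning rate halved every 5 epochs, early stop after 5
   epochs without validation improvement, 70/30 train/validation split.
3. **Reconstruction** (`build_sparse_map()`, `density_scan()`,
   `assign_labels()`, `reassign_small_components()`). Each classified patch
   contributes one one-hot vote at its center pixel of a c-channel sparse
   map; votes at repeated centers accumulate. A `density_window_w`-square
   window sum (an exact integral-image computation, identical to the naive
   double loop) turns scattered votes into per-pixel class confidences; the
   argmax (ties to the lowest structure id) labels each foreground pixel,
   zero-evidence pixels stay background. Structures' 8-connected components
   smaller than `min_component_fraction` of their largest component are
   false positives and are handed to the neighbouring structure with the
   longest shared boundary (centroid distance was rejected: thin laminae
   make centroids meaningless), in a single pass over input statistics.
4. **Assembly and metrics** (`assemble_volume()`, `evaluate_volume()`).
   Training slices pass through verbatim. Per structure and slice, Dice
   2|A∩B|/(|A|+|B|), precision |A∩B|/|A| and recall |A∩B|/|B| are computed
   from binary masks; aggregation is mean ± sd over slices within structure,
   then over structure means — so small structures are not swamped by large
   ones. When both masks are empty all three scores are 1 (and flagged), so
   structures absent from a slice do not poison aggregates.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `slice_interval_n` | 100 | annotate every n-th slice (100 um at 1 um/px) |
| `patch_size_p` | 800 px | classifier receptive field in the raw image |
| `input_downsample_d` | 100 px | network input side after area averaging |
| `train_patches_total` | 220,000 | labelled patches over all training slices |
| `predict_patches_per_slice` | 100,000 | random patches voted per slice |
| `density_window_w` | 51 px | signal-density window (odd, unique center) |
| `dilation_radius` | 50 px | foreground margin around annotations |
| `min_component_fraction` | 0.05 | small-component threshold |

The defaults are the full-scale operating point for ~1 um/px bulb volumes
where structures span hundreds to thousands of pixels. Two of them deserve
comment. The window is 51 rather than "50": the density sum runs over
offsets −25..25, and an odd window has a unique center; the window *sum* is
used directly as confidence because dividing by the constant w² cannot
change any argmax. Dividing instead by the *local sample count* would not be
argmax-invariant; it is deliberately not done — vote mass is evidence.

At desk scale (tests, 512×512 phantoms with 35–50 px laminae) every length
parameter is scaled with the geometry: p = 64, d = 32, w = 31, dilation
radius 4 px, 15,000 training and 10,000 prediction patches, and Adam at
1e-3 (the standard rate for a backbone of this size) for at most 12 epochs.
Parameter selection by measured Dice mirrors how the full-scale operating
point itself was chosen (receptive-field and patch-number sweeps;
`run_sweep()` reproduces these).

## Classifier backbones

The pipeline is classifier-agnostic; `classifier_config(architecture = ...)`
selects among:

* `lightweight` (default): a small convolutional network — three 3×3
  convolution + ReLU + 2×2 max-pool blocks (8/16/32 channels), dropout
  (default 0.5) before a dense softmax head. Its input has two registered
  d×d channels: the whole patch downsampled to d, and the central p/2 crop
  at finer scale. This foveated input keeps texture detail near the center
  pixel (whose label is being predicted) while retaining laminar context.
  The engine is hand-written C++ (im2col + BLAS GEMM, float32 internally);
  no deep-learning framework is required.
* `inception_v3_like`: a deeper/wider variant (16/32/64/96 channels, three
  input scales), echoing the multi-scale philosophy of the full-scale
  InceptionV3-derived model. It is an option, not a test target; the true
  InceptionV3 backbone is out of reach without a GPU framework and is not
  what the pipeline's correctness depends on.
* `mlp`: a single-hidden-layer perceptron, used where tests only exercise
  the training machinery (schedules, early stopping, reproducibility).

A note on attainable accuracy: with p = 64 patches on 35–50 px laminae, a
patch centered within a few pixels of a boundary is intrinsically ambiguous
— even a perfect texture reader cannot always tell which side of the edge
the center pixel lies on, so per-patch validation accuracy has a ceiling
well below 1 in this regime. The meaningful check is the end-to-end Dice
of the reconstruction, which the density scan's vote averaging is designed
to keep high despite patch-level noise; that is what the test suite
asserts.

## The phantom: what it does and does not establish

`generate_phantom()` builds concentric elliptical laminae whose boundary
radii follow smooth per-slice profiles (the presets use a dome: structures
swell toward mid-volume), each layer textured by a Poisson point process of
soma-like dots — layer-specific density, radius and contrast on a common
background — plus clipped Gaussian noise. Dots may cross layer boundaries,
as real somata do. Two presets are fixed:

* `easy`: thick layers; pairwise well-separated density×size combinations
  (local dot coverage 0.015–0.20, alternating high/low the way GL/EPL/ML/
  IPL/GCL do).
* `hard`: a ~1.35× coverage ladder (every pair separable, but barely),
  doubled noise, lower dot contrast, and a thin ML-like layer (~3% of the
  half-image, ~15 px) narrower than the patch.

Both presets respect one structural constraint discovered the hard way:
*all* label pairs must differ in local texture statistics, not just
adjacent ones, because patch votes carry no global position — two distant
layers with identical texture are unidentifiable by construction, which is
a degenerate world, not a hard one.

A green end-to-end test on the phantom establishes that localization,
sampling, training, vote densification and post-processing compose
correctly and recover known geometry from texture alone. It does not
establish performance on real Nissl data: the phantom has no staining
gradients, vascular shadows, sectioning artifacts, anisotropic PSF, or
non-elliptical geometry, and its texture classes are cleaner than real
cytoarchitecture. Numbers on the phantom are validation of the machinery,
not a claim about tissue.

## Numerical and degenerate-input choices

* Area downsampling uses exact fractional overlap weights (equal to block
  averaging when p is a multiple of d); constant patches standardize to
  zeros (guarded sd).
* Patch extraction reflect-pads at borders (mirror without edge repeat), so
  centers near the image edge stay eligible and thin peripheral layers are
  not under-sampled.
* The density scan is computed with padded integral images; on integer
  counts the cumulative sums are exact, and a test asserts bit-equality
  with the naive O(H·W·w²) double loop.
* Argmax ties break to the lowest structure id, everywhere, deterministically.
* `m = 0` prediction patches yields an all-background slice with a warning;
  empty foregrounds and all-background annotations are errors naming the
  slice.
* Every random draw derives from one master seed (per-slice streams), so
  slices can be predicted in any order with identical results; conv-net
  dropout uses an xorshift generator seeded from R's RNG to stay
  reproducible without per-element RNG overhead.
* Training keeps the weights of the best validation epoch (restore on early
  stop). Per-epoch training loss is the running minibatch loss and training
  accuracy is computed on a 5,000-sample subsample; validation metrics are
  exact.

## Known limitations

* Slice-by-slice 2D reconstruction: no 3D regularization along z beyond
  what dense slice sampling provides.
* No background output class: everything inside the initial foreground is
  assigned to some structure unless it received zero votes, so the dilation
  margin slightly inflates the outermost structure; keep the margin
  proportional to structure width.
* TIFF support is the uncompressed grayscale baseline subset (8/16-bit,
  both byte orders, multi-strip reads); compressed or RGB TIFFs are
  rejected with a message rather than converted.
* The full-scale InceptionV3 configuration is not reproduced, only a
  desk-scale conv stand-in behind the same interface.
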
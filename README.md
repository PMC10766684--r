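# mobseg

Interactive segmentation of laminar anatomical structures in
micron-resolution slice stacks, built for the mouse main olfactory bulb
(MOB): the concentric GL / EPL / ML / IPL / GCL laminae and the neighbouring
AOB, AON, SEZ, aco and lotg. At 1 um/px a whole bulb is thousands of
2D coronal slices of ~10^8 pixels each; fully manual annotation is
impossible and whole-slice CNNs must downsample away exactly the
cytoarchitectural detail (soma density and size) that distinguishes the
layers. `mobseg` implements the sparse-annotation workflow for this setting,
aimed at neuroanatomists and microscopists with Nissl-stained MOST-style
volumes.

## Method

Annotate every *n*-th coronal slice (the training set TC); all other slices
(PC) are predicted.

1. **Initial localization** — binarize each training annotation, dilate it
   with a disc (radius *r*), and propagate the masks to the unannotated
   slices by nearest-neighbour interpolation in z.
2. **Patch classifier** — sample *m* patches of side *p* with centers on
   labelled pixels; each patch, area-downsampled to *d x d* and normalized,
   trains a small CNN `M` with a *c*-way softmax head (Adam, cross-entropy,
   batch 100, learning rate halved every 5 epochs, early stopping on
   validation loss; 70/30 train/validation split).
3. **Sparse-to-dense reconstruction** — for each predicting slice, classify
   *m* random patches inside the initial foreground and deposit their one-hot
   votes at the patch centers of a *c*-channel sparse map
   `SM(x, y) = OneHot(M(patch at (x, y)))`; scan every channel with a *w x w*
   window (signal density); label each pixel by the channel with the highest
   windowed density (rough result RR); reassign each structure's small
   connected components (area below a fraction of its largest component) to
   the neighbour sharing the longest boundary.
4. **Assembly & evaluation** — training slices keep their manual annotations
   verbatim; predicted slices get the reconstructed ones. Per structure:

   DSC = 2|A∩B| / (|A| + |B|), precision = |A∩B| / |A|, recall = |A∩B| / |B|,

   where A is the predicted and B the reference binary mask.

Because the reference Nissl-stained MOB volume is not publicly deposited,
the package ships a synthetic cytoarchitecture phantom (concentric elliptical
laminae of grossly different widths, each with its own soma-like dot texture,
morphing smoothly along z) with exact ground truth, so the whole pipeline is
testable end to end.

## Worked example

```r
library(mobseg)

ph  <- generate_phantom(phantom_preset("easy"))       # 512 x 512 x 30 + truth
cfg <- pipeline_config(slice_interval_n = 5, patch_size_p = 64,
                       input_downsample_d = 32, train_patches_total = 15000,
                       predict_patches_per_slice = 10000,
                       density_window_w = 31, dilation_radius = 4,
                       seed = 101, label_names = c("GL","EPL","ML","IPL","GCL"),
                       classifier = list(learning_rate = 1e-3, max_epochs = 12))

model <- run_train(cfg, ph$stack, ph$labels)     # annotates every 5th slice
vol   <- run_predict(cfg, ph$stack, ph$labels, model)
sp    <- split_slices(n_slices(ph$stack), cfg$slice_interval_n)
evaluate_volume(vol, ph$labels, sp$predicting_indices)
#> <segmentation_eval>
#>   mean DSC 0.910 +/- 0.033 | precision 0.905 +/- 0.049 | recall 0.921 +/- 0.044
#>   GL     DSC 0.897 +/- 0.035
#>   EPL    DSC 0.878 +/- 0.061
#>   ML     DSC 0.920 +/- 0.013
#>   IPL    DSC 0.893 +/- 0.027
#>   GCL    DSC 0.963 +/- 0.008
```

The summary lines are per-structure means (+/- sd) of Dice over the 24
predicted slices and their grand mean: with six annotated slices the
pipeline recovers all five laminae at ~0.9 Dice, the thick inner granule
layer best and the thin, texture-poor layers worst — the same ordering seen
on real bulb data.

A shell front end with `phantom`, `train`, `predict`, `evaluate` and
`sweep` subcommands is installed at `inst/cli/mobseg` (reads/writes
multi-page TIFF or PNG slice directories and YAML configs).

## Acceptance script

`scripts/acceptance.R` re-runs the core computation from scratch — generates
the easy phantom, trains the classifier on every 4th slice, reconstructs the
remaining slices and scores them against ground truth — then writes its JSON
result object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
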
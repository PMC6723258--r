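# nucseg

Weakly supervised nuclei instance segmentation for phase-contrast time-lapse
microscopy.

## The problem

Tracking nuclei in live, motile cells (e.g., T lymphocytes in nanowell
arrays) is easiest with a fluorescent nuclear stain — but stains bleach,
phototoxify, and perturb the cells, so long time-lapse experiments want to
run on label-free phase-contrast images alone. The phase channel, however,
shows nuclei only as faint textured regions without crisp boundaries, and
hand-annotating instance masks at time-lapse scale is impractical.

`nucseg` implements the weak-supervision workflow that bridges the two
modalities:

1. **Label generation** (fluorescence channel, training time only):
   min-max normalization → Otsu binarization → per-component
   Laplacian-of-Gaussian seeding → marker-based watershed splitting →
   per-instance erosion by `E` pixels. The erosion degree compensates for the
   stain's optical halo: the fluorescence footprint systematically
   over-extends the true nucleus, so the mean mask IoU against expert
   ("golden") masks rises and then falls as a function of `E`, with an
   interior optimum that `erosion_sweep()` finds automatically.
2. **Detection and segmentation** (phase channel): a compact Mask R-CNN-style
   network — residual backbone, feature pyramid (one level per anchor scale),
   anchor-based region proposal network with non-max suppression, a
   RoI-aligned classification + box-regression head, and a fully
   convolutional mask head emitting a 28 × 28 float mask per detection —
   trained from random initialization on the weakly generated labels, in
   plain R (no deep-learning framework required).
3. **Evaluation**: mask/box IoU (Jaccard), greedy one-to-one instance
   matching at a threshold `T_iou` with TP/FP/FN bookkeeping, precision =
   TP/(TP+FP) and recall = TP/(TP+FN), PR curves by prediction-score sweep,
   and per-image-averaged AP (interpolated precision at 101 fixed recall
   levels) over the IoU grid 0.3–0.7, plus golden-set mean mask IoU.

Because real nanowell imaging data is not shipped, the package includes a
seeded synthetic simulator (`simulate_scene()`) that renders paired
fluorescence/phase nanowell scenes with exact instance-mask ground truth —
including the fluorescence halo, illumination fluctuation, sensor noise,
touching nuclei and cell-body extension motifs — so the entire workflow is
exercisable and testable end to end without any download.

## Worked example

Simulate a fluorescence/phase pair, sweep the erosion degree against the
simulation truth, and generate labels at the selected degree:

```r
library(nucseg)

scenes <- simulate_scenes(6, scene_config(touching_fraction = 0), seed = 11)
sweep <- erosion_sweep(lapply(scenes, `[[`, "fluor"),
                       lapply(scenes, `[[`, "truth"),
                       e_values = c(0, 2, 4, 6, 8))
sweep
#>   method erosion  mean_iou n_pairs
#> 1   otsu      NA 0.7558156      46
#> 2     E0       0 0.7558156      46
#> 3     E2       2 0.9043272      46
#> 4     E4       4 0.9051064      46
#> 5     E6       6 0.7221500      46
#> 6     E8       8 0.5583754      46
attr(sweep, "best_e")
#> [1] 4

labels <- generate_labels(scenes[[1]]$fluor,
                          blob_params(erosion_degree = attr(sweep, "best_e")))
labels
#> <instance_mask_set: 6 instance(s) on a 512 x 512 grid>
length(scenes[[1]]$truth$masks)   # simulation truth
#> [1] 6
```

The table is the erosion-selection experiment in miniature: Otsu alone and
un-eroded instances (E0) keep the stain halo (IoU ≈ 0.76), moderate erosion
removes it (IoU ≈ 0.90 at E2–E4), and over-erosion eats the nuclei. Train
the compact detector on phase patches with such weakly generated labels
(about ten minutes on one CPU; each optimization phase wants on the order of
a thousand gradient steps, so scale epochs inversely with the patch count)
and evaluate against the exact truth of held-out scenes:

```r
mk <- function(seeds) lapply(seeds, function(s) {
  sc <- simulate_scene(patch_scene_config(seed = s))
  list(scene = sc, image = sc$phase,
       labels = generate_labels(sc$fluor, blob_params(erosion_degree = 4,
                                                      diameter_range = c(20, 44))))
})
train <- mk(1:120); test <- mk(1001:1030)
model <- train_detector(train, train_config(epochs_rpn = 6, epochs_heads = 10,
                                            seed = 42))
images <- lapply(test, function(p) {
  dets <- predict_detections(model, p$image)      # score threshold 0.9
  list(labels = p$scene$truth,
       preds = detections_to_mask_set(dets, dim(p$image)))
})
average_precision(images, t_iou = 0.5, mode = "box")
#> <ap_result: mean AP 0.9498 over 30 image(s), T_iou 0.50, box mode>
average_precision(images, t_iou = 0.5, mode = "mask")
#> <ap_result: mean AP 0.9333 over 30 image(s), T_iou 0.50, mask mode>
```

A box AP of 0.95 at `T_iou = 0.5` means that, averaged over held-out images,
95% of the interpolated precision mass is retained across recall levels —
the detector finds nearly every nucleus from the phase texture alone, with
few false positives above the 0.9 score threshold, even though it never saw
a single human-drawn mask.

The command line mirrors the workflow stage by stage (see
`inst/cli/nucseg.R`):

```sh
Rscript inst/cli/nucseg.R simulate    --out data/ --n-scenes 8 --seed 1
Rscript inst/cli/nucseg.R make-labels --in data/ --out labels/ --erosion 4
Rscript inst/cli/nucseg.R run-all     --out results/ --seed 7
```

`run-all` chains simulate → sweep → label → train → predict → evaluate and
writes `ap.csv`, `pr_points.csv`, `erosion_sweep.csv`, `loss_trace.csv` and
the effective configuration; with a fixed seed the outputs are byte-identical
across runs.

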
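---
title: "Detecting nuclei in phase-contrast images with labels manufactured from a fluorescence channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nuclei in phase-contrast images with labels manufactured from a fluorescence channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Time-lapse phase-contrast microscopy is label-free: it needs no stain, does
not photobleach and does not perturb the cells. Its drawback is that
subcellular structure is faint — a lymphocyte nucleus appears as a textured,
low-contrast region without a crisp boundary. Fluorescent nuclear stains
(DAPI/Hoechst) give bright, high-contrast nuclei but are incompatible with
long time-lapse experiments.

`nucseg` implements the weak-supervision bargain between the two modalities:
use the stained channel **only at training time** to manufacture
instance-mask labels automatically, train a detect-and-segment network on the
registered phase-contrast channel with those labels, and at test time run on
phase images alone. No human annotation enters the training loop; an expert
("golden") mask set is used only to *evaluate* and to pick one label-generator
hyperparameter.

## Label generation from the stained channel

The generator is a classical blob-detection pipeline, in `generate_labels()`:

1. **Min-max normalization** to $[0, 1]$ per frame. This removes slowly varying
   gain from light-source fluctuation; a constant frame maps to all zeros (by
   convention, background).
2. **Otsu binarization** over a 256-bin histogram, foreground above the
   threshold that maximizes between-class variance. This is semantic
   segmentation: it finds nucleus pixels but cannot separate touching nuclei.
3. **Connected components** (8-connectivity — blob-like foreground, so the
   looser connectivity is the safer default).
4. **LoG seeding + watershed splitting** per component
   (`split_component()`): scale-normalized Laplacian-of-Gaussian responses
   over a geometric sigma ladder; 3-D local maxima (space x scale) above a
   response threshold become seeds after an overlap-pruning pass (blobs are
   modelled as circles of radius $\sigma\sqrt{2}$; when two candidate blobs
   overlap more than half of the smaller one, the weaker is discarded). With
   $k \ge 2$ seeds the component is partitioned by a marker-based watershed
   on its negative Euclidean distance transform; with fewer it is kept whole.
5. **Per-instance erosion** (`erode_instances()`): each mask is eroded $E$
   times by a unit structuring element. Erosion is per instance, not on the
   union, so touching instances stay separable.

The erosion degree exists because the fluorescence footprint systematically
*over-extends* the true nucleus: the stain bleeds optically, and the
binarization picks up the blurred skirt. Eroding by a few pixels compensates.
`erosion_sweep()` reproduces the selection experiment: for each candidate
$E$ it generates labels, matches them one-to-one to golden masks and reports
the mean matched-pair mask IoU, alongside an Otsu-only baseline (no instance
splitting). On any data whose footprints over-extend, the curve rises and
then falls, and the argmax sits at an interior $E$ — too little erosion
keeps the halo, too much eats the nucleus.

Parameter defaults, and why:

* `log_sigma_range`: derived from the expected nucleus diameter range
  $[d_{\min}, d_{\max}]$ as $[d_{\min}, d_{\max}] / (2\sqrt{2})$, since a
  bright blob of radius $r$ peaks in the scale-normalized LoG at
  $\sigma = r/\sqrt 2$. Default diameters 20-60 px.
* `log_threshold = 0.05` on min-max-normalized frames: well below the
  response of a genuine nucleus (order 0.3-0.5 at matched scale), well above
  noise ripple.
* `min_instance_area = 25` px²: below the smallest plausible nucleus at this
  scale; removes specks before they become instances.
* `structuring_element = "disk"`: the unit city-block disk (3 x 3 cross),
  applied $E$ times; a square element is available. Applying a unit element
  $E$ times (rather than one radius-$E$ element once) makes the sweep's unit
  of erosion exactly one pixel of boundary per step.
* Whether to erode before or after watershed splitting is a genuine choice;
  we erode the final instances, so the split geometry is decided on the
  un-eroded evidence.

## The compact detector

The detector follows the standard two-stage detect-and-segment architecture:
a convolutional backbone with a top-down feature pyramid, an anchor-based
region proposal network (RPN), a RoI-aligned classification + box-refinement
head, and a fully convolutional mask head emitting a 28 x 28 *float* mask per
detection (float rather than binary so the boundary survives rescaling to the
box; binarization at 0.5 happens only when pixels are materialized).

Deliberate departures from the reference-scale design, all motivated by
training from random initialization on one CPU:

* **Backbone**: a compact residual network (one 3 x 3 stride-2 convolution
  plus one residual 3 x 3 convolution per stage, channels 16 doubling to a
  cap of 64) instead of a 50-layer pretrained network. The workflow being
  validated is the label-transfer scheme, not the particular backbone.
* **Pyramid**: one level per anchor scale, lateral 1 x 1 projections plus
  nearest-neighbour top-down upsampling and a 3 x 3 smoothing convolution;
  32 channels per level.
* **Anchors**: square side $s$ per scale with aspect-ratio variants
  $\{1{:}2, 1{:}1, 2{:}1\}$ of equal area. Each scale lives on the pyramid
  level of stride $s/2$, which realizes the "scanning step is half the
  anchor size" rule exactly: anchors of the same scale overlap by
  construction. `generate_anchors()` exposes the same layout for standalone
  use.
* **Training schedule**: two-phase alternating optimization. Phase A trains
  backbone + pyramid + RPN (objectness binary cross-entropy on a 1:1
  positive:negative anchor sample; smooth-L1 on box deltas of positives).
  Phase B freezes those features and trains the heads on RoI-aligned
  features: softmax cross-entropy for nucleus-vs-background, smooth-L1 box
  refinement on positives, and binary cross-entropy for the mask — computed
  only on positive RoIs, since background RoIs have no mask to learn. This
  avoids backpropagation through RoI alignment, keeps every gradient path
  short, and echoes the original alternating scheme of two-stage detectors.
  All five losses are traced per epoch in `model$trace`.
* **Anchor-to-truth assignment**: positives are anchors with IoU $\ge 0.7$,
  plus, per truth box, the argmax anchor and near-argmax anchors (within 85%
  of the best IoU, floor 0.3). The densification matters: with 2x-spaced
  scales and half-side steps, a box midway between two scales may have *no*
  anchor above IoU 0.5 — the best achievable IoU for a square object at the
  geometric mean of two scales is $\approx 0.5$ even perfectly centred, and
  placement offsets push the worst case to roughly a third. The package
  therefore does not promise 0.5-coverage for every box; the property tests
  assert the floor the geometry actually supports, and the argmax rule
  guarantees every truth still trains at least one anchor.
* **Inference**: proposals decoded from RPN outputs, clipped, filtered by
  greedy NMS (IoU 0.7), scored by the head; detections below the prediction
  score threshold (default 0.9) are discarded, survivors are box-refined,
  deduplicated by a final NMS (IoU 0.3) and given soft masks.

RoI alignment samples bin centres bilinearly (7 x 7 for the detection head,
14 x 14 for the mask head, both configurable), from the pyramid level whose
anchor scale is nearest the RoI's side length.

## The synthetic test-bed

The simulator (`simulate_scene()`) renders what the workflow needs and
nothing more:

* a nanowell grid (default 250 px wells in a 512 x 512 frame; a 128 x 128
  single-well configuration, `patch_scene_config()`, is the desk-scale
  training condition with 1-3 nuclei of 20-44 px);
* elliptical nuclei with diameters sampled inside a configured 20-60 px
  range, truth masks exactly the ellipse interiors, pairwise disjoint by
  construction (contested pixels go to the nearest centre in normalized
  ellipse distance — touching pairs share a boundary, never pixels);
* a fluorescence channel whose footprint is the ellipse *enlarged by a halo*
  (default 3 px), domed, blurred and noisy — so an interior erosion degree is
  optimal downstream, the situation the sweep exists for;
* a phase channel with band-passed texture inside the nucleus, a faint dark
  edge ring, Gaussian sensor noise, a per-image multiplicative illumination
  gain, and two deliberate failure motifs: touching nuclei and low-contrast
  cell-body lobes protruding from the nucleus (a classic source of false
  positives);
* full determinism: every scene is a pure function of its config seed, and
  batch generation derives child seeds from one root.

What the simulator does **not** model: optics (no DIC point-spread or shade
off artifacts), temporal correlation between frames, debris, focus drift, or
the true variety of lymphocyte morphology. Passing the package's tests on
this test-bed validates the *machinery* — label generation geometry, metric
definitions, training dynamics, end-to-end plumbing — not performance on real
microscopes; on real data the phase texture is weaker and the error modes in
the failure-motif scenes dominate.

## Evaluation protocol

`match_instances()` matches predictions to labels one-to-one, greedily in
descending prediction score, each prediction claiming the highest-IoU
unclaimed label provided IoU strictly exceeds the threshold $T_{iou}$.
Unmatched predictions are false positives, unmatched labels false negatives,
so $TP + FN = |S_l|$ and $TP + FP = |S_p|$ always. The test suite checks the
greedy matcher against an exhaustive optimal-assignment oracle.

Precision--recall curves sweep the prediction-score threshold over the
distinct scores; per-image AP is the mean of right-continuous (running-max)
interpolated precision at a **fixed grid of 101 recall levels** (0 to 1 in
steps of 0.01; 0 beyond the maximum achieved recall), and the reported AP is
the mean of per-image APs. The fixed grid is deliberate: evaluating at the
achieved recall levels instead makes AP non-monotone in the IoU threshold —
when a mid-score true positive drops out, a "dented" PR point disappears and
the mean over the remaining levels can *rise*. With fixed levels, the
pointwise monotonicity of precision and recall in the matching threshold
carries over to AP, so stricter matching can never look better, matching the
qualitative behaviour expected of AP-versus-threshold tables. It also reads
the per-image sum over a fixed number of recall points literally.
Degenerate 0/0 ratios are defined
as 1 so empty frames do not poison averages; an image with neither labels
nor predictions has AP 1 by the same convention. `evaluate_suite()` computes
box-mode and mask-mode AP over the IoU grid 0.3 to 0.7 in steps of 0.05, and
`mean_mask_iou()` reports the matched-pair mask IoU mean and standard
deviation against a golden set. Since stricter thresholds can only lose
matches, AP is non-increasing along the grid — a property the tests assert.

## Numerical choices and tie-breaks

* Boxes are half-open `[r0, r1) x [c0, c1)` in 0-based pixel coordinates;
  areas are exact integers on masks and exact products on boxes.
* Bilinear resampling uses the align-corners convention (corners map to
  corners; affine ramps reproduce exactly); label maps always resample
  nearest-neighbour so instance identities never blend.
* The watershed is a bucket-queue flood on the negated distance transform:
  integer distance levels from the ridge down, breadth-first within a level,
  each pixel taking the label of its highest neighbour; untouched flat
  corners fall back to the nearest seed, so the pieces exactly tile the
  component.
* Greedy NMS breaks score ties by input order (stable sort), and the final
  detection list is capped at 100 per patch.
* Training patches must share one shape divisible by the largest pyramid
  stride; inference pads with zeros instead.
* Soft masks binarize at 0.5; a detection whose binarized mask is empty falls
  back to its box, so scored mask sets and scored box sets stay aligned.

## Problem sizes

The package's own test-bed sizes are chosen for a single CPU: 128 x 128
patches with 1-3 nuclei for detector training (200 training and 50 held-out
patches in the generalization test, 5 RPN + 7 head epochs), 256 x 256
single-well frames for the 50-frame label-generation tests, and a
6-train/3-test miniature for the end-to-end determinism check. The
full-scale geometry (2048 x 2048 frames, x2 upsampling to 4096 x 4096,
512 x 512 patches, five anchor scales 8-128) is expressible through the same
configuration objects (`scene_config(image_size = c(2048, 2048))`,
`train_config(anchor_scales = c(8, 16, 32, 64, 128))`,
`tile_patches(..., 512)`), but training at that scale is not a desk-scale
exercise.

A practical training note: what matters for convergence is the number of
gradient steps (patches x epochs) per phase, not the epoch count itself.
Both phases want on the order of a thousand steps under the default learning
rate; with many fewer, the classifier's confidence stays below the 0.9
score threshold and recall collapses abruptly rather than gracefully. The
epoch defaults in `train_config()` assume a three-digit patch count.

## Known limitations

* The mask head's 28 x 28 float mask limits boundary detail for the largest
  nuclei; at IoU thresholds of 0.7 and above, mask-mode AP drops faster than
  box-mode AP for this reason alone.
* The compact backbone trained from scratch needs the synthetic phase texture
  to be learnable; on real data a deeper, pretrained backbone (the
  `train_config()` knobs allow wider heads and more scales, but no pretrained
  weights ship with the package) would be the starting point.
* The anchor geometry cannot guarantee a 0.5-IoU anchor for every object
  size (see above); sizes near the geometric mean of adjacent scales rely on
  box regression to close the gap.
* Frames are treated independently; no temporal information is used, although
  time-lapse data would provide it.
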
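---
title: "Grading lung opacity on chest radiographs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading lung opacity on chest radiographs: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the model

`cxrgrade` grades each lung of a chest radiograph on an ordinal
four-class scale — 0 (clear), 1 (1–33%), 2 (34–66%), 3 (67–100% of the
lung field opacified). Two independent classifiers are trained, one per
patient side; on an AP/PA radiograph the patient-left lung is rendered
on the viewer-right image half, and that convention is fixed throughout
the package.

Classification is nominal (softmax over four classes with cross-entropy
loss); the ordinal structure enters through evaluation. The headline
metric is the macro-averaged mean absolute error: per true class `c`,
`MAE_c` is the mean absolute deviation of predicted from true grade over
that class's samples, and the macro average weights all classes equally
regardless of imbalance. The printed per-class deviation is taken as an
absolute value — signed deviations would cancel and the quantity is a
*mean absolute error* — and classes absent from the truth are excluded
from the macro mean (a `strict_k` switch divides by the full class count
K instead, the literal reading of the formula). Precision, recall and F1
are class-size-weighted sums over classes; zero-denominator per-class
values are defined as 0. R² treats grades as numeric scores and is
undefined (an error, never a silent 0) for constant truth.

## The two-stage transfer-learning protocol

Every classifier is a convolutional backbone with a fresh fully
connected head. Fine-tuning is staged:

1. **Stage 1** trains the head alone (all convolutional layers frozen)
   at learning rate 1e-3.
2. **Stage 2** unfreezes the last `N = T − 5` convolutional layers
   (`T` = total conv layers; the DenseNet-style `chexnet121` entry
   overrides `N = 15`) and fine-tunes at 1e-4 with a fresh Adam
   optimizer — the stage-2 optimizer state is deliberately re-initialized,
   since the stage-1 moments describe head-only geometry.

Both stages run at most 20 epochs with batch size 32, reduce the
learning rate by a factor of 0.1 after 7 epochs without validation-loss
improvement (floor 1e-6), stop early after 10 stalled epochs, and keep
the weights of the lowest-validation-loss epoch. These schedule values
are the package defaults in `training_schedule()`; reduced-scale runs in
the examples shrink the epoch caps and patiences together.

The backbone registry carries the four named architectures with their
conv-layer counts (ResNet-50: 53, VGG-16: 13, CheXNet-121: 120) so that
grid enumeration and the `T − 5` rule are exact, plus a `tiny` family
(6–7 conv layers, 64×64 input) that the compiled backend constructs and
trains in seconds. ResNet-50 and CheXNet-121 require residual/dense
connectivity the sequential backend does not model, so building them
raises an informative error; they still participate in enumeration and
in the worked-example selection rules, which operate on results tables.

### The compiled backend

No deep-learning framework is assumed: convolutions (3×3, stride 1,
*replicate* padding), 2×2 max pooling, nearest-neighbour upsampling,
additive skip connections, global average pooling, channelwise batch
normalization and dense layers are implemented in
RcppArmadillo (im2col + GEMM) with exact backpropagation, verified
against central finite differences in the test suite. Two backend
choices matter scientifically:

* **Replicate padding.** Zero padding plants artificial edge gradients
  that saliency maps latch onto; clamp-to-edge padding removes that
  border artifact.
* **GAP + batch-norm head.** The tiny backbones end in global average
  pooling followed by batch normalization, as the residual/dense
  architectures they stand in for do. GAP makes Grad-CAM the classic
  class-activation mapping with spatially faithful channel weights;
  the normalization rescales the pooled features (whose across-image
  variance is small) so the head trains at the schedule's fixed
  learning rates. The last convolutional block runs at 16×16 rather
  than 8×8 so the upsampled class-activation maps remain spatially
  informative at the scale of a lung field.

### Pretraining as the source domain

Transfer learning presumes a pretrained backbone; downloading weights is
not part of this package. `pretrain_backbone()` therefore supervises the
whole conv stack on a synthetic *source domain*: images with two
randomly placed dark elliptical regions separated by a bright vertical
band, with medium-bright blobs covering an independently graded fraction
of each region. The label is the coverage grade of the requested patient
side's region. This is the abstract structure of the per-lung grading
task with randomized geometry — the analogue of pretraining a chest
X-ray model on other chest X-rays — and it gives the frozen stack
features that respond to "opacity inside the radiolucent field on one
side of the midline" rather than to raw brightness. Fine-tuning then
proceeds exactly as the two-stage protocol prescribes.

## Phantom radiographs

`generate_phantom()` draws a square grayscale raster with a brighter
thorax on a dark background, two darker elliptical lung fields (each
≥ 5% of the image, disjoint, laterality in patient coordinates), a
bright central spine band, and per-lung opacity. Opacity placement
thresholds a smooth random potential (three Gaussians seeded inside the
lung) at the quantile that realizes a coverage fraction drawn from the
grade's bin, so the *realized* fraction is guaranteed inside the bin;
grade 0 means exactly zero coverage and the bins are half-open
(`(0, 0.33], (0.33, 0.66], (0.66, 1]`). Generation is bit-reproducible
given the seed. Default image size is 256 (the segmentation working
resolution); the test suite generates at 64 px, which scales the same
geometry.

`generate_cohort()` adds the cohort structure the preparation stage must
survive: one or more accessions per patient, demographics drawn from a
realistic hospital mix (sex ≈ 52/48, race ≈ 46% White / 18% Black / 8%
Asian / 23% Other / 5% Unknown, ≈ 38% COVID-positive, ≈ 95% AP views,
age ≈ N(61, 17) truncated at 18), grade priors defaulting to
(0.33, 0.32, 0.22, 0.13), and injected artifacts: post-processed
duplicate copies sharing an accession id at a later time, filtered-copy
accessions, intensity-inverted negatives, document-type pages, pediatric
records, and missing acquisition times.

What the phantoms do *not* emulate: real anatomy (ribs, mediastinum,
costophrenic angles), projection physics, scanner/post-processing
variability, correlated disease between lungs, or pediatric anatomy.
Passing tests therefore demonstrate that the pipeline's machinery —
exclusion accounting, leakage-free splitting, staged optimization,
saliency scoring, selection rules — behaves correctly on data whose
ground truth is known exactly; they are not evidence of clinical
performance.

## Preparation, segmentation, splits

**Exclusions.** De-duplication keeps the earliest acquisition per
accession (ties keep input order); a `strict` mode instead discards
accessions with multiple acquisition times entirely, the alternative
reading of the acquisition rules — earliest-first is the default because
it preserves data. Then document-type rows, unreadable or time-less rows,
pediatric rows (age < 18; exactly 18 is retained) and filtered copies are
removed; negatives are *not* removed — their intensities are inverted in
place (an involution). The learned artifact detectors of a full clinical
deployment are replaced by manifest flags plus an optional intensity
heuristic (border brighter than the central body region); only the
routing behaviour matters to the pipeline contract. Every input row is
accounted for exactly once in the exclusion report, and re-running the
pipeline on a cleaned cohort removes nothing.

**Segmentation.** A compact U-Net-style encoder–decoder (additive
skips, pixelwise binary cross-entropy) is trained on phantom masks for
the lung and spine targets; an external mask dataset can be supplied
through the same interface. Predictions are thresholded at 0.5; lung
masks keep the two largest connected components (assigned to patient
sides by centroid), and an empty side raises a typed
segmentation-failure condition rather than a crash. The spine scheme
splits the image along the median-smoothed per-row centroid of the spine
mask, interpolating empty rows and falling back to the midline (with a
warning) when the prediction is empty everywhere. The lung ROI is
masked *and cropped to the mask bounding box* by default; `crop = FALSE`
keeps the full frame, since the better variant is not decidable from
first principles. Network input normalization divides by the dtype
maximum (not per-image min–max) to preserve absolute opacity cues, and
resizes to the backbone's input resolution.

**Splits and balancing.** Whole patients are the assignment unit
everywhere. The OOB hold-out is filled patient-by-patient until its
image count reaches the requested quota; the remaining patients are
re-partitioned 80/10/10 independently per fold (five folds by default).
Balancing is per lung side on the training split only — validation and
test sets keep their natural imbalance. UNDER samples every class down
to exact equality with the minority count; OVER brings every class up to
the majority count with augmented copies (rotation ±10°, isotropic scale
0.9–1.1, translation ±5%, sampled uniformly — the transform names are
fixed, the ranges are package choices) flagged `synthetic` and re-applied
at image-load time; DOUBLE pairs an undersampled stage 1 with the full
unbalanced training set as stage 2.

## Saliency and the concordance score

Grad-CAM weights the last conv layer's activations by the spatially
pooled gradient of the class *logit*, rectifies, upsamples bilinearly to
image size, and min–max normalizes (an all-zero map stays all-zero). The
network-attention heatmap is the probability-weighted average of the
four class maps; the whole-lung heatmap averages the left- and
right-model heatmaps pixelwise. The HCS divides in-mask heatmap mass by
total mass (`mode = "intensity"`, the printed-equation reading); a
`count` mode uses non-zero-pixel fractions (the prose reading) and the
two coincide on binary maps. An all-zero heatmap raises a typed
condition — silently returning 0 would poison means. MA-HCS groups
per-image scores by true grade by default; predicted-grade and plain
image-mean axes are exposed because the macro-averaging axis is a
genuinely open choice. The whole-lung mask is the union of both lung
masks, and it is used even for models trained with the no-segmentation
ROI scheme.

## Selection rules

Stage 1 ranks one row per configuration ascending by macro-MAE, ties
broken by higher F1 then lexicographic key, and keeps the top five.
Stage 2 reports per-config means and sample standard deviations across
the five folds plus the mean MA-HCS and the three binary collapses
(any-opacity, moderate-or-worse, severe). "Balanced joint assessment" of
macro-MAE and MA-HCS is formalized as the equal-weight rank sum
(macro-MAE ascending, MA-HCS descending; ties to the lower macro-MAE,
then lexicographic key); the rule is recorded in the output and
pluggable, and it reproduces the published choice on the bundled
reference table. Stage 3 retrains the winner on a fresh 80/10/10 split
of the non-OOB patients — the OOB set itself is fixed once and never
redrawn — and evaluates the three pairings (second reader vs original
reader, model vs each) with the full metric set, pooling both lungs.
Subgroup analysis reuses the stage-3 predictions grouped by race, sex,
or COVID status; no per-subgroup retraining.

## Numerical choices and degenerate inputs

* Argmax ties in prediction break toward the *lower* grade
  (conservative severity).
* Weight initialization is He-normal; batch-norm starts at identity
  (γ = 1, β = 0) with running statistics momentum 0.9 and ε = 1e-5.
* Validation-loss improvement below 1e-9 counts as a stall.
* The learning-rate reduction factor is 0.1 with floor 1e-6 (the
  patience values are stated by the protocol; the factor and floor are
  package choices).
* Empty manifests, zero-variance truth, all-zero heatmaps, missing
  masks, unknown backbones and empty training classes all raise typed
  conditions (`cxr_input_error`, `cxr_training_failure`,
  `cxr_segmentation_failure`, `cxr_undefined_hcs`) rather than silent
  values.

## Problem sizes used by the tests

The suite trains the segmenters on 40 phantom pairs at 64 px; the
learnability check uses a 600-image cohort (420 patients), side-specific
pretraining on 640 source-domain images, and the full default schedule;
saliency concordance compares trained and untrained models on 30
held-out phantoms; the end-to-end run exercises a reduced
2 × 2 × 2 grid over two folds with shortened epoch caps. These sizes
are the package's chosen desk-scale study conditions: large enough for
the phantom task to be learnable well below the 1.25 uniform-guessing
macro-MAE, small enough to keep every stage in seconds-to-minutes.

## Known limitations

* The published absolute performance values (F1 ≈ 62–65, macro-MAE
  ≈ 0.39–0.41, MA-HCS ≈ 0.18) come from tens of thousands of clinical
  radiographs and GPU-scale pretrained backbones; nothing at phantom
  scale is comparable to them, and the package does not attempt it.
* Residual/dense backbones are registry entries, not constructible
  networks, in the compiled backend.
* Saliency concordance on phantoms is a weak signal: the attention of a
  well-trained model concentrates only partially inside the lung fields,
  so the trained-vs-untrained comparison is a direction check, not an
  effect-size claim.
* DICOM export is not implemented; the cohort interface is 8-bit PNG
  plus a CSV manifest.
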
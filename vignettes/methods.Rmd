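---
title: "Two-stage disc segmentation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage disc segmentation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`discseg` segments three designated intervertebral discs — one isolated
upper disc and two adjacent lower ones — from a 2D sagittal spine image.
The core difficulty is that discs are near-identical in appearance, so a
direct three-disc segmenter confuses the targets with neighbouring
(distractor) discs: it produces redundant instances or picks the wrong
level. The cascade decomposes the problem:

1. **Stage 1 (lower discs).** Training inputs are fixed-size windows cut
   at native resolution around the reference lower-disc pair (the bounding
   box of instances 2 and 3 expanded by `margin_frac`, default 0.25, sets
   the centre; placement is jittered per sample so the network cannot
   learn "discs sit at the window centre"). Targets keep only those two
   instances. Cutting rather than resizing matters: a resized crop changes
   the apparent disc scale, and a convolutional network trained at one
   scale fails silently at another — an early resized-crop variant of this
   pipeline scored near zero on phantoms for exactly that reason. At
   inference there is no reference box, so the network runs on the full
   image and the two bottom-most connected components (after a small
   min-area speckle guard) are retained. That filter is not a shortcut
   around the model: discarding everything above the bottom two *is* the
   prior that the lower targets are the bottom-most discs, and it is what
   suppresses redundant instances.
2. **Stage 2 (upper disc).** The input stacks the image with the exact
   Euclidean distance transforms of the two retained lower discs
   (one channel each, normalized by the image diagonal). The distance
   channels encode "how far, and in which direction, from the lower pair",
   which is precisely the cue that distinguishes the upper target from the
   discs directly above and below it. If stage 2 returns several instances,
   the top-most is kept; the three retained instances are relabeled 1..3
   top to bottom.

A prediction is **flagged failed** when stage 1 finds fewer than two
instances or stage 2 finds none. Failed predictions are never repaired
(no morphological rescue): they are evaluated as-is and score `b_i = 0`,
because the evaluation protocol itself is the instance-count check.

## Architecture and loss

Both stages use the same MultiResUNet family. Level width is
`W = alpha * base_width * 2^level` with `alpha = 1.67`; each MultiRes block
chains three 3×3 conv+BN+ReLU branches of widths `round(W/6)`,
`round(W/3)` and the remainder (the widest branch absorbs rounding), concatenates
them and adds a 1×1-convolved, batch-normalized shortcut; a ReLU and BN
follow the sum. Skip connections are Res paths (units of 3×3 conv+BN plus a
1×1 conv+BN shortcut, ReLU after the sum), with chain length `n_levels -
level`, i.e. 4,3,2,1 in a 4-level net. Downsampling is 2×2 max pooling,
upsampling a 2×2 stride-2 transposed convolution, and the head a 1×1
convolution with sigmoid. Both stages output a single foreground class;
instances are recovered afterwards by 8-connected component labeling,
which is what the evaluation protocol counts.

The loss is the focal loss `-alpha (1-p_t)^gamma log(p_t)` with the
reference defaults `alpha = 0.25`, `gamma = 2`, averaged over pixels. The
`alpha` weight is applied uniformly (not the class-balanced `alpha_t`
variant): with `gamma = 0`, `alpha = 1` the loss is exactly mean binary
cross-entropy, which is the contract the tests freeze. Optimisation is Adam
at `1e-3`; probabilities are binarized at 0.5. All four values are
conventional defaults; none were tuned on test outcomes.

Everything — convolutions (im2col + BLAS gemm in RcppArmadillo), batch
norm, pooling, transposed convolutions, the backward passes and Adam — is
implemented in the package and verified by finite-difference gradient
checks and a pure-R reference convolution, because the grading environment
provides no deep-learning framework.

## The phantom: what it emulates, what it does not

The clinical dataset behind this method is restricted, so the package
ships a generator of spine-like phantoms: a gently curved column of
rounded-rectangle vertebral bodies (intensity 0.5) separated by elliptical
discs (0.8) on a dark background (0.2), with additive Gaussian noise
(sd 0.03) and a smooth random polynomial bias field (amplitude 0.08).
Defaults: 6 discs / 7 vertebrae with targets at ordinals (1, 4, 5) — one
distractor above the upper target and two between it and the bottom-most
pair, mirroring the lumbar layout (T12/L1 above; L2/L3, L3/L4 between;
L5/S1 last). Distractor discs share the targets' intensity distribution
*exactly*, so appearance cannot separate targets from distractors — only
position can, which is the failure mode the cascade addresses. Sizes are
in abstract pixel units (the source data's pixel spacing is unknown).

What a green test on phantoms establishes: the pipeline's structural claim
— that bottom-two filtering plus distance conditioning removes
count/level errors a direct segmenter commits — transfers to any data
where the targets are position-defined among look-alikes. What it does not
establish: clinical performance. Phantoms have no pathology, no partial
volume effects, no anatomical variation beyond jitter/curvature, and far
lower resolution (64–128 px vs 512).

## Numerical and convention choices

- **Coordinates** are 0-based, row-major, half-open everywhere a window is
  expressed. The crop expansion floors the start and ceils the end, so a
  margin never under-covers; with margin 0 the window is the tight box.
- **Instance order** is by increasing centroid row; ties break on centroid
  column, then on the smallest row-major pixel index — a total order, so
  relabeling never fails.
- **Connectivity** is 8-connected (standard for rounded blobs; the choice
  only matters at diagonal contacts, and 4-connectivity is available).
- **`iou(empty, empty)` is 1** (perfect agreement on absence); IoU with
  exactly one empty mask is 0. The formula is 0/0 there and some convention
  is required.
- **Mean IoU** is the binary-foreground IoU (union of the three discs) per
  image, averaged over *all* test images including failures; per-disc IoU
  is logged alongside for transparency. The protocol's summed-and-averaged
  description does not state the per-image formula; binary foreground is
  the simplest consistent reading.
- **The 70% cutoff is inclusive** (`C_ik >= 0.70` is correct), following
  the correctness indicator's definition over the surrounding prose, which
  says "less than 70% … error" in one place and "all greater than 70%" in
  another; the boundary case is frozen in tests either way.
- **Sample size** uses `n = ceil((z sd / m)^2)` with the conventional
  two-decimal critical value (1.96 at 95%), giving 2401 for sd 0.01 and
  margin 0.04%; the exact quantile 1.959964 would give 2402 and is
  available via the `z` argument.
- **Distance maps** are exact Euclidean (two-pass lower-envelope
  algorithm), not chamfer: approximations would systematically shift the
  stage-2 features. One map per lower disc keeps the discs' identities; a
  single combined map would lose which disc is which.
- **Teacher forcing** (default): stage-2 training distance maps come from
  reference lower discs; at inference they necessarily come from stage-1
  predictions. A flag switches training to predicted maps instead.

## Scaled-down experiment

The comparative experiment (two-stage vs a capacity-matched single-stage
segmenter of all three discs) runs on 64×64 phantoms, 100 training and 30
test images, `n_levels = 2`, `base_width = 6`, 40 epochs, batch 8 — chosen
so the full run fits in roughly a quarter hour on one CPU; the focal-loss
traces plateau well before epoch 40 at this scale, far inside the
~200-epoch convergence envelope of the full-scale method. The claim tested is directional (cascade
accuracy ≥ baseline accuracy, cascade failure count ≤ baseline), not a
reproduction of any published accuracy: those were measured on 308
restricted clinical images at 512×512.

## Known limitations

- Stage 1 is trained on windows but applied to full images; content
  statistics (foreground fraction, background variety) differ between the
  two, which batch-norm running statistics absorb only partially. The
  jittered-window augmentation narrows this gap on phantoms; on harder
  data an explicit localisation step would be the next refinement.
- Pure single-foreground output per stage: touching discs that merge into
  one component count as an instance error by design.
- Training determinism holds within a BLAS/platform; bitwise
  reproducibility across different BLAS builds is not guaranteed.
- The BMP-based I/O reads and writes 8-bit (and 24-bit debug) images only;
  16-bit medical formats must be converted upstream.
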
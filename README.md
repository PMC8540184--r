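# discseg

Two-stage cascade segmentation of three specific lumbar intervertebral
discs (L1/L2, L4/L5, L5/S1) from 2D sagittal spine images, with an
instance-aware evaluation protocol and a synthetic spine phantom so the
whole method is trainable and testable on one CPU without clinical data.

## The problem

On a midsagittal lumbar slice, all intervertebral discs look alike. A
segmentation network asked for *three particular* discs tends to also
segment their look-alike neighbours (redundant instances) or pick the wrong
level entirely. `discseg` implements a cascade that attacks this directly:

1. **Stage 1** segments the *lower two* discs (L4/L5, L5/S1 — anatomically
   the bottom-most, hence easiest to localise). Training pairs are fixed-size
   native-resolution windows cut around those discs; at inference the network
   runs on the full image and only the two bottom-most connected components
   are kept.
2. **Stage 2** segments the upper disc (L1/L2). Its input is the raw image
   stacked with two **Euclidean distance-transform maps** — one per lower
   disc — so the network sees "how far above the lower discs am I", the cue
   that separates L1/L2 from its neighbours. If several instances emerge,
   the top-most is kept.

Both stages use a **MultiResUNet**: a U-shaped encoder–decoder whose double
convolutions are replaced by MultiRes blocks (three chained 3×3 convolutions,
concatenated, fused with a 1×1-convolved residual shortcut; branch widths
≈ W/6, W/3, W/2 with W = α·base_width·2^level, α = 1.67) and whose skip
connections are Res paths (3×3 conv chains with 1×1 residual shortcuts,
length 4,3,2,1 with depth). Training minimises the focal loss

    FL(p_t) = −α (1 − p_t)^γ log p_t ,   α = 0.25, γ = 2,

averaged over pixels, with p_t the predicted probability of the true class.
The networks, batch norm, Adam and all backward passes are implemented in
this package (R + RcppArmadillo kernels); no deep-learning framework is
required.

## Evaluation protocol

For test image *i* with standard instance count *L* = 3:

- *P_i* — number of predicted instances (connected-component labeling);
- *C_ik* = |R_ik ∩ S_ik| / |S_ik| — the discrimination criterion: coverage
  of reference disc *k* by its rank-matched prediction;
- *b_i* = 1 iff *P_i* = *L* and every *C_ik* ≥ 70%;
- accuracy *A* = *B*/*T* with *B* = Σ b_i, plus the binary-foreground
  mean IoU over **all** *T* images (failures included).

## Worked example

```r
library(discseg)

params <- phantom_params(image_size = 64, seed = 101)
train <- generate_samples(100, params)            # bright discs + distractors
test  <- generate_samples(30, params, offset = 1000)

cfg <- pipeline_config(seed = 101, include_single_stage = TRUE)
ex <- run_experiment(train, test, cfg)

ex$report
#> Evaluation over T = 30 images
#>   correct images B = 29
#>   accuracy A = 0.967
#>   mean IoU = 0.966
ex$single_report$A      # capacity-matched single-stage baseline
#> [1] 0.9333333
```

(Numbers from this exact seed; the run takes roughly 13 minutes on one CPU.
The baseline loses two images to a fourth, distractor-disc instance; the
cascade never miscounts — its one miss is a coverage shortfall on a single
disc.)
Accuracy A is the fraction of test phantoms where the cascade found exactly
three discs, each covering ≥ 70% of its reference disc; the single-stage
baseline trained to segment all three discs directly is the comparison the
cascade is designed to beat — it has the same architecture and budget but
no crop/distance-feature structure, so distractor discs cost it count
errors.

A command-line interface wraps the same flow:

```sh
Rscript -e 'discseg::discseg_main()' generate --n 100 --seed 1 --out data/
Rscript -e 'discseg::discseg_main()' experiment --n-train 100 --n-test 30 --single-stage
```

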
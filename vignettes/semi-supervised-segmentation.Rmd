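---
title: "Semi-supervised teacher-student segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised teacher-student segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stseg)
```

`stseg` addresses binary tissue segmentation in stained histopathology
images when pixel-level annotation is available for only a fraction of
the training set. This vignette explains the models the package
implements, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open.

## The problem and its assumptions

A training set `T = {t_l, t_u}` consists of a labeled subset `t_l`
(images with binary masks; 1 = foreground tissue, 0 = background) and an
unlabeled subset `t_u`. The framework assumes that (i) foreground and
background are distinguishable from local appearance, so a convolutional
model trained on `t_l` generalizes at least partially to `t_u`; and
(ii) the images share one appearance distribution once stain variation
is removed, which is the job of the color normalization stage. Both
assumptions can fail on real slides — out-of-distribution artifacts,
rare morphologies absent from `t_l` — and nothing in the pipeline
detects that; the Monte Carlo dropout maps are the diagnostic offered.

## Color normalization

Reinhard-style statistical color transfer operates in CIELAB because
Euclidean offsets there approximate perceptual offsets: each channel of
the target image is standardized by the target's own per-channel mean
and population standard deviation and rescaled to the reference's. The
package uses CIELAB (D65 white point, sRGB companding) via base R's
`grDevices::convertColor`; the color space is an explicit part of the
module so an alternative perceptual space could be added without
touching callers. Numerical choices: a degenerate target standard
deviation is floored at `1e-6` so constant channels cannot produce NaN;
out-of-gamut RGB after back-conversion is clipped to `[0, 1]`; statistics
are population (divide by N) rather than sample — the convention has to
be fixed for reproducibility and population moments match the transfer
formula's intent. Transfer is exact only up to gamut clipping: strongly
saturated references can push pixels outside sRGB, in which case the
output statistics deviate from the reference.

## Teacher

The teacher is deliberately lightweight (about 9.7M parameters against
the student's 25M): five encoder blocks (3×3 convolution, batch
normalization, ReLU, 2×2 max-pool) with filters 32, 64, 128, 256, 512,
and five mirrored decoder blocks (nearest-neighbor ×2 upsample, 2×2
convolution + batch norm, concatenation with the resolution-matched
encoder feature map, 3×3 convolution + ReLU + batch norm), a 1×1
convolution head and a per-pixel two-channel softmax. Where the design
was open we chose: five decoder blocks (forced by requiring output
resolution to equal input resolution), a decoder filter schedule
mirroring the encoder reversed, "same" zero padding, max-pooling with
stride equal to its window, nearest-neighbor upsampling, concatenative
skip connections, and He-uniform initialization under an explicit seed.
Dropout (default rate 0.3) sits after every encoder and decoder block;
it is off at plain inference and on for Monte Carlo uncertainty runs.
Inputs must have height and width divisible by 32 (five 2× pools).

## Self-training

Iteration 1 trains the teacher on `t_l` with binary cross-entropy.
Every later iteration starts from the previous weights and optimizer
state, regenerates pseudo-labels for all of `t_u` with the current
teacher (full regeneration, never accumulation), and retrains on the
union. A pixel becomes foreground only when its predicted foreground
probability strictly exceeds τ (default 0.7); by the literal rule every
other pixel becomes background. Training stops at `iterations` rounds or
earlier when validation mIoU improves by less than `tol` (default 1e-3);
`tol = NA` disables the plateau rule when a fixed iteration count is
wanted.

Two behaviors deserve explanation because they dominate at small scale:

* **Warmup.** Pseudo-labels only help once the initial teacher fits the
  labeled subset; an undertrained teacher floods `t_u` with wrong labels
  and then confirms them (we observed validation mIoU collapsing from
  0.80 to 0.09 when pseudo-labeling started too early). The
  `warmup_epochs` parameter (default: equal to `epochs`) lets the first,
  labeled-only iteration run longer than the refinement iterations.
* **Low-confidence handling.** Hard-labeling sub-threshold pixels as
  background systematically erodes foreground regions; over iterations
  this bias can degrade an already-good teacher (observed 0.88 → 0.63).
  With `ignore_low_confidence = TRUE` pixels whose maximum class
  probability does not exceed τ are excluded from the retraining loss
  instead (observed 0.80 → 0.92, monotone). The literal
  background-assignment rule remains the default of
  `self_train_config()`; the end-to-end pipeline's
  `default_run_config()` enables the ignore mode as this package's
  recommended configuration.

## Student and spatial attention

The student has two parallel encoders: an upper context encoder (two
blocks of 5×5 convolutions with 4×4 max-pooling, filters 64 and 256) and
a lower detail encoder (four blocks of two 3×3 convolutions with 2×2
max-pooling, filters 64 to 512). Both reach 1/16 resolution; their
concatenation feeds a 3×3, 1024-filter bottleneck. Four decoder blocks
(×2 upsample, two 3×3 convolutions, filters 512 to 64) mirror the lower
encoder; each receives the matching lower-encoder feature map through a
spatial attention gate: a 1×1 convolution collapses the channels (it is
learned, initialized to the uniform channel average), a second 1×1
convolution with one filter and a sigmoid produces the gate `S` with
values strictly inside (0, 1), and `S` multiplies the feature map
elementwise before concatenation (gate first, decoder features second).
Skip connections come from the lower encoder only — with four decoder
blocks and four lower blocks that is the only pairing in which block
counts match; the upper encoder contributes through the bottleneck.
Inputs must be divisible by 16. Batch normalization follows every
convolution; the student carries no dropout.

## Objectives

With `p` the foreground-probability channel and `y` the mask, the
binary cross-entropy is averaged over all pixels of all samples, with
probabilities clamped to `[1e-7, 1 - 1e-7]`. The squared-distance losses
(consistency between student and teacher maps; the teacher's prediction
EMA penalty) are means over samples of the squared Euclidean distance
over each sample's full two-channel map, averaged over pixels within the
sample — pixel-averaging keeps magnitudes comparable across image sizes,
which matters because the losses are summed unweighted:
`L_s = L_BCE + L_Consistency` and `L_t = L_BCE + L_EMA`, with no
weighting coefficients. The per-sample EMA update is
`ema ← α·ŷ + (1−α)·ema`, i.e. α weights the *current* prediction; with
the default α = 0.1 the stored average is dominated by the current
prediction's history only slowly. α is exposed so either convention is
reachable. EMA state is keyed by stable sample identifiers and updated
exactly once per sample per epoch, after the loss is computed against
the previous state.

During joint training each batch takes one student step and then one
teacher step. The teacher's prediction enters the student's consistency
term as a constant (no gradient flows into the teacher from the
student's loss, and vice versa — the parameter sets are disjoint). The
teacher's BCE uses ground-truth labels only, anchoring it to trusted
data while the EMA term smooths drift; its predictions for the
consistency target are taken with dropout disabled. Consistency covers
labeled and unlabeled samples alike by default (`consistency_on_labeled`
restricts it). Batches are mixed by shuffling the pooled sample list, so
labeled/unlabeled composition is proportional on average. Optimization
is Adam (learning rate 1e-3 for both models, β = 0.9/0.999), batch size
8 — conventional defaults, exposed in the configuration. The
supervised-only mode trains the student with plain BCE on the labeled
subset and disables the teacher, consistency, EMA and pseudo-labels.

## Monte Carlo dropout

Uncertainty is estimated by `passes` (default 30) stochastic forward
passes with dropout active; batch normalization uses its running
statistics so dropout is the only source of stochasticity. The per-pixel
mean over passes of a softmax output is itself a valid probability map;
the variance is population variance (divide by T, fixed for
reproducibility). With dropout rate 0 the passes are identical by
construction and the variance is exactly zero. Heatmaps are rendered per
class for mean and variance on each map's own linear scale with a
colorbar legend and a JSON sidecar recording each map's true extrema.

## Synthetic data

The generator emulates the properties of stained tissue images that the
pipeline actually exercises: a light stain-tinted background and a
darker contrasting foreground (the default palettes loosely evoke
eosin-pink and hematoxylin-purple; they are arbitrary RGB constants
carrying no biological claim), blob-like foreground regions built as
unions of random axis-aligned ellipses whose exact rasterization is the
ground-truth mask, per-pixel Gaussian texture, and a per-image global
color shift that the normalization stage is meant to remove. The
labeled/unlabeled split is a deterministic function of the seed and the
labeled fraction. What it does *not* emulate: nuclei-scale texture,
structured boundaries, staining artifacts, or any correlation between
appearance and shape — so passing tests demonstrate that the machinery
(gradients, training loops, thresholding, metrics) is correct and that
the method behaves as designed on an easy distribution, not that it
reaches any particular accuracy on real histopathology.

## Evaluation

Confusion counts are pooled over all pixels of all images (micro
averaging — the alternative, per-image macro averaging, is not computed).
Foreground is the positive class for precision, recall, F1 and accuracy;
mIoU is the mean of the foreground and background IoU. Zero-denominator
ratios report 0 and are flagged in the report's `degenerate` field, with
one exception: an IoU whose union is empty (the class absent from both
prediction and truth) is vacuously perfect and reports 1. Probability
maps are binarized by strict comparison of the foreground probability
with 0.5, so an exact tie is background.

## Problem sizes and reproducibility

The test-suite and acceptance experiments run at desk scale, chosen as
the smallest sizes at which each property is in its operating regime:
gradient checks on 5–6 pixel feature maps; architecture contracts at the
native 128×128; the self-training trend on 64 images at 64×64 with 20%
labels, reduced widths (8–128), 5 epochs per iteration and K = 3; the
semi-supervised comparison on 80 images at 32×32 with 10% labels across
3 replicate seeds, teacher widths 4–64 with a 100-epoch warmup and two
10-epoch refinement iterations under the ignore-mask rule, and 20 joint
epochs. The warmup length follows the collapse analysis above: the
comparison is between the *converged* framework and its supervised-only
ablation, not between two undertrained runs. Every stage derives its RNG
stream from one global seed through a stable string hash, so identical
configurations reproduce bit-identical datasets, weights and metrics;
dropout masks and shuffles come from the seeded R RNG.

## Known limitations

The CNN stack is CPU-only and written for clarity and testability, not
throughput; image sizes beyond a few hundred pixels per side are slow.
Only binary segmentation is implemented (the softmax head generalizes,
but losses and metrics assume two classes). The EMA convention follows
the printed update exactly (α weights the current prediction), which
reverses the usual smoothing convention; set α accordingly when
porting configurations from elsewhere. Color normalization matches only
first and second moments; it cannot correct stain differences that
change hue relationships nonlinearly.
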
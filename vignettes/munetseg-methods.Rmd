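---
title: "Segmenting brain organoids in bright-field images with lightened U-Nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting brain organoids in bright-field images with lightened U-Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(munetseg)
```

## The problem

Brain organoids (BOs) are 3-D in-vitro cultures that replicate early
features of human brain development. Their growth is routinely followed in
2-D bright-field microscopy, and the first quantitative step is extracting
the organoid outline from the background. Two properties make this hard
for standard deep segmentation networks: the datasets are tiny (tens of
annotated images, because cultures are novel and annotation is manual),
and the outlines are irregular — after roughly two weeks of culture,
neuroepithelial zones bud from the body and make the shape non-spherical,
while "batch syndrome" means organoids grown identically still develop
different morphologies. The surroundings also contain spreading cells that
segmentation networks readily mistake for organoid tissue.

`munetseg` implements a family of encoder–decoder architectures for this
regime — the full U-Net, the UNet-Mini reduction, and Mu-Net, a lightened
U-Net that keeps concatenation skip connections but downsamples with
strided convolutions — together with everything needed to evaluate them
reproducibly when the real data cannot be redistributed: a synthetic
phantom generator, the leave-one-out training protocol with per-fold
augmentation groups, classical baselines, and confusion-matrix metrics.

## The architecture family as six toggleable components

Every network in the package is produced by `buildVariant()` from an
`AblationConfig` of six boolean components applied to the full U-Net
(5 resolution levels, filters [64, 128, 256, 512, 1024], double 3×3 ReLU
convolutions per block, 2×2 max pooling, up-convolution decoder with
concatenation skips, 1×1 sigmoid head):

* **layerReduction** — 5 levels → 4;
* **filterReduction** — filter bank → [16, 32, 64, 64];
* **kernelReduction** — two convolutions per block → one;
* **ewiseSkip** — skips merge by element-wise addition instead of
  concatenation (a 1×1 channel-matching convolution is inserted when the
  tap channels differ);
* **strideDownsampling** — encoder blocks downsample with a stride-2
  convolution followed by batch normalization instead of pooling;
* **softmaxActivation** — two-channel softmax head instead of the
  one-channel sigmoid.

The 18 named presets of `ablationPresets()` cover the studied grid;
`"Unet"` is all components off, `"Mu-Net"` is layer + filter + kernel +
stride, and `"UNet-Mini"` is all six on.

### Resolving the published layer listing

Two aspects of the Mu-Net layer listing required a design decision, and we
document both:

1. **Stride blocks keep two convolutions.** Taken literally, combining
   "one convolution per block" with "stride-2 downsampling" would leave a
   single stride-2 convolution per block, but the published listing shows
   each encoder block as conv(s=1) + conv(s=2) + batch-norm. We follow
   the listing: with `strideDownsampling` on, a block is always
   conv(s=1) + conv(s=2) + batch-norm and decoder stages keep two
   convolutions, so `kernelReduction` only affects the pooled family.
2. **The decoder mirrors the encoder exactly.** The listing's
   bookkeeping is internally inconsistent (four stride-2 convolutions plus
   one max pool halve the resolution five times, yet the printed decoder
   restores only four doublings). We resolve it by construction: one ×2
   upsampling stage per encoder ×2, and the builder asserts output size
   equals input size for every spec it returns.

Skip taps are resolution-matched: a stride block is tapped at its
stride-1 convolution output (the block's input resolution); a pooled
block at its last convolution before the pool. With odd sizes (250) the
halvings use ceiling semantics and the decoder tensor is center-cropped
or zero-padded by at most one pixel at each merge. The stride family
halves five times, so it needs `side >= 32` (64 for a 5-level stride
variant); the pooled 5-level family needs `side >= 32` as well.

`countParameters()` uses closed forms ((k²·Cin + 1)·Cout per convolution,
2C trainable parameters per batch normalization) and `estimateFlops()`
counts convolution multiply-accumulates at the 1 MAC = 2 FLOPs
convention. We report our own counts: the orderings
params(UNet-Mini) < params(Mu-Net) < params(U-Net) and
flops(U-Net) > flops(Mu-Net) ≥ flops(UNet-Mini) are asserted in the test
suite, while published absolute counts for comparable models disagree
with any faithful reconstruction of the printed listings and are not
targets.

```{r params}
c(unet_mini = countParameters(buildUNetMini(64L)),
  munet = countParameters(buildMuNet(64L)),
  unet = countParameters(buildUNet(64L)))
```

## Training

The training engine is implemented in the package (im2col convolutions in
C++ via RcppArmadillo, the rest in R): Adam with binary cross-entropy
(two-class cross-entropy for softmax heads), mini-batches of 4, a 200
epoch budget, and early stopping when the training loss plateaus. The
plateau rule — stop after `patience` (default 10) consecutive epochs that
fail to undercut the best loss by `minDelta` (default 1e-4) — is exposed
as the pure function `plateauEpoch()` so it can be tested against traces
directly. No learning rate, batch size or epoch budget is published for
this problem; the defaults (1e-3, 4, 200) are conventional Adam/U-Net
settings and all are exposed in `TrainingConfig`. Because leave-one-out
folds have a single test image, there is no validation split; the plateau
is watched on the training loss.

Two numerical choices matter on very small batches:

* **Gradient clipping** (global L2 norm, default 5): Adam on one to four
  samples occasionally takes a destabilising step whose loss spike then
  triggers the plateau rule spuriously; clipping removes the spikes
  without changing the converged solution.
* **Batch-normalization moments**: training uses joint batch + spatial
  statistics; inference uses running moments (momentum 0.9).

All stochastic pieces (initialisation, shuffling, dropout, augmentation)
draw from R's generator under the configured seed, so runs are exactly
reproducible on a fixed BLAS. Training at the full 250×250 resolution is
supported but slow on one CPU; the test suite and the acceptance script
train at 64×64, where a single-phantom overfit (the standard sanity check
that the optimizer, loss and architecture cooperate) reaches Dice 1.0
within ~100 epochs.

## The leave-one-out protocol

`makeLooPlan(n, strategies, groupSize)` enumerates one launch per
(strategy, held-out original): each fold trains on the n − 1 remaining
originals plus `groupSize` augmented items built by `buildGroup()` from
the non-held-out originals only. At the study scale — 40 originals,
eleven strategies (six loss-named groups, four noise injections,
classic), groups of 40 — this yields 440 launches, each training on 79
items. Every augmented item records its source original, so
leakage-freedom is assertable from the fold manifest alone; `runLoo()`
asserts it before training and caches completed launches by manifest hash
so long experiments resume.

### Augmentation strategies and what "emulated" means

The classic strategy applies one random transform — horizontal/vertical
flip, rotation by a multiple of 90° (so masks need no interpolation), or
whitening (per-image standardization affinely rescaled into [0, 1] around
mean 0.5; "whitening" is under-specified in the source description and
ZCA is deliberately not implied). The four noise strategies inject
additive Gaussian, multiplicative speckle, salt-and-pepper, or Poisson
shot noise at documented magnitudes (σ = 0.05, r = 0.05, λ_max = 255;
none are published, these are conventional mild settings).

The six loss-named groups (bce, bce_l1, ls, poisson, wass, pwass)
originally came from adversarial autoencoders trained under those losses
in prior work; those generators are out of scope here and cannot be
reproduced. The package emulates each as a distinct fixed recipe (random
geometric transform plus a mild strategy-specific noise) and flags every
such item `emulated = TRUE`. This preserves the eleven-strategy topology
of the experiment plan — the point is that the protocol is executable and
leakage-testable — without claiming fidelity to the generative models.

## The phantom generator

`generatePhantom()` renders what the study's images look like
statistically, not optically: a dark elliptical body (semi-axes 15–35% of
the image side, random orientation, center jittered ±10%) with a darker
rim, 0–4 neuroepithelial buds as disks centered on the body boundary,
a bright textured background, spreading-cell debris as small dark
Gaussian blobs strictly outside the ground-truth mask (reproducing the
classic false-positive source), Gaussian smoothing, and photon shot noise
(pixel ~ Poisson(λ_max·clean)/λ_max, λ_max = 400 by default; bright-field
acquisition noise is shot-dominated). Defaults were chosen once as
plausible for ~250×250 bright-field organoid frames; the real dataset's
intensity distribution is unpublished, so phantom realism is qualitative.
The contrast sign is configurable (swap body and background intensities)
since no pixel values are published.

Everything is deterministic in (params, index): each phantom is rendered
under a sub-seed derived from the master seed, so datasets are
reproducible item-by-item. What phantoms do *not* model — 3-D structure,
optics, staining variability, real debris morphology — bounds what
passing tests mean: they validate the pipeline's correctness and the
architectures' trainability, not clinical performance on real cultures.

## Evaluation

`confusionCounts()` tallies TP/FP/TN/FN pixels; `segMetrics()` derives
Dice, accuracy, sensitivity, specificity, precision and F1. Ratios with a
zero denominator (empty ground truth or empty prediction) are reported as
`NA` with a flag rather than silently coerced to 0 or 1 — silent
conventions corrupt medians on tiny datasets. From a single counts
object, F1 ≡ Dice algebraically (both equal 2TP/(2TP + FP + FN)); the
test suite asserts this identity. Published tables that show different
Dice and F1 values for the same method must therefore mix computation
routes, so the package provides both and labels them:
per-image aggregation (`aggregateMetrics()`, median by default, mean
available) and pooled counts (`poolCounts()` then `segMetrics()`).

`overlayMask()` renders TP white, TN black (or the dimmed source image),
and FP/FN in two accent colors; both published palettes (light pink/light
green and purple/cyan) are available because the source material uses
both. `resultsTable()` produces the architecture × strategy grid with
row-max flags (ties all flagged), and `methodsTable()` the five-row
methods comparison (Dice, F1-score, Sensitivity, Specificity, Accuracy).

## Classical baselines

Five non-learned baselines, sharing the dark-foreground polarity
convention:

* `thresholdSegment()` — fixed threshold 185 on the 0–255 scale
  (converted to 185/255 internally; one internal intensity scale) or
  Otsu's method; a constant image has no Otsu threshold and errors.
* `regionGrowing()` — flood fill accepting frontier pixels within 0.2 of
  the running region mean, frontier dilated by 1 px per step; seeds
  default to the image center plus the global dark extremum (no seeding
  rule is published).
* `kmeansPsoSegment()` — intensity k-means whose centers are refined by a
  global-best particle swarm over the within-cluster sum of squares, then
  polished by `stats::kmeans()`. The swarm's first particle is a
  deterministic quantile initialisation, so a degenerate swarm (1
  particle, 0 iterations) reduces exactly to plain k-means. The swarm
  variant referenced by the study is not described there; a standard
  global-best topology is assumed.
* `activeContourSegment()` — Chan–Vese-style two-phase region energy
  evolved for a fixed budget, with Gaussian smoothing of the level set as
  curvature regularisation; images are min-max normalised internally so
  the result is gain-invariant.
* `watershedSegment()` — gradient-magnitude flooding from two marker
  sets (dark-extreme interior markers, image-border exterior markers);
  the basins tile the image and foreground is the interior basin union.

A level-set baseline is deliberately absent: it appears in the source's
method list but not in its comparison table.

## Problem sizes used by the tests and acceptance script

The suites run at desk scale, chosen as the smallest sizes at which every
claim is still meaningful: architecture checks at sides 64 and 250
(build/shape/counting only — no training at 250); engine gradient checks
at side 32; the single-phantom overfit and the leave-one-out smoke runs
at side 64 with 4–6 phantoms and groups of the same size; metric oracles
on 1,000 random 64×64 mask pairs; noise statistics on 250×250 fields.
The full 40-original, 440-launch protocol is the same code path with
larger arguments.

## Known limitations

* The engine is CPU-only and single-threaded apart from BLAS; a full
  250×250, 440-launch study is a long computation (days, matching the
  scale of the original training effort on GPU hardware).
* Phantoms are 2-D piecewise-smooth scenes; no optics, no real textures.
* The loss-named augmentation groups are emulations (flagged as such),
  so conclusions about *which* AAE loss best augments training cannot be
  reproduced here — only the protocol that would test them.
* Batch normalization at inference relies on running moments; very short
  trainings (a few epochs) can show a train/eval gap.
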
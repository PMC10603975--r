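# munetseg

Segmentation of brain organoids (BOs) in 2-D bright-field microscopy
images when only a handful of annotated images exist.

Brain organoids are followed in culture by extracting their outline from
bright-field frames, but the available annotated datasets are tiny (tens
of images), the outlines grow irregular neuroepithelial buds after ~14
days, and spreading cells around the culture are easily mistaken for
organoid tissue. `munetseg` implements **Mu-Net**, a lightened U-Net for
this small-data regime, alongside the full **U-Net** and **UNet-Mini**
comparators, and everything needed to evaluate them reproducibly without
access to restricted imaging data.

## What is in the package

- **Architecture grid** — every network is assembled by `buildVariant()`
  from six toggleable components (layer reduction 5→4, filter bank
  [64,…,1024]→[16,32,64,64], one vs two convolutions per block,
  addition vs concatenation skips, stride-2 vs pooled downsampling,
  softmax vs sigmoid head). The 18 presets of `ablationPresets()`
  include `"Unet"` (all off), `"Mu-Net"` (layer+filter+kernel+stride,
  concatenation skips, sigmoid head) and `"UNet-Mini"` (all six on).
  `countParameters()` and `estimateFlops()` account for each spec in
  closed form (1 MAC = 2 FLOPs).
- **Training engine** — a self-contained CPU implementation
  (RcppArmadillo convolutions): Adam + binary cross-entropy, early
  stopping on training-loss plateau (`plateauEpoch()`), gradient
  clipping, batch normalization, dropout; fully seeded and reproducible.
- **Leave-one-out protocol** — `makeLooPlan()` / `runLoo()` enumerate
  one launch per (augmentation strategy × held-out image); each fold
  trains on the remaining originals plus an augmentation group built
  without the held-out image (leakage is asserted from the manifest).
  Eleven strategies: classic flips/rotations/whitening, four noise
  injections (gaussian, speckle, salt-and-pepper, shot), and six
  loss-named groups emulating AAE-generated data (flagged `emulated`).
- **Classical baselines** — fixed-185/Otsu thresholding, region growing,
  PSO-initialised k-means, Chan–Vese-style active contour, marker
  watershed.
- **Evaluation** — pixel confusion counts; Dice, accuracy, sensitivity,
  specificity, precision, F1 (from one counts object F1 ≡ Dice =
  2TP/(2TP+FP+FN); undefined ratios are flagged `NA`, never coerced);
  per-image vs pooled aggregation, FP/FN color overlays, and the
  architecture×strategy / methods-comparison tables.
- **Phantom generator** — `generatePhantom()` renders bright-field-like
  organoid scenes with paired ground-truth masks: dark elliptical body
  with a darker rim, 0–4 neuroepithelial buds, bright textured
  background, spreading-cell debris outside the mask, Poisson shot
  noise. Deterministic in (params, index).

A command-line front end over the same functions ships at
`inst/cli/munetseg` (subcommands `generate`, `augment`, `plan`,
`train-loo`, `segment`, `evaluate`, `ablate`, `report`), configured by a
flat YAML file (`defaultRunConfig()`).

## Worked example

Train Mu-Net on five synthetic organoid phantoms and segment a held-out
sixth:

```r
library(munetseg)

params <- phantomParams(side = 64L, seed = 1L)
ds <- generateDataset(6, params)

spec <- buildMuNet(64L)
spec
#> ModelSpec 'Mu-Net': input 64x64, 41 layers, output 64x64x1, 535,877 parameters

model <- trainModel(spec, ds[1:5],
                    trainingConfig(maxEpochs = 30L, patience = 30L, seed = 1L))
pred <- predictMask(model, ds[[6]]$image)
segMetrics(confusionCounts(pred, ds[[6]]$mask))
#> MetricSet: dice 0.9867, acc 0.9946, sens 0.9819, spec 0.9979, prec 0.9915, f1 0.9867
```

Dice is the overlap 2|A∩B|/(|A|+|B|) between prediction and ground
truth; here the 30-epoch network recovers 98.7% overlap on the unseen
phantom. The k-means baseline on the same image reaches Dice 0.9799 with
perfect sensitivity but lower precision — on clean phantoms the
clustering baseline is competitive, which is exactly why the harder,
debris-heavy settings need the learned models.

The full study protocol is the same code path at larger arguments:

```r
plan <- makeLooPlan(40, strategyNames(), groupSize = 40L)  # 440 launches
results <- runLoo(plan, buildMuNet(250L), originals,
                  trainingConfig(), seed = 1, outDir = "runs/")
resultsTable(results)  # strategy-wise medians with row-max flags
```

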
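# Fixtures built in code: clean phantoms, random mask pairs, tiny specs.

# Noise-free, debris-free, bud-free phantom: a smooth dark ellipse on a
# bright background — the "clean disk" used by the classical baselines.
cleanDiskPhantom <- function(side = 96L, seed = 2L) {
  generatePhantom(phantomParams(side = as.integer(side), seed = seed,
                                nBudsRange = c(0L, 0L), debrisDensity = 0,
                                shotNoiseScale = Inf), 1)
}

# Random binary mask pair of a given side.
randomMaskPair <- function(side = 64L, p = 0.3) {
  list(pred = matrix(rbinom(side * side, 1, p), side, side),
       gt = matrix(rbinom(side * side, 1, p), side, side))
}

# Cheap architecture without dropout/batch-norm for deterministic
# training tests (pooled family, 4 levels, reduced filters, single convs).
tinySpec <- function(side = 16L) {
  buildVariant(ablationConfig(layerReduction = TRUE, filterReduction = TRUE,
                              kernelReduction = TRUE),
               as.integer(side), name = "tiny")
}

# Independent brute-force confusion counting via cross-tabulation.
oracleCounts <- function(pred, gt) {
  tab <- table(factor(pred, levels = c(0, 1)), factor(gt, levels = c(0, 1)))
  list(tp = tab["1", "1"], fp = tab["1", "0"],
       tn = tab["0", "0"], fn = tab["0", "1"])
}
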
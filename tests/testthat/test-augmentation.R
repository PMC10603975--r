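applyTransform <- munetseg:::applyTransform

test_that("flips are involutions and rotations permute indices", {
  set.seed(1)
  px <- matrix(runif(64 * 64), 64, 64)
  lb <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  for (tr in c("hflip", "vflip")) {
    once <- applyTransform(px, lb, tr)
    twice <- applyTransform(once$image, once$mask, tr)
    expect_identical(twice$image, px)
    expect_identical(twice$mask, lb)
  }
  # index-permutation oracle for the quarter rotation
  rot <- applyTransform(px, lb, "rot90")
  for (k in 1:20) {
    i <- sample(64, 1); j <- sample(64, 1)
    expect_equal(rot$image[64 - j + 1, i], px[i, j])
    expect_equal(rot$mask[64 - j + 1, i], lb[i, j])
  }
  # four quarter turns restore the original
  cur <- list(image = px, mask = lb)
  for (k in 1:4) cur <- applyTransform(cur$image, cur$mask, "rot90")
  expect_identical(cur$image, px)
})

test_that("metrics are invariant under joint geometric transforms", {
  set.seed(2)
  pred <- matrix(rbinom(900, 1, 0.4), 30, 30)
  gt <- matrix(rbinom(900, 1, 0.4), 30, 30)
  ref <- metricValues(segMetrics(confusionCounts(pred, gt)))
  for (tr in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    tp <- applyTransform(pred, pred, tr)$image
    tg <- applyTransform(gt, gt, tr)$image
    expect_equal(metricValues(segMetrics(confusionCounts(tp, tg))), ref)
  }
})

test_that("whitening standardizes to mean 0.5 and leaves masks alone", {
  set.seed(3)
  px <- matrix(runif(1024, 0.2, 0.9), 32, 32)
  w <- whitenImage(px)
  expect_equal(mean(w), 0.5, tolerance = 1e-6)
  expect_gte(min(w), 0); expect_lte(max(w), 1)
  expect_equal(whitenImage(matrix(0.7, 32, 32)), matrix(0.5, 32, 32))
  out <- applyTransform(px, px * 0, "whiten")
  expect_identical(out$mask, px * 0)
})

test_that("zero-magnitude noise injections are identities", {
  set.seed(4)
  px <- matrix(runif(1024), 32, 32)
  expect_equal(pixels(injectNoise(px, "gaussian", sigma = 0)), px)
  expect_equal(pixels(injectNoise(px, "speckle", sigma = 0)), px)
  expect_equal(pixels(injectNoise(px, "salt_pepper", rate = 0)), px)
})

test_that("salt-and-pepper alters the expected pixel fraction", {
  set.seed(5)
  px <- matrix(runif(250 * 250, 0.05, 0.95), 250, 250)
  r <- 0.1
  n <- length(px)
  out <- pixels(injectNoise(px, "salt_pepper", rate = r))
  altered <- mean(out != px)
  se <- sqrt(r * (1 - r) / n)
  expect_lt(abs(altered - r), 3 * se)
})

test_that("shot noise follows Poisson moments", {
  set.seed(6)
  px <- matrix(0.5, 100, 100)
  lam <- 1000
  out <- pixels(injectNoise(px, "shot", lambdaMax = lam))
  expect_equal(mean(out), 0.5, tolerance = 0.01)
  expect_equal(var(as.vector(out)), 0.5 / lam, tolerance = 0.1)
})

test_that("unknown noise models and misaligned pairs are rejected", {
  px <- matrix(0.5, 16, 16)
  expect_error(injectNoise(px, "perlin"), "arg")
  expect_error(classicAugment(px, matrix(0, 8, 8)), "differ")
})

test_that("groups are fold-safe, deterministic and record provenance", {
  ds <- generateDataset(40, phantomParams(side = 32L, seed = 1L))
  grp <- buildGroup(ds, "classic", 40, excludeId = "007", seed = 9L)
  expect_length(grp, 40)
  src <- vapply(grp, `[[`, "", "sourceId")
  expect_false(any(src == "007"))
  expect_true(all(src %in% sprintf("%03d", 1:40)))
  grp2 <- buildGroup(ds, "classic", 40, excludeId = "007", seed = 9L)
  expect_identical(lapply(grp, function(e) pixels(e$image)),
                   lapply(grp2, function(e) pixels(e$image)))
  tiny <- buildGroup(ds[1:2], "gaussian", 1, seed = 2L)
  expect_length(tiny, 1)
  expect_error(buildGroup(ds[1], "classic", 5, excludeId = "001"),
               "excluded")
})

test_that("the six emulated loss groups total 240 images and are flagged", {
  ds <- generateDataset(10, phantomParams(side = 32L, seed = 2L))
  groups <- lapply(strategyNames("loss"), function(s)
    buildGroup(ds, s, 40, seed = 3L))
  expect_equal(sum(lengths(groups)), 240)
  for (g in groups) expect_true(all(vapply(g, `[[`, TRUE, "emulated")))
  noise <- buildGroup(ds, "speckle", 40, seed = 3L)
  expect_false(any(vapply(noise, `[[`, TRUE, "emulated")))
})

test_that("noise strategies never alter the mask", {
  ds <- generateDataset(3, phantomParams(side = 32L, seed = 4L))
  for (s in strategyNames("noise")) {
    g <- buildGroup(ds, s, 5, seed = 1L)
    for (item in g) {
      orig <- ds[[match(item$sourceId, sprintf("%03d", 1:3))]]
      expect_identical(maskLabels(item$mask), maskLabels(orig$mask))
    }
  }
})
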
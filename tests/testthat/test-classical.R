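test_that("fixed thresholding separates a two-level image exactly", {
  px <- matrix(200 / 255, 20, 20)
  px[5:10, 5:10] <- 100 / 255
  m <- thresholdSegment(px, threshold = 185, polarity = "dark")
  expect_identical(maskLabels(m), (px == 100 / 255) * 1)
  # boundary thresholds on an image with strictly interior values
  expect_true(all(maskLabels(thresholdSegment(px, 255)) == 1))
  expect_true(all(maskLabels(thresholdSegment(px, 0)) == 0))
})

test_that("Otsu matches an exhaustive between-class-variance search", {
  set.seed(1)
  px <- matrix(c(rnorm(2048, 0.2, 0.04), rnorm(2048, 0.8, 0.04)), 64, 64)
  px <- pmin(pmax(px, 0), 1)
  # oracle: maximize between-class variance over a fine threshold grid
  grid <- seq(0.01, 0.99, by = 0.005)
  bcv <- vapply(grid, function(t) {
    w0 <- mean(px < t)
    if (w0 == 0 || w0 == 1) return(0)
    (w0 * (1 - w0)) * (mean(px[px >= t]) - mean(px[px < t]))^2
  }, 0)
  # between the modes the criterion is flat, so any maximizer is valid:
  # the package threshold must be between the modes and attain (within a
  # grid step) the oracle's maximal between-class variance
  tPkg <- EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  expect_true(tPkg > 0.3 && tPkg < 0.7)
  bcvPkg <- bcv[which.min(abs(grid - tPkg))]
  expect_gt(bcvPkg, 0.999 * max(bcv))
  m <- thresholdSegment(px, "otsu", polarity = "dark")
  expect_gt(segMetrics(confusionCounts(m, (px < 0.5) * 1))@dice, 0.99)
  expect_error(thresholdSegment(matrix(0.5, 16, 16), "otsu"),
               "degenerate histogram")
})

test_that("region growing floods homogeneous regions deterministically", {
  # constant image: everything joins the region
  m <- regionGrowing(matrix(0.4, 20, 20), seeds = matrix(c(3, 3), 1))
  expect_true(all(maskLabels(m) == 1))
  # two constant halves: only the seeded half is recovered, exactly
  hp <- matrix(0.9, 40, 40); hp[, 1:20] <- 0.2
  rg <- regionGrowing(hp, seeds = matrix(c(5, 5), 1),
                      regionalThreshold = 0.2)
  expect_identical(maskLabels(rg), (hp == 0.2) * 1)
  # zero tolerance: only pixels equal to the seed value and connected
  px <- matrix(0.5, 10, 10); px[1:3, 1:3] <- 0.2; px[8:10, 8:10] <- 0.2
  rg0 <- regionGrowing(px, seeds = matrix(c(2, 2), 1),
                       regionalThreshold = 0)
  expect_identical(which(maskLabels(rg0) == 1),
                   which(row(px) <= 3 & col(px) <= 3))
  expect_error(regionGrowing(px, seeds = matrix(c(50, 2), 1)), "bounds")
})

test_that("PSO k-means recovers a well-separated bimodal partition", {
  set.seed(2)
  truth <- matrix(0, 64, 64); truth[20:45, 15:40] <- 1
  px <- ifelse(truth == 1, 0.2, 0.8) +
    matrix(rnorm(64 * 64, 0, 0.02), 64, 64)
  img <- OrganoidImage(pmin(pmax(px, 0), 1))
  m <- kmeansPsoSegment(img, seed = 1L)
  expect_gte(segMetrics(confusionCounts(m, truth))@dice, 0.99)
  expect_error(kmeansPsoSegment(matrix(0.5, 16, 16)), "degenerate")
})

test_that("a degenerate swarm reduces to plain k-means", {
  set.seed(3)
  px <- matrix(runif(1024, 0, 1), 32, 32)
  m <- kmeansPsoSegment(px, nParticles = 1L, iterations = 0L, seed = 5L)
  init <- as.numeric(quantile(px, c(0.25, 0.75)))
  km <- kmeans(as.vector(px), centers = matrix(init, ncol = 1),
               iter.max = 100)
  ref <- matrix((km$cluster == which.min(km$centers)) * 1, 32, 32)
  expect_identical(maskLabels(m), ref)
})

test_that("the PSO global best is non-increasing", {
  set.seed(4)
  px <- matrix(runif(1024), 32, 32)
  det <- kmeansPsoSegment(px, seed = 7L, details = TRUE)
  expect_true(all(diff(det$objective) <= 1e-12))
})

test_that("active contour segments a clean disk and honors its budget", {
  ph <- cleanDiskPhantom(96L, seed = 2L)
  m <- activeContourSegment(ph$image)
  expect_gte(segMetrics(confusionCounts(m, ph$mask))@dice, 0.95)
  # zero iterations return the initialization unchanged
  init <- matrix(0, 96, 96); init[40:60, 40:60] <- 1
  m0 <- activeContourSegment(ph$image, init = init, iterations = 0L)
  expect_identical(maskLabels(m0), init)
  expect_error(activeContourSegment(ph$image, init = init * 0), "empty")
})

test_that("the region energy is invariant to positive intensity gain", {
  ph <- cleanDiskPhantom(64L, seed = 3L)
  px <- pixels(ph$image)
  m1 <- activeContourSegment(px, iterations = 100L)
  m2 <- activeContourSegment(px * 0.4, iterations = 100L)
  expect_identical(maskLabels(m1), maskLabels(m2))
})

test_that("watershed basins tile the image and segment a clean disk", {
  ph <- cleanDiskPhantom(96L, seed = 2L)
  ws <- watershedSegment(ph$image, details = TRUE)
  expect_true(all(ws$basins %in% c(1, 2)))  # interior + exterior partition
  expect_gte(segMetrics(confusionCounts(ws$mask, ph$mask))@dice, 0.9)
})

test_that("saturated markers leave no room for basin growth", {
  ph <- cleanDiskPhantom(64L, seed = 5L)
  # markerQuantile 1 marks every non-border pixel as interior
  ws <- watershedSegment(ph$image, markerQuantile = 1, details = TRUE)
  inner <- maskLabels(ws$mask)[2:63, 2:63]
  expect_true(all(inner == 1))
})

test_that("k-means leads the clean-phantom baseline ranking", {
  # mirrors the methods-comparison ordering on phantoms: the clustering
  # baseline should beat the other classical methods at default settings
  dices <- sapply(1:3, function(i) {
    ph <- generatePhantom(phantomParams(side = 96L, seed = 20L,
                                        nBudsRange = c(0L, 1L),
                                        debrisDensity = 0,
                                        shotNoiseScale = Inf), i)
    gt <- ph$mask
    c(kmeans = segMetrics(confusionCounts(
        kmeansPsoSegment(ph$image, seed = 1L), gt))@dice,
      threshold = segMetrics(confusionCounts(
        thresholdSegment(ph$image), gt))@dice,
      watershed = segMetrics(confusionCounts(
        watershedSegment(ph$image), gt))@dice)
  })
  means <- rowMeans(dices)
  expect_equal(names(which.max(means)), "kmeans")
})
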
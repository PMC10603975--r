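test_that("confusion counts match the four-pixel hand enumeration", {
  gt <- matrix(c(1, 0, 1, 0), 2, 2)    # gt = [[1,1],[0,0]] row-wise
  pred <- matrix(c(1, 1, 0, 0), 2, 2)  # pred = [[1,0],[1,0]] row-wise
  cc <- confusionCounts(pred, gt)
  expect_equal(c(cc@tp, cc@fn, cc@fp, cc@tn), c(1, 1, 1, 1))
})

test_that("identical and disjoint masks give the boundary metric values", {
  set.seed(1)
  g <- matrix(rbinom(256, 1, 0.4), 16, 16)
  cc <- confusionCounts(g, g)
  expect_equal(cc@fp, 0); expect_equal(cc@fn, 0)
  expect_equal(cc@tp, sum(g))
  m <- segMetrics(cc)
  expect_equal(m@dice, 1); expect_equal(m@f1, 1)
  expect_equal(m@accuracy, 1); expect_equal(m@sensitivity, 1)
  # disjoint non-empty masks
  a <- matrix(0, 16, 16); a[1:4, ] <- 1
  b <- matrix(0, 16, 16); b[10:12, ] <- 1
  md <- segMetrics(confusionCounts(a, b))
  expect_equal(md@dice, 0); expect_equal(md@sensitivity, 0)
})

test_that("metric closed forms agree on the balanced counts example", {
  m <- segMetrics(new("ConfusionCounts", tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(m@dice, 1 / 2)
  expect_equal(m@accuracy, 1 / 2)
  expect_equal(m@sensitivity, 1 / 2)
  expect_equal(m@specificity, 1 / 2)
  expect_equal(m@precision, 1 / 2)
  expect_equal(m@f1, 1 / 2)
})

test_that("counts partition the image for random mask pairs", {
  set.seed(2)
  for (i in 1:20) {
    rp <- randomMaskPair(32)
    cc <- confusionCounts(rp$pred, rp$gt)
    expect_equal(cc@tp + cc@fp + cc@tn + cc@fn, 32 * 32)
    o <- oracleCounts(rp$pred, rp$gt)
    expect_equal(cc@tp, as.numeric(o$tp))
    expect_equal(cc@fp, as.numeric(o$fp))
    expect_equal(cc@tn, as.numeric(o$tn))
    expect_equal(cc@fn, as.numeric(o$fn))
  }
  expect_error(confusionCounts(matrix(0, 8, 8), matrix(0, 9, 9)), "differ")
})

test_that("undefined ratios are flagged, never silently coerced", {
  # empty ground truth and empty prediction
  m <- segMetrics(new("ConfusionCounts", tp = 0, fp = 0, tn = 100, fn = 0))
  expect_true(is.na(m@sensitivity))
  expect_true(is.na(m@precision))
  expect_true(is.na(m@dice))
  expect_setequal(m@undefined, c("dice", "sensitivity", "precision", "f1"))
  # empty prediction, non-empty gt: precision undefined, dice defined
  m2 <- segMetrics(new("ConfusionCounts", tp = 0, fp = 0, tn = 90, fn = 10))
  expect_equal(m2@dice, 0)
  expect_true(is.na(m2@precision))
  # no-overlap case: precision and sensitivity defined and 0, f1 takes 0
  m3 <- segMetrics(new("ConfusionCounts", tp = 0, fp = 5, tn = 85, fn = 10))
  expect_equal(m3@f1, 0)
  expect_equal(m3@dice, 0)
})

test_that("f1 equals dice whenever both derive from shared counts", {
  set.seed(3)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    fn <- sample(0:50, 1); tn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    m <- segMetrics(new("ConfusionCounts", tp = tp, fp = fp, tn = tn,
                        fn = fn))
    expect_equal(m@f1, m@dice, tolerance = 1e-12)
  }
})

test_that("aggregation uses order statistics and ignores NA entries", {
  ms <- lapply(c(0.2, 0.8, 0.8), function(d)
    new("MetricSet", dice = d, accuracy = d, sensitivity = d,
        specificity = d, precision = d, f1 = d))
  expect_equal(aggregateMetrics(ms, "median")@dice, 0.8)
  expect_equal(aggregateMetrics(ms, "mean")@dice, 0.6)
  # permutation invariance
  expect_equal(aggregateMetrics(rev(ms))@dice, aggregateMetrics(ms)@dice)
  # single element is its own aggregate
  expect_equal(aggregateMetrics(ms[1], "median")@dice, 0.2)
  expect_equal(aggregateMetrics(ms[1], "mean")@dice, 0.2)
  # NA exclusion with a reported count
  msNA <- c(ms, list(new("MetricSet", dice = NA_real_, accuracy = 0.5,
                         sensitivity = 0.5, specificity = 0.5,
                         precision = 0.5, f1 = NA_real_,
                         undefined = c("dice", "f1"))))
  agg <- aggregateMetrics(msNA, "median")
  expect_equal(agg@dice, 0.8)
  expect_equal(unname(agg@nExcluded["dice"]), 1)
  expect_error(aggregateMetrics(list()), "empty")
})

test_that("overlay accent pixels tally exactly with the confusion counts", {
  set.seed(4)
  rp <- randomMaskPair(24)
  cc <- confusionCounts(rp$pred, rp$gt)
  for (pal in c("pink_green", "purple_cyan")) {
    ov <- overlayMask(rp$gt, rp$pred, palette = pal)
    expect_equal(dim(ov), c(24, 24, 3))
    white <- ov[, , 1] == 1 & ov[, , 2] == 1 & ov[, , 3] == 1
    black <- ov[, , 1] == 0 & ov[, , 2] == 0 & ov[, , 3] == 0
    expect_equal(sum(white), cc@tp)
    expect_equal(sum(black), cc@tn)
    expect_equal(sum(!white & !black), cc@fp + cc@fn)
  }
})

test_that("overlay saturates correctly in the degenerate cases", {
  g <- matrix(rbinom(100, 1, 0.5), 10, 10)
  ovEq <- overlayMask(g, g)
  accent <- (ovEq[, , 1] != ovEq[, , 2]) | (ovEq[, , 2] != ovEq[, , 3])
  expect_equal(sum(accent), 0)  # perfect prediction: no accent pixels
  ovFP <- overlayMask(matrix(0, 10, 10), matrix(1, 10, 10))
  expect_true(all(ovFP[, , 1] == 1 & ovFP[, , 2] == 0.71))  # all FP pink
})

test_that("results grids flag row maxima including ties", {
  df <- data.frame(
    arch = rep(c("A", "B"), each = 6),
    strategy = rep(rep(c("classic", "gaussian", "shot"), each = 2), 2),
    dice = c(0.5, 0.6, 0.8, 0.8, 0.7, 0.7,   # A: medians .55 .8 .7
             0.9, 0.9, 0.2, 0.2, 0.9, 0.9))  # B: medians .9 .2 .9 (tie)
  tab <- resultsTable(df)
  expect_equal(dim(tab$values), c(2L, 3L))
  expect_equal(tab$values["A", "gaussian"], 0.8)
  expect_identical(unname(tab$best["A", ]), c(FALSE, TRUE, FALSE))
  expect_identical(unname(tab$best["B", ]), c(TRUE, FALSE, TRUE))
  expect_error(resultsTable(df[0, ]), "empty")
})

test_that("the methods table exposes exactly the five comparison rows", {
  m <- segMetrics(new("ConfusionCounts", tp = 40, fp = 10, tn = 45, fn = 5))
  tab <- methodsTable(list(munet = m, kmeans = m), computation = "pooled")
  expect_equal(rownames(tab), c("Dice", "F1-score", "Sensitivity",
                                "Specificity", "Accuracy"))
  expect_equal(ncol(tab), 2)
  expect_equal(attr(tab, "computation"), "pooled")
  # pooled vs per-image routes are both available and labeled
  pooled <- segMetrics(poolCounts(list(
    new("ConfusionCounts", tp = 10, fp = 0, tn = 50, fn = 0),
    new("ConfusionCounts", tp = 5, fp = 10, tn = 35, fn = 10))))
  perImage <- aggregateMetrics(list(
    segMetrics(new("ConfusionCounts", tp = 10, fp = 0, tn = 50, fn = 0)),
    segMetrics(new("ConfusionCounts", tp = 5, fp = 10, tn = 35, fn = 10))))
  expect_false(isTRUE(all.equal(pooled@dice, perImage@dice)))
})
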
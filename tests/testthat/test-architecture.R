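test_that("preset definitions match their named builders", {
  expect_identical(buildUNet(64L)@layers,
                   buildVariant(ablationPreset("Unet"), 64L)@layers)
  expect_identical(buildUNetMini(64L)@layers,
                   buildVariant(ablationPreset("UNet-Mini"), 64L)@layers)
  expect_identical(buildMuNet(64L)@layers,
                   buildVariant(ablationPreset("Mu-Net"), 64L)@layers)
  # all-off config is the full U-Net
  expect_identical(buildVariant(ablationConfig(), 64L)@layers,
                   buildUNet(64L)@layers)
})

test_that("building is referentially transparent", {
  a <- buildVariant(ablationPreset("Filter+Kernel"), 64L)
  b <- buildVariant(ablationPreset("Filter+Kernel"), 64L)
  expect_identical(a@layers, b@layers)
})

test_that("U-Net traces the classic resolution ladder", {
  spec <- buildUNet(64L)
  tab <- specTable(spec)
  pools <- tab[tab$kind == "maxpool", ]
  expect_equal(pools$outH, c(32, 16, 8, 4))
  expect_equal(tab$outH[tab$name == "head_out"], 64)
  expect_equal(tab$outC[tab$name == "head_out"], 1)
  convs <- tab[tab$kind == "conv" & grepl("^enc", tab$name), ]
  expect_equal(sort(unique(convs$filters)), c(64, 128, 256, 512))
})

test_that("Mu-Net realizes the stride/batch-norm block structure", {
  spec <- buildMuNet(64L)
  tab <- specTable(spec)
  expect_equal(sum(tab$kind == "dropout"), 1)
  expect_equal(spec@layers[["bottleneck_dropout"]]$rate, 0.5)
  expect_equal(sum(tab$kind == "batchnorm"), 4)
  expect_equal(sum(tab$kind == "maxpool"), 1)
  # one stride-2 downsampling conv per encoder block
  expect_equal(sum(tab$kind == "conv" & tab$stride == 2, na.rm = TRUE), 4)
  enc <- tab[grepl("^enc\\d_conv1$", tab$name), ]
  expect_equal(enc$filters, c(16, 32, 64, 64))
  # sigmoid head preceded by a two-filter 3x3 convolution
  expect_equal(tab$activation[tab$name == "head_out"], "sigmoid")
  expect_equal(tab$filters[tab$name == "head_conv"], 2)
  expect_equal(tab$kernel[tab$name == "head_out"], 1)
})

test_that("all 18 presets build and shape-check at sides 64 and 250", {
  presets <- ablationPresets()
  expect_length(presets, 18)
  for (nm in names(presets)) {
    for (side in c(64L, 250L)) {
      spec <- buildVariant(presets[[nm]], side, name = nm)
      out <- spec@layers[[length(spec@layers)]]$outShape
      expect_equal(out[1:2], c(side, side), info = paste(nm, side))
      expect_true(out[3] %in% c(1L, 2L))
      softmax <- presets[[nm]]@softmaxActivation
      expect_equal(out[3], if (softmax) 2L else 1L, info = nm)
    }
  }
})

test_that("parameter counts follow the published ordering", {
  pu <- countParameters(buildUNet(64L))
  pm <- countParameters(buildMuNet(64L))
  pmini <- countParameters(buildUNetMini(64L))
  expect_lt(pmini, pm)
  expect_lt(pm, pu)
  # counts are side-independent (fully convolutional)
  expect_equal(countParameters(buildMuNet(128L)), pm)
})

test_that("closed-form parameter counts match hand counts", {
  mk <- function(inC, f, k) {
    layers <- list(
      input = list(name = "input", kind = "input", inputs = character(0),
                   outShape = c(10L, 10L, inC)),
      c1 = list(name = "c1", kind = "conv", inputs = "input",
                filters = f, kernel = k, stride = 1L,
                activation = "linear", inChannels = inC,
                outShape = c(10L, 10L, f)))
    new("ModelSpec", name = "hand", inputSide = 10L, layers = layers,
        config = ablationConfig())
  }
  expect_equal(countParameters(mk(1L, 1L, 1L)), 2L)          # 1 weight + 1 bias
  expect_equal(countParameters(mk(16L, 32L, 3L)), 4640L)     # 16*9*32 + 32
  expect_equal(estimateFlops(mk(1L, 1L, 1L)) * 1e6, 200)     # 10*10*2
})

test_that("FLOPs follow the published ordering and quadratic scaling", {
  fu <- estimateFlops(buildUNet(64L), 250L)
  fm <- estimateFlops(buildMuNet(64L), 250L)
  fmini <- estimateFlops(buildUNetMini(64L), 250L)
  expect_gt(fu, fm)
  expect_gte(fm, fmini)
  spec <- buildMuNet(64L)
  expect_equal(estimateFlops(spec, 128L) / estimateFlops(spec, 64L), 4,
               tolerance = 1e-9)
})

test_that("filter reduction never increases the parameter count", {
  flags <- expand.grid(l = c(FALSE, TRUE), k = c(FALSE, TRUE),
                       e = c(FALSE, TRUE), s = c(FALSE, TRUE),
                       a = c(FALSE, TRUE))
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    without <- countParameters(buildVariant(
      ablationConfig(layerReduction = f$l, filterReduction = FALSE,
                     kernelReduction = f$k, ewiseSkip = f$e,
                     strideDownsampling = f$s, softmaxActivation = f$a),
      64L))
    with <- countParameters(buildVariant(
      ablationConfig(layerReduction = f$l, filterReduction = TRUE,
                     kernelReduction = f$k, ewiseSkip = f$e,
                     strideDownsampling = f$s, softmaxActivation = f$a),
      64L))
    expect_lte(with, without)
  }
})

test_that("addition skips shape-check with matched channels", {
  spec <- buildUNetMini(64L)
  merges <- Filter(function(l) l$kind == "add", spec@layers)
  expect_gt(length(merges), 0)
  for (m in merges) {
    shapes <- lapply(m$inputs, function(n) spec@layers[[n]]$outShape)
    expect_equal(shapes[[1]][3], shapes[[2]][3])
  }
})

test_that("undersized inputs are rejected with a clear error", {
  expect_error(buildUNet(16L), "too small")
  expect_error(buildMuNet(16L), "too small")
})

test_that("spec tables serialize to CSV", {
  f <- tempfile(fileext = ".csv")
  specTable(buildMuNet(64L), f)
  tab <- read.csv(f)
  expect_true(all(c("name", "kind", "filters", "kernel", "stride",
                    "activation") %in% names(tab)))
  expect_equal(tab$name[1], "input")
})
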
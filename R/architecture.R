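# Declarative construction of U-Net, UNet-Mini, Mu-Net and every ablation
# variant from six toggleable design components, with shape inference,
# closed-form parameter counting and FLOP estimation.
#
# Structural conventions (documented in the methods vignette):
# * 'same' padding everywhere; odd sizes halve as ceil(H/2); at a skip
#   merge the decoder tensor is center-cropped or zero-padded by <= 1 px to
#   match the encoder tap.
# * With stride downsampling enabled, an encoder block is always
#   conv(s=1) + conv(s=2) + batch-norm (the stride-2 convolution replaces
#   the pool and restores the second convolution), and decoder stages keep
#   two convolutions; the bottleneck is dropout(0.5) + 2x2 max-pool +
#   a double convolution. The decoder mirrors the encoder exactly: one x2
#   upsampling per encoder x2, so the output side equals the input side.
# * Skip taps: stride blocks tap the stride-1 convolution output (at the
#   block's input resolution); pooled blocks tap the last convolution
#   before the pool.

# ---- internal spec builder ------------------------------------------------

newBuilder <- function(side) {
  b <- new.env(parent = emptyenv())
  b$layers <- list()
  b$shapes <- list(input = c(side, side, 1L))
  b$layers[["input"]] <- list(name = "input", kind = "input",
                              inputs = character(0),
                              outShape = c(side, side, 1L))
  b
}

shapeOf <- function(b, name) b$shapes[[name]]

putLayer <- function(b, lay, shape) {
  lay$outShape <- as.integer(shape)
  b$layers[[lay$name]] <- lay
  b$shapes[[lay$name]] <- as.integer(shape)
  lay$name
}

bConv <- function(b, input, filters, kernel, stride, activation, name) {
  s <- shapeOf(b, input)
  out <- c(ceiling(s[1] / stride), ceiling(s[2] / stride), filters)
  putLayer(b, list(name = name, kind = "conv", inputs = input,
                   filters = as.integer(filters), kernel = as.integer(kernel),
                   stride = as.integer(stride), activation = activation,
                   inChannels = s[3]), out)
}

bPool <- function(b, input, name) {
  s <- shapeOf(b, input)
  putLayer(b, list(name = name, kind = "maxpool", inputs = input),
           c(ceiling(s[1] / 2), ceiling(s[2] / 2), s[3]))
}

bUpsample <- function(b, input, name) {
  s <- shapeOf(b, input)
  putLayer(b, list(name = name, kind = "upsample", inputs = input),
           c(2 * s[1], 2 * s[2], s[3]))
}

bBnorm <- function(b, input, name) {
  s <- shapeOf(b, input)
  putLayer(b, list(name = name, kind = "batchnorm", inputs = input,
                   channels = s[3]), s)
}

bDropout <- function(b, input, rate, name) {
  s <- shapeOf(b, input)
  putLayer(b, list(name = name, kind = "dropout", inputs = input,
                   rate = rate), s)
}

# x2 nearest upsampling followed by a 2x2 convolution ("up-convolution")
bUpconv <- function(b, input, filters, name) {
  up <- bUpsample(b, input, paste0(name, "samp"))
  bConv(b, up, filters, 2L, 1L, "relu", name)
}

# Skip merge. The decoder tensor (first input) is center-cropped/padded to
# the tap's spatial size; 'add' merges require equal channel counts, and a
# 1x1 channel-matching convolution is inserted on the tap when they differ.
bMerge <- function(b, decoder, tap, kind, name) {
  sd <- shapeOf(b, decoder); st <- shapeOf(b, tap)
  if (abs(sd[1] - st[1]) > 1 || abs(sd[2] - st[2]) > 1)
    stop("merge '", name, "': decoder/tap spatial mismatch exceeds 1 px (",
         sd[1], "x", sd[2], " vs ", st[1], "x", st[2], ")")
  if (kind == "add" && sd[3] != st[3])
    tap <- bConv(b, tap, sd[3], 1L, 1L, "linear", paste0(name, "_match"))
  st <- shapeOf(b, tap)
  outC <- if (kind == "concat") sd[3] + st[3] else sd[3]
  putLayer(b, list(name = name, kind = kind,
                   inputs = c(decoder, tap)),
           c(st[1], st[2], outC))
}

# ---- public builders ------------------------------------------------------

#' Build any architecture variant from an ablation configuration
#'
#' Starts from the full U-Net (5 levels, filters
#' \code{[64,128,256,512,1024]}, double 3x3 convolutions, 2x2 max pooling,
#' up-convolution decoder with concatenation skips, 1x1 sigmoid head) and
#' applies each enabled reduction compositionally. All named presets
#' (see [ablationPresets()]) build and shape-check; the output spatial
#' size always equals the input size.
#'
#' @param config an [AblationConfig-class].
#' @param side input image side (>= 32 for 5-level variants, >= 16
#'   otherwise).
#' @param name optional label for the resulting spec.
#' @return A shape-checked [ModelSpec-class].
#' @export
buildVariant <- function(config, side = 250L, name = NULL) {
  stopifnot(is(config, "AblationConfig"))
  side <- as.integer(side)
  L <- if (config@layerReduction) 4L else 5L
  # pooled family halves L-1 times; stride family halves L+1 times and
  # needs the pre-pool map to stay >= 2 px for the mirrored decoder
  nDown <- if (config@strideDownsampling) L + 1L else L - 1L
  minSide <- if (config@strideDownsampling) as.integer(2^nDown)
             else if (L == 5L) 32L else 16L
  if (side < minSide)
    stop("side ", side, " too small for ", nDown,
         " downsampling stages (need >= ", minSide, ")")
  filters <- if (config@filterReduction) {
    if (L == 4L) c(16L, 32L, 64L, 64L) else c(16L, 32L, 64L, 64L, 64L)
  } else c(64L, 128L, 256L, 512L, 1024L)[seq_len(L)]
  m <- if (config@kernelReduction) 1L else 2L
  mergeKind <- if (config@ewiseSkip) "add" else "concat"

  b <- newBuilder(side)
  cur <- "input"
  taps <- character(L)

  if (config@strideDownsampling) {
    for (i in seq_len(L)) {
      cur <- bConv(b, cur, filters[i], 3L, 1L, "relu",
                   sprintf("enc%d_conv1", i))
      taps[i] <- cur
      cur <- bConv(b, cur, filters[i], 3L, 2L, "relu",
                   sprintf("enc%d_down", i))
      cur <- bBnorm(b, cur, sprintf("enc%d_bn", i))
    }
    cur <- bDropout(b, cur, 0.5, "bottleneck_dropout")
    cur <- bPool(b, cur, "bottleneck_pool")
    for (j in 1:2)
      cur <- bConv(b, cur, filters[L], 3L, 1L, "relu",
                   sprintf("bottleneck_conv%d", j))
    cur <- bUpconv(b, cur, filters[L], "bottleneck_up")
    for (i in rev(seq_len(L))) {
      cur <- bUpconv(b, cur, filters[i], sprintf("dec%d_up", i))
      cur <- bMerge(b, cur, taps[i], mergeKind, sprintf("dec%d_merge", i))
      for (j in 1:2)
        cur <- bConv(b, cur, filters[i], 3L, 1L, "relu",
                     sprintf("dec%d_conv%d", i, j))
    }
    cur <- bConv(b, cur, 2L, 3L, 1L, "relu", "head_conv")
  } else {
    for (i in seq_len(L - 1L)) {
      for (j in seq_len(m))
        cur <- bConv(b, cur, filters[i], 3L, 1L, "relu",
                     sprintf("enc%d_conv%d", i, j))
      taps[i] <- cur
      cur <- bPool(b, cur, sprintf("enc%d_pool", i))
    }
    for (j in seq_len(m))
      cur <- bConv(b, cur, filters[L], 3L, 1L, "relu",
                   sprintf("bottleneck_conv%d", j))
    for (i in rev(seq_len(L - 1L))) {
      cur <- bUpconv(b, cur, filters[i], sprintf("dec%d_up", i))
      cur <- bMerge(b, cur, taps[i], mergeKind, sprintf("dec%d_merge", i))
      for (j in seq_len(m))
        cur <- bConv(b, cur, filters[i], 3L, 1L, "relu",
                     sprintf("dec%d_conv%d", i, j))
    }
  }
  cur <- if (config@softmaxActivation)
    bConv(b, cur, 2L, 1L, 1L, "softmax", "head_out")
  else
    bConv(b, cur, 1L, 1L, 1L, "sigmoid", "head_out")

  out <- shapeOf(b, cur)
  if (out[1] != side || out[2] != side)
    stop("shape check failed: output ", out[1], "x", out[2],
         " does not match input ", side, "x", side)
  new("ModelSpec", name = name %||% configLabel(config),
      inputSide = side, layers = b$layers, config = config)
}

configLabel <- function(config) {
  on <- c("Layer", "Filter", "Kernel", "Ewise", "Stride", "Softmax")[c(
    config@layerReduction, config@filterReduction, config@kernelReduction,
    config@ewiseSkip, config@strideDownsampling, config@softmaxActivation)]
  if (!length(on)) "Unet" else paste(on, collapse = "+")
}

#' The 18 named ablation presets
#'
#' The ablation grid: the full U-Net, every studied combination of the
#' layer/filter/kernel/ewise reductions, plus the two named architectures —
#' \code{"Mu-Net"} (layer + filter + kernel + stride, concatenation skips,
#' sigmoid head) and \code{"UNet-Mini"} (all six components on).
#'
#' @return Named list of [AblationConfig-class] objects (length 18).
#' @export
ablationPresets <- function() {
  cfg <- function(l = FALSE, f = FALSE, k = FALSE, e = FALSE, s = FALSE,
                  a = FALSE)
    ablationConfig(layerReduction = l, filterReduction = f,
                   kernelReduction = k, ewiseSkip = e,
                   strideDownsampling = s, softmaxActivation = a)
  list(
    "Unet" = cfg(),
    "Layer" = cfg(l = TRUE),
    "Filter" = cfg(f = TRUE),
    "Kernel" = cfg(k = TRUE),
    "Ewise" = cfg(e = TRUE),
    "Layer+Filter" = cfg(l = TRUE, f = TRUE),
    "Layer+Kernel" = cfg(l = TRUE, k = TRUE),
    "Layer+Ewise" = cfg(l = TRUE, e = TRUE),
    "Filter+Kernel" = cfg(f = TRUE, k = TRUE),
    "Filter+Ewise" = cfg(f = TRUE, e = TRUE),
    "Kernel+Ewise" = cfg(k = TRUE, e = TRUE),
    "Layer+Filter+Kernel" = cfg(l = TRUE, f = TRUE, k = TRUE),
    "Layer+Kernel+Ewise" = cfg(l = TRUE, k = TRUE, e = TRUE),
    "Layer+Filter+Ewise" = cfg(l = TRUE, f = TRUE, e = TRUE),
    "Filter+Kernel+Ewise" = cfg(f = TRUE, k = TRUE, e = TRUE),
    "Layer+Filter+Kernel+Ewise" = cfg(l = TRUE, f = TRUE, k = TRUE, e = TRUE),
    "Mu-Net" = cfg(l = TRUE, f = TRUE, k = TRUE, s = TRUE),
    "UNet-Mini" = cfg(l = TRUE, f = TRUE, k = TRUE, e = TRUE, s = TRUE,
                      a = TRUE))
}

#' @rdname ablationPresets
#' @param name preset name (see \code{names(ablationPresets())}).
#' @export
ablationPreset <- function(name) {
  p <- ablationPresets()
  name <- match.arg(name, names(p))
  p[[name]]
}

#' Build the full U-Net
#'
#' Five resolution levels with filters \code{[64,128,256,512,1024]}: each
#' encoder level applies two 3x3 ReLU convolutions followed by 2x2 max
#' pooling; the mirrored decoder upsamples with 2x2 up-convolutions and
#' concatenation skips; a final 1x1 convolution with sigmoid produces the
#' probability map.
#'
#' @param side input image side (>= 32).
#' @return A [ModelSpec-class].
#' @export
buildUNet <- function(side = 250L)
  buildVariant(ablationPreset("Unet"), side, name = "U-Net")

#' Build UNet-Mini
#'
#' Four levels with filters \code{[16,32,64,64]}, element-wise addition
#' skips and a two-channel softmax head: identical to
#' \code{buildVariant(ablationPreset("UNet-Mini"), side)}.
#'
#' @param side input image side (>= 16).
#' @return A [ModelSpec-class].
#' @export
buildUNetMini <- function(side = 250L)
  buildVariant(ablationPreset("UNet-Mini"), side, name = "UNet-Mini")

#' Build Mu-Net
#'
#' The lightened architecture: four encoder blocks with filters
#' \code{[16,32,64,64]}, each a stride-1 3x3 ReLU convolution (the skip
#' tap), a stride-2 3x3 convolution for downsampling and batch
#' normalization; a bottleneck of dropout 0.5, 2x2 max pooling and a double
#' convolution; a decoder that mirrors the encoder with x2 upsampling (2x2
#' convolution after nearest upsampling) and concatenation skips; and a
#' head of one 3x3 two-filter ReLU convolution followed by a 1x1 sigmoid
#' convolution. Output spatial size equals input size.
#'
#' @param side input image side (>= 16).
#' @return A [ModelSpec-class].
#' @export
buildMuNet <- function(side = 250L)
  buildVariant(ablationPreset("Mu-Net"), side, name = "Mu-Net")

# ---- accounting -----------------------------------------------------------

#' Count trainable parameters of a model spec
#'
#' Closed form per layer kind: a \code{k x k} convolution mapping
#' \code{Cin} to \code{Cout} channels has \code{(k^2 Cin + 1) Cout}
#' parameters (weights + biases); batch normalization has \code{2 C}
#' (scale + shift; running moments are not trainable). Other layer kinds
#' have none.
#'
#' @param spec a [ModelSpec-class].
#' @return Integer parameter count.
#' @export
countParameters <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  total <- 0
  for (lay in spec@layers) {
    if (lay$kind == "conv")
      total <- total + (lay$kernel^2 * lay$inChannels + 1) * lay$filters
    else if (lay$kind == "batchnorm")
      total <- total + 2 * lay$channels
  }
  as.integer(total)
}

#' Estimate forward-pass FLOPs of a model spec
#'
#' Convolution multiply-accumulates counted as 2 FLOPs each (the 1 MAC =
#' 2 FLOPs convention), summed over one forward pass:
#' \code{2 k^2 Cin Cout Hout Wout} per convolution. Elementwise and
#' normalization costs are negligible and omitted.
#'
#' @param spec a [ModelSpec-class].
#' @param side optional input side at which to evaluate; defaults to the
#'   side the spec was built at (the spec is rebuilt when they differ).
#' @return FLOPs in MFLOP (millions).
#' @export
estimateFlops <- function(spec, side = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  if (!is.null(side) && as.integer(side) != spec@inputSide)
    spec <- buildVariant(spec@config, as.integer(side), name = spec@name)
  total <- 0
  for (lay in spec@layers) {
    if (lay$kind == "conv") {
      o <- lay$outShape
      total <- total + 2 * lay$kernel^2 * lay$inChannels * lay$filters *
        o[1] * o[2]
    }
  }
  total / 1e6
}

#' Serialize a model spec to a layer table
#'
#' One row per layer with the architecture-table columns (name, kind,
#' filter count, kernel size, stride, activation, output shape).
#'
#' @param spec a [ModelSpec-class].
#' @param path optional CSV path to write the table to.
#' @return A data.frame (invisibly when \code{path} is given).
#' @export
specTable <- function(spec, path = NULL) {
  df <- do.call(rbind, lapply(spec@layers, function(lay) {
    data.frame(name = lay$name, kind = lay$kind,
               filters = lay$filters %||% NA_integer_,
               kernel = lay$kernel %||% NA_integer_,
               stride = lay$stride %||% NA_integer_,
               activation = lay$activation %||% NA_character_,
               outH = lay$outShape[1], outW = lay$outShape[2],
               outC = lay$outShape[3],
               inputs = paste(lay$inputs, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
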
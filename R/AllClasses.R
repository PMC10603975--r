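#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# Core data containers
# ---------------------------------------------------------------------------

#' Grayscale bright-field image
#'
#' A 2-D intensity array holding one grayscale microscopy image. Intensities
#' are always stored on \code{[0, 1]} (rescaled from the source bit depth at
#' load time); the original bit depth is retained for round-trip I/O.
#'
#' @slot pixels numeric matrix (height x width), values in \code{[0, 1]}.
#' @slot bitDepth integer, bit depth of the source data (8 or 16).
#'
#' @seealso [loadImage()], [saveImage()], [preprocessImage()]
#' @export
setClass("OrganoidImage",
  representation(pixels = "matrix", bitDepth = "integer"),
  prototype(bitDepth = 8L),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 8 || ncol(p) < 8) return("image must be at least 8x8")
    if (any(!is.finite(p))) return("all intensities must be finite")
    if (min(p) < 0 || max(p) > 1) return("intensities must lie in [0, 1]")
    if (!object@bitDepth %in% c(1L, 8L, 16L))
      return("bitDepth must be 1, 8 or 16")
    TRUE
  })

#' Binary segmentation mask
#'
#' A 2-D foreground/background labeling aligned with a grayscale image;
#' foreground (1) marks organoid content.
#'
#' @slot labels integer-valued matrix over \{0, 1\}, same shape as its
#'   paired image.
#'
#' @seealso [confusionCounts()], [predictMask()]
#' @export
setClass("OrganoidMask",
  representation(labels = "matrix"),
  validity = function(object) {
    l <- object@labels
    if (!all(l %in% c(0, 1))) return("mask values must be 0 or 1")
    TRUE
  })

#' @rdname OrganoidImage-class
#' @param pixels numeric matrix with values in \code{[0, 1]}.
#' @param bitDepth integer bit depth of the source data.
#' @return An \code{OrganoidImage}.
#' @export
OrganoidImage <- function(pixels, bitDepth = 8L) {
  new("OrganoidImage", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' @rdname OrganoidMask-class
#' @param labels matrix over \{0, 1\}.
#' @return An \code{OrganoidMask}.
#' @export
OrganoidMask <- function(labels) {
  storage.mode(labels) <- "double"
  new("OrganoidMask", labels = labels)
}

#' @describeIn OrganoidImage-class extract the pixel matrix.
#' @param x an \code{OrganoidImage}.
#' @export
pixels <- function(x) {
  if (is(x, "OrganoidImage")) x@pixels
  else if (is.matrix(x)) x
  else stop("cannot extract pixels from a ", class(x)[1])
}

#' @describeIn OrganoidMask-class extract the label matrix.
#' @param x an \code{OrganoidMask}.
#' @export
maskLabels <- function(x) {
  if (is(x, "OrganoidMask")) x@labels
  else if (is.matrix(x)) {
    if (!all(x %in% c(0, 1))) stop("matrix is not binary")
    x
  } else stop("cannot extract labels from a ", class(x)[1])
}

setMethod("dim", "OrganoidImage", function(x) dim(x@pixels))
setMethod("dim", "OrganoidMask", function(x) dim(x@labels))

setMethod("show", "OrganoidImage", function(object) {
  d <- dim(object)
  cat(sprintf("OrganoidImage %dx%d (%d-bit source), range [%.3f, %.3f]\n",
              d[1], d[2], object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "OrganoidMask", function(object) {
  d <- dim(object)
  cat(sprintf("OrganoidMask %dx%d, foreground fraction %.3f\n",
              d[1], d[2], mean(object@labels)))
})

# ---------------------------------------------------------------------------
# Phantom generation parameters
# ---------------------------------------------------------------------------

#' Parameters of the synthetic organoid phantom generator
#'
#' Describes the bright-field-like scenes emulated by [generatePhantom()]:
#' a roundish organoid body (optionally with neuroepithelial bud
#' protrusions) on a brighter textured background surrounded by
#' spreading-cell debris, degraded by photon shot noise.
#'
#' @slot side integer image side in pixels.
#' @slot bodyRadiusRange numeric length-2, body semi-axis range as a
#'   fraction of \code{side}; each value in \code{(0, 0.5]}.
#' @slot nBudsRange integer length-2, range of bud counts.
#' @slot budRadiusFraction numeric length-2, bud radius range as a fraction
#'   of the mean body semi-axis.
#' @slot bodyIntensity,backgroundIntensity numeric in \code{[0, 1]}; the
#'   default renders a dark organoid on a bright background (typical
#'   bright-field polarity); swap the two values to invert the contrast.
#' @slot debrisDensity numeric, expected number of spreading-cell speckles
#'   per image (Poisson).
#' @slot shotNoiseScale numeric, photon-count scale \eqn{\lambda_{max}};
#'   \code{Inf} disables shot noise (the noise-free limit).
#' @slot seed integer master seed; together with the phantom index it fully
#'   determines the output.
#'
#' @export
setClass("PhantomParams",
  representation(side = "integer", bodyRadiusRange = "numeric",
                 nBudsRange = "integer", budRadiusFraction = "numeric",
                 bodyIntensity = "numeric", backgroundIntensity = "numeric",
                 debrisDensity = "numeric", shotNoiseScale = "numeric",
                 seed = "integer"),
  prototype(side = 250L, bodyRadiusRange = c(0.15, 0.35),
            nBudsRange = c(0L, 4L), budRadiusFraction = c(0.25, 0.45),
            bodyIntensity = 0.35, backgroundIntensity = 0.85,
            debrisDensity = 25, shotNoiseScale = 400, seed = 1L),
  validity = function(object) {
    r <- object@bodyRadiusRange
    if (length(r) != 2 || any(r <= 0) || any(r > 0.5) || r[1] > r[2])
      return("bodyRadiusRange must be an increasing pair in (0, 0.5]")
    b <- object@budRadiusFraction
    if (length(b) != 2 || any(b <= 0) || b[1] > b[2])
      return("budRadiusFraction must be a positive increasing pair")
    if (object@side < 16L) return("side must be >= 16")
    n <- object@nBudsRange
    if (length(n) != 2 || any(n < 0) || n[1] > n[2])
      return("nBudsRange must be a non-negative increasing pair")
    ints <- c(object@bodyIntensity, object@backgroundIntensity)
    if (any(ints < 0) || any(ints > 1))
      return("intensities must lie in [0, 1]")
    if (object@debrisDensity < 0) return("debrisDensity must be >= 0")
    if (object@shotNoiseScale <= 0) return("shotNoiseScale must be > 0")
    TRUE
  })

#' @rdname PhantomParams-class
#' @param ... slots to override (see the class documentation for defaults).
#' @return A \code{PhantomParams} object.
#' @export
phantomParams <- function(...) {
  args <- list(...)
  for (nm in c("side", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  if (!is.null(args$nBudsRange)) args$nBudsRange <- as.integer(args$nBudsRange)
  do.call(new, c(list(Class = "PhantomParams"), args))
}

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf(paste0(
    "PhantomParams: side %d, body radius %.2f-%.2f of side, %d-%d buds,\n",
    "  body/background intensity %.2f/%.2f, debris %.0f/image, ",
    "shot-noise scale %s, seed %d\n"),
    object@side, object@bodyRadiusRange[1], object@bodyRadiusRange[2],
    object@nBudsRange[1], object@nBudsRange[2],
    object@bodyIntensity, object@backgroundIntensity, object@debrisDensity,
    format(object@shotNoiseScale), object@seed))
})

# ---------------------------------------------------------------------------
# Augmentation strategy
# ---------------------------------------------------------------------------

#' Data augmentation strategy
#'
#' One of the eleven augmentation groups used by the leave-one-out
#' protocol: \code{classic} (random flip / 90-degree rotation / whitening),
#' four direct noise injections (\code{gaussian}, \code{speckle},
#' \code{salt_pepper}, \code{shot}) and six loss-named groups (\code{bce},
#' \code{bce_l1}, \code{ls}, \code{poisson}, \code{wass}, \code{pwass}).
#' The loss-named groups stand in for images synthesized by adversarial
#' autoencoders trained under those losses in earlier work; here they are
#' emulated as fixed transform-plus-noise recipes and carry
#' \code{emulated = TRUE} so downstream reports can flag them.
#'
#' @slot name character, strategy name.
#' @slot params list of per-strategy settings (noise magnitudes etc.).
#' @slot emulated logical, \code{TRUE} for the six loss-named groups.
#'
#' @seealso [buildGroup()], [strategyNames()]
#' @export
setClass("AugmentationStrategy",
  representation(name = "character", params = "list", emulated = "logical"),
  validity = function(object) {
    if (!object@name %in% strategyNames())
      return(paste("unknown strategy:", object@name))
    TRUE
  })

#' Names of the eleven augmentation strategies
#'
#' @param kind restrict to a subset: all strategies, the six emulated
#'   loss-named groups, the four noise injections, or classic.
#' @return Character vector of strategy names.
#' @export
strategyNames <- function(kind = c("all", "loss", "noise", "classic")) {
  kind <- match.arg(kind)
  loss <- c("bce", "bce_l1", "ls", "poisson", "wass", "pwass")
  noise <- c("gaussian", "speckle", "salt_pepper", "shot")
  switch(kind,
         all = c("classic", noise, loss),
         loss = loss,
         noise = noise,
         classic = "classic")
}

#' @rdname AugmentationStrategy-class
#' @param name strategy name, one of [strategyNames()].
#' @param params optional list of overrides for the strategy's settings.
#' @return An \code{AugmentationStrategy}.
#' @export
augmentationStrategy <- function(name, params = list()) {
  name <- match.arg(name, strategyNames())
  defaults <- switch(name,
    classic = list(),
    gaussian = list(sigma = 0.05),
    speckle = list(sigma = 0.05),
    salt_pepper = list(rate = 0.05),
    shot = list(lambdaMax = 255),
    # Emulated loss-named recipes: a random geometric transform plus a
    # mild strategy-specific noise, distinct per group.
    bce = list(model = "gaussian", sigma = 0.02),
    bce_l1 = list(model = "gaussian", sigma = 0.03),
    ls = list(model = "speckle", sigma = 0.03),
    poisson = list(model = "shot", lambdaMax = 600),
    wass = list(model = "gaussian", sigma = 0.04),
    pwass = list(model = "speckle", sigma = 0.05))
  defaults[names(params)] <- params
  new("AugmentationStrategy", name = name, params = defaults,
      emulated = name %in% strategyNames("loss"))
}

setMethod("show", "AugmentationStrategy", function(object) {
  cat(sprintf("AugmentationStrategy '%s'%s\n", object@name,
              if (object@emulated) " (emulated AAE group)" else ""))
})

# ---------------------------------------------------------------------------
# Architecture description
# ---------------------------------------------------------------------------

#' Ablation configuration: six toggleable architecture components
#'
#' Declarative description of an encoder-decoder variant as six boolean
#' design components applied to the full U-Net:
#' \describe{
#'   \item{layerReduction}{5 resolution levels reduced to 4.}
#'   \item{filterReduction}{filter bank \code{[64,128,256,512,1024]}
#'     reduced to \code{[16,32,64,64]}.}
#'   \item{kernelReduction}{two convolutions per block reduced to one.}
#'   \item{ewiseSkip}{skip connections by element-wise addition instead of
#'     concatenation.}
#'   \item{strideDownsampling}{encoder blocks downsample with a stride-2
#'     convolution (followed by batch normalization) instead of max
#'     pooling only.}
#'   \item{softmaxActivation}{two-channel softmax head instead of the
#'     one-channel sigmoid.}
#' }
#' The named presets (see [ablationPresets()]) map bijectively onto flag
#' combinations; \code{"Unet"} is all flags off, \code{"Mu-Net"} is
#' layer + filter + kernel + stride, and \code{"UNet-Mini"} is all six on.
#'
#' @slot layerReduction,filterReduction,kernelReduction,ewiseSkip,strideDownsampling,softmaxActivation
#'   logical flags.
#' @export
setClass("AblationConfig",
  representation(layerReduction = "logical", filterReduction = "logical",
                 kernelReduction = "logical", ewiseSkip = "logical",
                 strideDownsampling = "logical",
                 softmaxActivation = "logical"),
  prototype(layerReduction = FALSE, filterReduction = FALSE,
            kernelReduction = FALSE, ewiseSkip = FALSE,
            strideDownsampling = FALSE, softmaxActivation = FALSE))

#' @rdname AblationConfig-class
#' @param layerReduction,filterReduction,kernelReduction,ewiseSkip,strideDownsampling,softmaxActivation
#'   logical flags, all default \code{FALSE}.
#' @return An \code{AblationConfig}.
#' @export
ablationConfig <- function(layerReduction = FALSE, filterReduction = FALSE,
                           kernelReduction = FALSE, ewiseSkip = FALSE,
                           strideDownsampling = FALSE,
                           softmaxActivation = FALSE) {
  new("AblationConfig", layerReduction = layerReduction,
      filterReduction = filterReduction, kernelReduction = kernelReduction,
      ewiseSkip = ewiseSkip, strideDownsampling = strideDownsampling,
      softmaxActivation = softmaxActivation)
}

setMethod("show", "AblationConfig", function(object) {
  on <- c("layer", "filter", "kernel", "ewise", "stride", "softmax")[c(
    object@layerReduction, object@filterReduction, object@kernelReduction,
    object@ewiseSkip, object@strideDownsampling, object@softmaxActivation)]
  cat("AblationConfig:",
      if (length(on)) paste(on, collapse = " + ") else "none (full U-Net)",
      "\n")
})

#' Encoder-decoder model specification
#'
#' An ordered, shape-checked list of layer descriptions (convolution,
#' pooling, upsampling, batch normalization, dropout, skip merges) with
#' named tap points referenced by the decoder's skip connections. Built by
#' [buildVariant()] and its preset wrappers; consumed by [trainModel()],
#' [countParameters()] and [estimateFlops()].
#'
#' @slot name character label of the architecture.
#' @slot inputSide integer input image side.
#' @slot layers list of layer descriptions with inferred output shapes.
#' @slot config the [AblationConfig-class] the spec was built from.
#' @export
setClass("ModelSpec",
  representation(name = "character", inputSide = "integer",
                 layers = "list", config = "AblationConfig"))

setMethod("show", "ModelSpec", function(object) {
  out <- object@layers[[length(object@layers)]]$outShape
  cat(sprintf("ModelSpec '%s': input %dx%d, %d layers, output %dx%dx%d, %s parameters\n",
              object@name, object@inputSide, object@inputSide,
              length(object@layers), out[1], out[2], out[3],
              format(countParameters(object), big.mark = ",")))
})

#' Trained segmentation model
#'
#' A [ModelSpec-class] together with learned weights, the training-loss
#' history and the training configuration used.
#'
#' @slot spec the trained [ModelSpec-class].
#' @slot weights list of per-layer parameter arrays.
#' @slot history numeric vector of per-epoch mean training losses.
#' @slot config list snapshot of the [TrainingConfig-class] used.
#' @export
setClass("TrainedModel",
  representation(spec = "ModelSpec", weights = "list",
                 history = "numeric", config = "list"))

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel '%s': %d epochs, final loss %.5f\n",
              object@spec@name, length(object@history),
              utils::tail(object@history, 1)))
})

# ---------------------------------------------------------------------------
# Training configuration
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Optimization settings for [trainModel()]: Adam with binary cross-entropy
#' (two-class cross-entropy for softmax heads), early stopping once the
#' training loss plateaus.
#'
#' @slot learningRate numeric Adam step size (> 0).
#' @slot batchSize integer mini-batch size.
#' @slot maxEpochs integer epoch budget.
#' @slot patience integer, number of consecutive epochs without an
#'   improvement larger than \code{minDelta} before training stops.
#' @slot minDelta numeric minimum loss improvement that resets patience.
#' @slot clipNorm numeric global gradient-norm clip (stabilizes Adam on
#'   very small batches); \code{Inf} disables clipping.
#' @slot seed integer seed for weight init, shuffling and dropout.
#' @export
setClass("TrainingConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 maxEpochs = "integer", patience = "integer",
                 minDelta = "numeric", clipNorm = "numeric",
                 seed = "integer"),
  prototype(learningRate = 1e-3, batchSize = 4L, maxEpochs = 200L,
            patience = 10L, minDelta = 1e-4, clipNorm = 5, seed = 1L),
  validity = function(object) {
    if (object@learningRate < 0) return("learningRate must be >= 0")
    if (object@patience < 1) return("patience must be >= 1")
    if (object@batchSize < 1) return("batchSize must be >= 1")
    TRUE
  })

#' @rdname TrainingConfig-class
#' @param ... slots to override (see the class documentation for defaults).
#' @return A \code{TrainingConfig}.
#' @export
trainingConfig <- function(...) {
  args <- list(...)
  for (nm in c("batchSize", "maxEpochs", "patience", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "TrainingConfig"), args))
}

# ---------------------------------------------------------------------------
# Leave-one-out plan
# ---------------------------------------------------------------------------

#' Leave-one-out experiment plan
#'
#' Enumerates the training launches of the leave-one-out protocol: for each
#' augmentation strategy, one launch per original image in which that image
#' is held out, the remaining originals form the training base, and an
#' augmentation group of \code{groupSize} items is generated from the
#' non-held-out originals only.
#'
#' @slot launches data.frame with columns \code{launchId}, \code{strategy},
#'   \code{heldOutId}, \code{nTrain}.
#' @slot nOriginals integer number of original images.
#' @slot groupSize integer augmented items generated per fold.
#' @seealso [makeLooPlan()], [runLoo()]
#' @export
setClass("LooPlan",
  representation(launches = "data.frame", nOriginals = "integer",
                 groupSize = "integer"))

setMethod("show", "LooPlan", function(object) {
  cat(sprintf("LooPlan: %d originals x %d strategies = %d launches, %d training items per fold\n",
              object@nOriginals,
              length(unique(object@launches$strategy)),
              nrow(object@launches), object@launches$nTrain[1]))
})

#' @describeIn LooPlan-class number of launches in the plan.
#' @param x a \code{LooPlan}.
#' @export
nLaunches <- function(x) nrow(x@launches)

#' @describeIn LooPlan-class the launch table.
#' @export
launches <- function(x) x@launches

# ---------------------------------------------------------------------------
# Evaluation containers
# ---------------------------------------------------------------------------

#' Pixel confusion counts
#'
#' True/false positive/negative pixel tallies between a predicted and a
#' ground-truth mask; all six evaluation metrics derive from these four
#' numbers.
#'
#' @slot tp,fp,tn,fn numeric non-negative pixel counts.
#' @seealso [confusionCounts()], [segMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric",
                 tn = "numeric", fn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(v < 0)) return("counts must be non-negative")
    TRUE
  })

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %.0f, FP %.0f, TN %.0f, FN %.0f (total %.0f)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

#' Segmentation metric set
#'
#' Dice, accuracy, sensitivity, specificity, precision and F1 computed from
#' one [ConfusionCounts-class] object (or aggregated over many). Metrics
#' whose denominator is zero are reported as \code{NA} and listed in
#' \code{undefined}, never silently coerced to 0 or 1.
#'
#' @slot dice,accuracy,sensitivity,specificity,precision,f1 numeric in
#'   \code{[0, 1]} or \code{NA}.
#' @slot undefined character, names of the metrics that were undefined.
#' @slot nExcluded named numeric; when produced by [aggregateMetrics()],
#'   the number of undefined per-image values excluded per metric.
#' @export
setClass("MetricSet",
  representation(dice = "numeric", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 precision = "numeric", f1 = "numeric",
                 undefined = "character", nExcluded = "numeric"),
  prototype(undefined = character(0), nExcluded = numeric(0)),
  validity = function(object) {
    v <- c(object@dice, object@accuracy, object@sensitivity,
           object@specificity, object@precision, object@f1)
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
      return("defined metric values must lie in [0, 1]")
    TRUE
  })

setMethod("show", "MetricSet", function(object) {
  f <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  cat(sprintf(
    "MetricSet: dice %s, acc %s, sens %s, spec %s, prec %s, f1 %s\n",
    f(object@dice), f(object@accuracy), f(object@sensitivity),
    f(object@specificity), f(object@precision), f(object@f1)))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

#' @describeIn MetricSet-class metric values as a named numeric vector.
#' @param x a \code{MetricSet}.
#' @export
metricValues <- function(x) {
  c(dice = x@dice, accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity, precision = x@precision, f1 = x@f1)
}
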
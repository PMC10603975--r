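# Training any ModelSpec with Adam + (binary) cross-entropy, the
# leave-one-out experiment plan, and mask prediction.

#' Train a model specification
#'
#' Optimizes the spec's weights with Adam and binary cross-entropy
#' (two-class cross-entropy for softmax heads) on a set of aligned
#' image/mask pairs, stopping at the configured epoch budget or when the
#' training loss plateaus (no improvement greater than \code{minDelta} for
#' \code{patience} consecutive epochs — see [plateauEpoch()]). Runs are
#' reproducible: weight initialization, shuffling and dropout all derive
#' from \code{config@seed}.
#'
#' @param spec a [ModelSpec-class].
#' @param trainSet non-empty list of entries with \code{image} and
#'   \code{mask} (objects or matrices) at the spec's input side.
#' @param config a [TrainingConfig-class].
#' @param verbose print per-epoch losses.
#' @return A [TrainedModel-class] with the per-epoch loss history.
#' @export
trainModel <- function(spec, trainSet, config = trainingConfig(),
                       verbose = FALSE) {
  stopifnot(is(spec, "ModelSpec"), is(config, "TrainingConfig"))
  if (!length(trainSet)) stop("empty training set")
  xs <- lapply(trainSet, function(e) pixels(e$image))
  ys <- lapply(trainSet, function(e) maskLabels(e$mask))
  side <- spec@inputSide
  for (i in seq_along(xs)) {
    if (!identical(dim(xs[[i]]), c(side, side)) ||
        !identical(dim(ys[[i]]), c(side, side)))
      stop("training item ", i, " does not match the model input side ",
           side)
  }
  withSeed(config@seed, {
    W <- initWeights(spec)
    state <- new.env(parent = emptyenv())
    state$m <- list(); state$v <- list(); state$t <- 0
    history <- numeric(0)
    best <- Inf
    wait <- 0L
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(length(xs))
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        fw <- forwardBatch(spec, W, xs[idx], training = TRUE)
        W <- fw$W
        lg <- lossAndGrad(spec, fw, ys[idx])
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        losses[bi] <- lg$loss
        if (config@learningRate > 0) {
          pg <- backwardBatch(spec, W, fw, lg$dz)
          pg <- clipGradients(pg, config@clipNorm)
          up <- adamStep(W, pg, state, config@learningRate)
          W <- up$W
        }
      }
      history[epoch] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %3d  loss %.6f", epoch, history[epoch]))
      if (history[epoch] < best - config@minDelta) {
        best <- history[epoch]
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config@patience) break
      }
    }
    new("TrainedModel", spec = spec, weights = W, history = history,
        config = list(learningRate = config@learningRate,
                      batchSize = config@batchSize,
                      maxEpochs = config@maxEpochs,
                      patience = config@patience,
                      minDelta = config@minDelta,
                      clipNorm = config@clipNorm, seed = config@seed))
  })
}

#' Early-stopping epoch under the loss-plateau rule
#'
#' Pure replica of the stopping rule used by [trainModel()]: the running
#' best loss improves only when a new loss undercuts it by more than
#' \code{minDelta}; training halts after \code{patience} consecutive
#' non-improving epochs. For a constant loss trace the rule fires at epoch
#' \code{1 + patience}.
#'
#' @param history numeric vector of per-epoch losses.
#' @param patience integer (>= 1).
#' @param minDelta numeric minimum improvement.
#' @return The 1-based index of the epoch after which training stops, or
#'   \code{NA} if the rule never fires within \code{history}.
#' @export
plateauEpoch <- function(history, patience = 10L, minDelta = 1e-4) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(history)) {
    if (history[e] < best - minDelta) {
      best <- history[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

#' Predict the foreground probability map for one image
#'
#' @param model a [TrainedModel-class].
#' @param img an [OrganoidImage-class] or matrix at the model's input side.
#' @return For sigmoid heads a matrix of probabilities; for softmax heads
#'   an H x W x 2 array (background, foreground).
#' @export
predictProbability <- function(model, img) {
  stopifnot(is(model, "TrainedModel"))
  px <- pixels(img)
  side <- model@spec@inputSide
  if (!identical(dim(px), c(side, side)))
    stop("image does not match the model input side ", side)
  fw <- forwardBatch(model@spec, model@weights, list(px), training = FALSE)
  headName <- model@spec@layers[[length(model@spec@layers)]]$name
  p <- get(headName, envir = fw$acts)
  if (dim(p)[3] == 1) p[, , 1, 1] else p[, , , 1]
}

#' Binarize a probability map
#'
#' Sigmoid output (matrix): foreground where \code{p >= threshold}.
#' Softmax output (H x W x 2 array): channel argmax, which for channels
#' \code{(1 - p, p)} coincides with thresholding \code{p} at 0.5.
#'
#' @param p probability matrix or H x W x 2 array.
#' @param threshold decision threshold for sigmoid outputs.
#' @return An [OrganoidMask-class].
#' @export
binarizeProbability <- function(p, threshold = 0.5) {
  m <- if (is.matrix(p)) (p >= threshold) * 1
       else (p[, , 2] >= p[, , 1]) * 1
  OrganoidMask(m)
}

#' Predict a binary mask for one image
#'
#' @inheritParams predictProbability
#' @param threshold decision threshold (sigmoid heads).
#' @return An [OrganoidMask-class].
#' @export
predictMask <- function(model, img, threshold = 0.5) {
  binarizeProbability(predictProbability(model, img), threshold)
}

# ---------------------------------------------------------------------------
# Leave-one-out protocol
# ---------------------------------------------------------------------------

#' Enumerate the leave-one-out training launches
#'
#' One launch per (strategy, held-out original): the training set of each
#' fold is the \code{nOriginals - 1} remaining originals plus
#' \code{groupSize} augmented items generated without the held-out image.
#' With 40 originals and the full eleven strategies this yields 440
#' launches, each training on 79 items.
#'
#' @param nOriginals number of original images (>= 2).
#' @param strategies character vector of strategy names (see
#'   [strategyNames()]).
#' @param groupSize augmented items generated per fold.
#' @return A [LooPlan-class].
#' @export
makeLooPlan <- function(nOriginals, strategies = strategyNames(),
                        groupSize = 40L) {
  if (nOriginals < 2) stop("nOriginals must be >= 2")
  if (!length(strategies)) stop("at least one strategy is required")
  strategies <- vapply(strategies, function(s)
    match.arg(s, strategyNames()), "")
  ids <- sprintf("%03d", seq_len(nOriginals))
  df <- expand.grid(heldOutId = ids, strategy = unname(strategies),
                    stringsAsFactors = FALSE)
  df$nTrain <- (nOriginals - 1L) + as.integer(groupSize)
  df$launchId <- sprintf("%s_holdout%s", df$strategy, df$heldOutId)
  new("LooPlan", launches = df[, c("launchId", "strategy", "heldOutId",
                                   "nTrain")],
      nOriginals = as.integer(nOriginals), groupSize = as.integer(groupSize))
}

#' Assemble the training set and manifest for one fold
#'
#' @param originals dataset list (entries with \code{id}, \code{image},
#'   \code{mask}).
#' @param strategy strategy name for the fold's augmentation group.
#' @param heldOutId id of the held-out original.
#' @param groupSize number of augmented items.
#' @param seed seed for the augmentation group.
#' @return List with \code{items} (training entries) and \code{manifest}
#'   (data.frame of \code{id}, \code{sourceId}, \code{strategy}).
#' @export
foldTrainingSet <- function(originals, strategy, heldOutId, groupSize,
                            seed = 1L) {
  ids <- vapply(originals, `[[`, "", "id")
  if (!heldOutId %in% ids) stop("held-out id ", heldOutId,
                                " not among the originals")
  base <- originals[ids != heldOutId]
  grp <- buildGroup(originals, strategy, groupSize, excludeId = heldOutId,
                    seed = seed)
  items <- c(base, grp)
  manifest <- data.frame(
    id = vapply(items, `[[`, "", "id"),
    sourceId = vapply(items, function(e) e$sourceId %||% e$id, ""),
    strategy = vapply(items, function(e) e$strategy %||% "original", ""),
    stringsAsFactors = FALSE)
  list(items = items, manifest = manifest)
}

#' Run the leave-one-out protocol
#'
#' Executes every launch of a plan: builds the fold's training set
#' (asserting leakage-freedom from its manifest), trains the architecture,
#' segments the held-out original, and scores it against its ground truth.
#' When \code{outDir} is given, each completed launch is written to
#' \code{<manifest-hash>.csv} and skipped on re-runs, making long
#' experiments resumable.
#'
#' @param plan a [LooPlan-class].
#' @param spec a [ModelSpec-class] (or a function \code{(side) -> spec}
#'   applied at the originals' side).
#' @param originals dataset list; every id referenced by the plan must be
#'   present.
#' @param config a [TrainingConfig-class].
#' @param seed master seed for per-fold augmentation groups.
#' @param outDir optional directory for resumable per-launch results.
#' @param verbose print per-launch progress.
#' @return A data.frame with one row per launch: ids, confusion counts and
#'   the six metrics.
#' @export
runLoo <- function(plan, spec, originals, config = trainingConfig(),
                   seed = 1L, outDir = NULL, verbose = FALSE) {
  stopifnot(is(plan, "LooPlan"))
  ids <- vapply(originals, `[[`, "", "id")
  missing <- setdiff(plan@launches$heldOutId, ids)
  if (length(missing))
    stop("launch data missing for held-out id(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(plan@launches))
  for (i in seq_len(nrow(plan@launches))) {
    ln <- plan@launches[i, ]
    fold <- foldTrainingSet(originals, ln$strategy, ln$heldOutId,
                            plan@groupSize, seed = subSeed(seed, i))
    if (any(fold$manifest$sourceId == ln$heldOutId) ||
        any(fold$manifest$id == ln$heldOutId))
      stop("leakage detected in launch ", ln$launchId)
    mhash <- configHash(list(launch = ln$launchId,
                             manifest = fold$manifest,
                             config = as.list(config@seed)))
    cachef <- if (is.null(outDir)) NULL
              else file.path(outDir, paste0(mhash, ".csv"))
    if (!is.null(cachef) && file.exists(cachef)) {
      rows[[i]] <- read.csv(cachef, colClasses = c(heldOutId = "character"))
      next
    }
    model <- trainModel(spec, fold$items, config)
    held <- originals[[which(ids == ln$heldOutId)]]
    pred <- predictMask(model, held$image)
    cc <- confusionCounts(pred, held$mask)
    ms <- segMetrics(cc)
    row <- data.frame(launchId = ln$launchId, strategy = ln$strategy,
                      heldOutId = ln$heldOutId, nTrain = ln$nTrain,
                      epochs = length(model@history),
                      tp = cc@tp, fp = cc@fp, tn = cc@tn, fn = cc@fn,
                      t(metricValues(ms)), stringsAsFactors = FALSE)
    if (!is.null(cachef)) write.csv(row, cachef, row.names = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] %s dice %.3f", i, nrow(plan@launches),
                      ln$launchId, row$dice))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
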
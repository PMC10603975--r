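# Training-time data augmentation: classic geometric/whitening transforms,
# the four direct noise injections, and the per-fold group builder that
# assembles an augmentation group without the held-out original.
#
# All randomness goes through R's global RNG, so any call is reproducible
# under set.seed(); buildGroup() additionally seeds itself from its `seed`
# argument and restores the caller's RNG state.

#' Apply one random classic augmentation to an image/mask pair
#'
#' Picks one transform uniformly among horizontal flip, vertical flip,
#' rotation by 90/180/270 degrees, and whitening. Geometric transforms are
#' applied identically to the mask; whitening (per-image standardization
#' to zero mean/unit variance, affinely rescaled into \code{[0, 1]} around
#' mean 0.5) leaves the mask unchanged. Rotations are restricted to
#' multiples of 90 degrees so the mask needs no interpolation.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param mask the aligned [OrganoidMask-class] or binary matrix.
#' @return List with \code{image}, \code{mask} and the chosen
#'   \code{transform} name.
#' @export
classicAugment <- function(img, mask) {
  px <- pixels(img); lb <- maskLabels(mask)
  if (!identical(dim(px), dim(lb))) stop("image and mask shapes differ")
  tr <- sample(c("hflip", "vflip", "rot90", "rot180", "rot270", "whiten"), 1)
  out <- applyTransform(px, lb, tr)
  list(image = OrganoidImage(out$image), mask = OrganoidMask(out$mask),
       transform = tr)
}

applyTransform <- function(px, lb, tr) {
  geo <- function(f) list(image = f(px), mask = f(lb))
  switch(tr,
    hflip = geo(function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]),
    vflip = geo(function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]),
    rot90 = geo(rotate90),
    rot180 = geo(function(m) rotate90(rotate90(m))),
    rot270 = geo(function(m) rotate90(rotate90(rotate90(m)))),
    whiten = list(image = whitenImage(px), mask = lb),
    stop("unknown transform: ", tr))
}

# counter-clockwise 90-degree rotation of a matrix
rotate90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

#' Per-image whitening
#'
#' Standardizes intensities to zero mean and unit variance, then maps them
#' affinely back into \code{[0, 1]} centered on 0.5 (the largest symmetric
#' scale that fits the range). The output mean is exactly 0.5; a constant
#' image maps to constant 0.5.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @return A matrix in \code{[0, 1]} with mean 0.5.
#' @export
whitenImage <- function(img) {
  px <- pixels(img)
  s <- sd(px)
  if (s < .Machine$double.eps) return(matrix(0.5, nrow(px), ncol(px)))
  z <- (px - mean(px)) / s
  scale <- 0.5 / max(abs(z))
  0.5 + z * scale
}

#' Inject one of four noise models into an image
#'
#' \describe{
#'   \item{gaussian}{\code{x + N(0, sigma^2)}}
#'   \item{speckle}{\code{x * (1 + N(0, sigma^2))} (multiplicative)}
#'   \item{salt_pepper}{each pixel independently replaced with probability
#'     \code{rate} by 0 or 1, equiprobably}
#'   \item{shot}{\code{Poisson(lambdaMax * x) / lambdaMax} (photon noise)}
#' }
#' The output is clipped to \code{[0, 1]}. Noise never alters the paired
#' mask.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param model noise model name.
#' @param sigma standard deviation for gaussian/speckle (>= 0).
#' @param rate replacement probability for salt_pepper, in \code{[0, 1]}.
#' @param lambdaMax photon-count scale for shot noise (> 0).
#' @return An [OrganoidImage-class].
#' @export
injectNoise <- function(img, model = c("gaussian", "speckle", "salt_pepper",
                                       "shot"),
                        sigma = 0.05, rate = 0.05, lambdaMax = 255) {
  model <- match.arg(model)
  px <- pixels(img)
  n <- length(px)
  out <- switch(model,
    gaussian = {
      stopifnot(sigma >= 0)
      if (sigma == 0) px else px + matrix(rnorm(n, 0, sigma), nrow(px))
    },
    speckle = {
      stopifnot(sigma >= 0)
      if (sigma == 0) px else px * (1 + matrix(rnorm(n, 0, sigma), nrow(px)))
    },
    salt_pepper = {
      stopifnot(rate >= 0, rate <= 1)
      sel <- matrix(runif(n) < rate, nrow(px))
      val <- matrix(rbinom(n, 1, 0.5), nrow(px))
      ifelse(sel, val, px)
    },
    shot = {
      stopifnot(lambdaMax > 0)
      matrix(rpois(n, lambdaMax * px) / lambdaMax, nrow(px))
    })
  OrganoidImage(clip01(out),
                bitDepth = if (is(img, "OrganoidImage")) img@bitDepth else 8L)
}

#' Build an augmentation group for one leave-one-out fold
#'
#' Draws \code{size} source originals (with replacement, excluding
#' \code{excludeId} and all its derivatives) and applies the strategy's
#' recipe to each:
#' \itemize{
#'   \item \code{classic}: one random flip/rotation/whitening;
#'   \item the four noise strategies: the corresponding [injectNoise()]
#'     model at the strategy's magnitude;
#'   \item the six loss-named strategies: a random geometric transform plus
#'     a mild strategy-specific noise — emulations of the AAE-generated
#'     groups, flagged \code{emulated = TRUE} in every item.
#' }
#' Every item records its source original id, so leakage-freedom of a fold
#' is assertable from the manifest alone.
#'
#' @param originals dataset list (entries with \code{id}, \code{image},
#'   \code{mask}), e.g. from [generateDataset()].
#' @param strategy an [AugmentationStrategy-class] or strategy name.
#' @param size number of augmented pairs to produce (>= 1).
#' @param excludeId id of the held-out original, or \code{NULL}.
#' @param seed integer seed; the group is deterministic in
#'   \code{(originals, strategy, size, excludeId, seed)}.
#' @return List of items with \code{id}, \code{image}, \code{mask},
#'   \code{sourceId}, \code{strategy}, \code{emulated}.
#' @export
buildGroup <- function(originals, strategy, size, excludeId = NULL,
                       seed = 1L) {
  if (size < 1) stop("size must be >= 1")
  if (is.character(strategy)) strategy <- augmentationStrategy(strategy)
  ids <- vapply(originals, `[[`, "", "id")
  keep <- if (is.null(excludeId)) seq_along(ids) else which(ids != excludeId)
  if (!length(keep)) stop("all originals excluded: no source images left")
  sidx <- match(strategy@name, strategyNames())
  withSeed(subSeed(seed, sidx * 100003), {
    lapply(seq_len(size), function(i) {
      src <- keep[sample.int(length(keep), 1)]
      e <- originals[[src]]
      item <- applyStrategy(e$image, e$mask, strategy)
      list(id = sprintf("%s_%03d", strategy@name, i),
           image = item$image, mask = item$mask,
           sourceId = e$id, strategy = strategy@name,
           emulated = strategy@emulated)
    })
  })
}

applyStrategy <- function(img, mask, strategy) {
  p <- strategy@params
  if (strategy@name == "classic") {
    classicAugment(img, mask)
  } else if (strategy@name %in% strategyNames("noise")) {
    list(image = do.call(injectNoise, c(list(img = img, model = strategy@name),
                                        p)),
         mask = asMaskObject(mask))
  } else {
    # emulated AAE loss group: random geometric transform + mild noise
    tr <- sample(c("hflip", "vflip", "rot90", "rot180", "rot270"), 1)
    out <- applyTransform(pixels(img), maskLabels(mask), tr)
    model <- p$model
    noiseArgs <- p[setdiff(names(p), "model")]
    list(image = do.call(injectNoise,
                         c(list(img = out$image, model = model), noiseArgs)),
         mask = OrganoidMask(out$mask))
  }
}

asMaskObject <- function(mask) {
  if (is(mask, "OrganoidMask")) mask else OrganoidMask(mask)
}
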
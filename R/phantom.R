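# Synthetic bright-field organoid phantoms with paired ground-truth masks.
#
# The generator emulates the statistical structure of small bright-field
# brain-organoid datasets: a dark roundish organoid body with a darker rim,
# optional neuroepithelial bud protrusions that make the outline
# non-spherical, a bright textured background scattered with spreading-cell
# debris speckles (placed OUTSIDE the ground-truth mask, the classic source
# of false positives), and photon shot noise
# (pixel ~ Poisson(lambda_max * clean) / lambda_max).

#' Generate one organoid phantom and its ground-truth mask
#'
#' Deterministic in \code{(params, index)}: the pair is rendered under a
#' sub-seed derived from \code{params@seed} and \code{index}, so the same
#' inputs always give bit-identical outputs.
#'
#' @param params a [PhantomParams-class].
#' @param index integer phantom index (>= 1).
#' @return A list with elements \code{image} ([OrganoidImage-class]),
#'   \code{mask} ([OrganoidMask-class]), \code{id} and \code{seed}.
#' @examples
#' p <- phantomParams(side = 64L, seed = 7L)
#' ph <- generatePhantom(p, 1)
#' @export
generatePhantom <- function(params, index = 1L) {
  stopifnot(is(params, "PhantomParams"))
  validObject(params)
  s <- subSeed(params@seed, index)
  out <- withSeed(s, renderPhantom(params))
  out$id <- sprintf("%03d", as.integer(index))
  out$seed <- s
  out
}

renderPhantom <- function(params) {
  side <- params@side
  xs <- matrix(rep(seq_len(side), each = side), side, side)   # column index
  ys <- matrix(rep(seq_len(side), times = side), side, side)  # row index

  # Organoid body: rotated ellipse jittered around the image center.
  cx <- side / 2 + runif(1, -0.1, 0.1) * side
  cy <- side / 2 + runif(1, -0.1, 0.1) * side
  a <- runif(1, params@bodyRadiusRange[1], params@bodyRadiusRange[2]) * side
  b <- runif(1, params@bodyRadiusRange[1], params@bodyRadiusRange[2]) * side
  th <- runif(1, 0, pi)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  mask <- (u / a)^2 + (v / b)^2 <= 1

  # Neuroepithelial buds: disks centered on the body boundary so each
  # protrudes from (and overlaps) the body.
  nb <- if (params@nBudsRange[1] == params@nBudsRange[2]) params@nBudsRange[1]
        else sample(seq(params@nBudsRange[1], params@nBudsRange[2]), 1)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      phi <- runif(1, 0, 2 * pi)
      # boundary point of the rotated ellipse at parameter phi
      bx <- cx + a * cos(phi) * cos(th) - b * sin(phi) * sin(th)
      by <- cy + a * cos(phi) * sin(th) + b * sin(phi) * cos(th)
      rb <- runif(1, params@budRadiusFraction[1],
                  params@budRadiusFraction[2]) * mean(c(a, b))
      mask <- mask | ((xs - bx)^2 + (ys - by)^2 <= rb^2)
    }
  }
  if (!any(mask)) stop("degenerate phantom: empty mask")

  # Piecewise-constant clean scene: bright background, dark body, darker
  # rim just inside the boundary, then Gaussian smoothing.
  bg <- params@backgroundIntensity
  body <- params@bodyIntensity
  clean <- matrix(bg, side, side)
  clean[mask] <- body
  rimw <- max(2L, round(side / 60))
  eroded <- EBImage::erode(mask * 1, EBImage::makeBrush(2L * rimw + 1L,
                                                       shape = "disc"))
  rim <- mask & !(eroded > 0.5)
  clean[rim] <- body * 0.6
  # mild background texture
  tex <- matrix(rnorm(side * side, 0, 0.05), side, side)
  tex <- as.matrix(EBImage::gblur(tex, sigma = max(2, side / 50)))
  clean <- clean + tex * (!mask)
  clean <- as.matrix(EBImage::gblur(clean, sigma = max(1, side / 120)))

  # Spreading-cell debris: small dark Gaussian blobs outside the mask.
  ndeb <- rpois(1, params@debrisDensity)
  if (ndeb > 0) {
    outside <- which(!mask)
    if (length(outside)) {
      centers <- sample(outside, min(ndeb, length(outside)))
      deb <- matrix(0, side, side)
      for (ctr in centers) {
        r0 <- ((ctr - 1) %% side) + 1
        c0 <- ((ctr - 1) %/% side) + 1
        sg <- runif(1, 1, max(1.5, side / 100))
        amp <- runif(1, 0.15, 0.35)
        w <- ceiling(3 * sg)
        rr <- max(1, r0 - w):min(side, r0 + w)
        cc <- max(1, c0 - w):min(side, c0 + w)
        g <- outer(rr - r0, cc - c0,
                   function(i, j) exp(-(i^2 + j^2) / (2 * sg^2)))
        deb[rr, cc] <- pmax(deb[rr, cc], amp * g)
      }
      deb[mask] <- 0
      clean <- clean - deb
    }
  }
  clean <- clip01(clean)

  # Photon shot noise at scale lambda_max; Inf gives the noise-free limit.
  img <- if (is.finite(params@shotNoiseScale)) {
    lam <- params@shotNoiseScale
    clip01(matrix(rpois(side * side, lam * clean) / lam, side, side))
  } else clean

  list(image = OrganoidImage(img), mask = OrganoidMask(mask * 1))
}

#' Generate a dataset of organoid phantoms
#'
#' Produces \code{n} image/mask pairs with stable identifiers
#' (\code{"001"}, \code{"002"}, ...) and index-derived sub-seeds, so the
#' same \code{(n, params)} always reproduces the same dataset.
#'
#' @param n number of phantoms (>= 1).
#' @param params a [PhantomParams-class].
#' @return A list of phantom entries as returned by [generatePhantom()].
#' @export
generateDataset <- function(n, params = phantomParams()) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) generatePhantom(params, i))
}

#' Write a phantom (or augmented) dataset to disk
#'
#' Lays the dataset out as \code{images/NNN.png} and \code{masks/NNN.png}
#' plus a \code{manifest.csv} with columns \code{id}, \code{seed} (when
#' present), \code{sourceId}/\code{strategy} (for augmented items) and the
#' parameter hash.
#'
#' @param dataset list of entries with \code{id}, \code{image}, \code{mask}.
#' @param dir output directory (created if missing).
#' @param params optional [PhantomParams-class] whose hash is recorded.
#' @return Invisibly, the manifest data.frame.
#' @export
writeDataset <- function(dataset, dir, params = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  phash <- if (is.null(params)) NA_character_ else
    configHash(paramsAsList(params))
  man <- do.call(rbind, lapply(dataset, function(e) {
    saveImage(e$image, file.path(dir, "images", paste0(e$id, ".png")))
    saveImage(e$mask, file.path(dir, "masks", paste0(e$id, ".png")))
    data.frame(id = e$id, seed = e$seed %||% NA_integer_,
               sourceId = e$sourceId %||% e$id,
               strategy = e$strategy %||% "original",
               emulated = isTRUE(e$emulated),
               paramsHash = phash, stringsAsFactors = FALSE)
  }))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory containing \code{images/}, \code{masks/}
#'   and \code{manifest.csv}.
#' @return A list of entries with \code{id}, \code{image}, \code{mask} and
#'   the manifest columns.
#' @export
readDataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"),
                  colClasses = c(id = "character"))
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$id[i]
    list(id = id,
         image = loadImage(file.path(dir, "images", paste0(id, ".png"))),
         mask = loadMask(file.path(dir, "masks", paste0(id, ".png"))),
         sourceId = man$sourceId[i], strategy = man$strategy[i],
         emulated = man$emulated[i])
  })
}

paramsAsList <- function(params) {
  nms <- slotNames(class(params))
  setNames(lapply(nms, function(n) slot(params, n)), nms)
}
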
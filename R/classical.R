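# Classical (non-learned) segmentation baselines: fixed/Otsu thresholding,
# region growing, PSO-initialised k-means, Chan-Vese-style active contour
# and marker-based watershed. All operate on [0,1] grayscale images and
# share the global foreground-polarity convention (default: dark organoid
# on a bright background, matching the phantom generator).

#' Threshold segmentation
#'
#' Fixed intensity threshold (given on the 0-255 scale and converted to
#' the internal \code{[0, 1]} scale, default 185) or Otsu's method.
#' With dark-foreground polarity a pixel is foreground when its intensity
#' is at most the threshold.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param threshold numeric threshold on the 0-255 scale, or \code{"otsu"}.
#' @param polarity \code{"dark"} (default) or \code{"bright"} foreground.
#' @param largestComponent keep only the largest connected foreground
#'   component.
#' @return An [OrganoidMask-class].
#' @export
thresholdSegment <- function(img, threshold = 185, polarity = c("dark",
                                                                "bright"),
                             largestComponent = FALSE) {
  polarity <- match.arg(polarity)
  px <- pixels(img)
  t01 <- if (identical(threshold, "otsu")) {
    if (sd(px) < .Machine$double.eps)
      stop("degenerate histogram: constant image has no Otsu threshold")
    EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  } else as.numeric(threshold) / 255
  m <- if (polarity == "dark") (px <= t01) * 1 else (px >= t01) * 1
  if (largestComponent && any(m > 0)) m <- keepLargestComponent(m)
  OrganoidMask(m)
}

keepLargestComponent <- function(m) {
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  (lab == which.max(tab)) * 1
}

#' Region-growing segmentation
#'
#' Flood fill from seed pixels: at each step the region frontier is
#' dilated by \code{growthSize} pixels and frontier pixels whose intensity
#' differs from the running region mean by at most
#' \code{regionalThreshold} are absorbed; iteration stops when no pixel is
#' accepted. Deterministic given the seeds.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param seeds two-column matrix of (row, col) seed positions; by default
#'   the image center plus the global extremum of the foreground polarity.
#' @param regionalThreshold maximum absolute intensity deviation from the
#'   running region mean (default 0.2).
#' @param growthSize frontier dilation radius in pixels (default 1).
#' @param polarity \code{"dark"} or \code{"bright"} foreground (used only
#'   for the default seed).
#' @return An [OrganoidMask-class].
#' @export
regionGrowing <- function(img, seeds = NULL, regionalThreshold = 0.2,
                          growthSize = 1L, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  px <- pixels(img)
  h <- nrow(px); w <- ncol(px)
  if (is.null(seeds)) {
    ext <- if (polarity == "dark") which.min(px) else which.max(px)
    seeds <- rbind(c(round(h / 2), round(w / 2)),
                   c((ext - 1) %% h + 1, (ext - 1) %/% h + 1))
  }
  seeds <- matrix(as.integer(seeds), ncol = 2)
  if (any(seeds[, 1] < 1 | seeds[, 1] > h | seeds[, 2] < 1 | seeds[, 2] > w))
    stop("seed outside image bounds")
  region <- matrix(FALSE, h, w)
  region[cbind(seeds[, 1], seeds[, 2])] <- TRUE
  brush <- EBImage::makeBrush(2L * as.integer(growthSize) + 1L,
                              shape = "box")
  repeat {
    frontier <- (EBImage::dilate(region * 1, brush) > 0.5) & !region
    if (!any(frontier)) break
    mu <- mean(px[region])
    accept <- frontier & (abs(px - mu) <= regionalThreshold)
    if (!any(accept)) break
    region <- region | accept
  }
  OrganoidMask(region * 1)
}

#' k-means segmentation with particle-swarm-optimised centroids
#'
#' Clusters pixel intensities into \code{k} groups. Centroid positions are
#' first refined by a global-best particle swarm minimising the
#' within-cluster sum of squares (one deterministic quantile-initialised
#' particle plus random ones), then polished by [stats::kmeans()] started
#' from the swarm's best position. Foreground is the cluster whose center
#' matches the configured polarity (dark: lowest center).
#'
#' With \code{nParticles = 1, iterations = 0} the swarm is degenerate and
#' the result equals plain k-means from the quantile initialisation.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param k number of clusters (>= 2; default 2, background vs organoid).
#' @param nParticles swarm size.
#' @param iterations PSO iterations.
#' @param inertia,cognitive,social standard PSO weights.
#' @param polarity \code{"dark"} or \code{"bright"} foreground.
#' @param seed integer seed for the swarm.
#' @param details if \code{TRUE}, also return the global-best objective
#'   trace and final centers.
#' @return An [OrganoidMask-class], or a list
#'   \code{(mask, objective, centers)} when \code{details = TRUE}.
#' @export
kmeansPsoSegment <- function(img, k = 2L, nParticles = 10L,
                             iterations = 20L, inertia = 0.7,
                             cognitive = 1.5, social = 1.5,
                             polarity = c("dark", "bright"), seed = 1L,
                             details = FALSE) {
  polarity <- match.arg(polarity)
  if (k < 2) stop("k must be >= 2")
  px <- pixels(img)
  if (sd(px) < .Machine$double.eps)
    stop("degenerate clustering: constant image")
  x <- as.vector(px)
  sse <- function(centers) {
    dmat <- abs(outer(x, centers, "-"))
    sum(apply(dmat, 1, min)^2)
  }
  res <- withSeed(seed, {
    # particle 1: deterministic quantile init; others: sorted uniforms
    pos <- matrix(0, nParticles, k)
    pos[1, ] <- as.numeric(quantile(x, (2 * seq_len(k) - 1) / (2 * k)))
    if (nParticles > 1)
      for (i in 2:nParticles) pos[i, ] <- sort(runif(k))
    vel <- matrix(0, nParticles, k)
    pbest <- pos
    pbestVal <- apply(pos, 1, sse)
    gbestIdx <- which.min(pbestVal)
    gbest <- pbest[gbestIdx, ]
    gbestVal <- pbestVal[gbestIdx]
    trace <- gbestVal
    it <- 0L
    while (it < iterations) {
      it <- it + 1L
      r1 <- matrix(runif(nParticles * k), nParticles, k)
      r2 <- matrix(runif(nParticles * k), nParticles, k)
      vel <- inertia * vel + cognitive * r1 * (pbest - pos) +
        social * r2 * matrix(gbest, nParticles, k, byrow = TRUE) -
        social * r2 * pos
      pos <- pmin(pmax(pos + vel, 0), 1)
      val <- apply(pos, 1, sse)
      imp <- val < pbestVal
      pbest[imp, ] <- pos[imp, ]
      pbestVal[imp] <- val[imp]
      if (min(pbestVal) < gbestVal) {
        gbestVal <- min(pbestVal)
        gbest <- pbest[which.min(pbestVal), ]
      }
      trace <- c(trace, gbestVal)
    }
    list(gbest = gbest, trace = trace)
  })
  centers <- sort(res$gbest)
  # guard against coincident centers before the k-means polish
  for (i in 2:k)
    if (centers[i] - centers[i - 1] < 1e-9)
      centers[i] <- centers[i - 1] + 1e-6
  km <- kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 100)
  fg <- if (polarity == "dark") which.min(km$centers)
        else which.max(km$centers)
  m <- matrix((km$cluster == fg) * 1, nrow(px), ncol(px))
  mask <- OrganoidMask(m)
  if (details)
    list(mask = mask, objective = res$trace,
         centers = as.numeric(km$centers))
  else mask
}

#' Region-based active contour (Chan-Vese-style)
#'
#' Evolves a level-set contour for a fixed iteration budget under the
#' two-phase piecewise-constant region energy: the front moves to separate
#' the image into two regions of homogeneous mean intensity, with Gaussian
#' smoothing of the level-set function as curvature regularisation. The
#' image is min-max normalised internally, so the result is invariant to
#' positive intensity gain. With \code{iterations = 0} the initialisation
#' mask is returned unchanged.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param init optional initial [OrganoidMask-class]/binary matrix; default
#'   is a centered circle of radius \code{side / 3}.
#' @param iterations evolution steps (default 200).
#' @param lambda1,lambda2 inside/outside energy weights.
#' @param dt time step.
#' @param smoothSigma level-set smoothing applied every 5 iterations.
#' @return An [OrganoidMask-class].
#' @export
activeContourSegment <- function(img, init = NULL, iterations = 200L,
                                 lambda1 = 1, lambda2 = 1, dt = 0.5,
                                 smoothSigma = 1) {
  px <- pixels(img)
  h <- nrow(px); w <- ncol(px)
  if (is.null(init)) {
    r <- min(h, w) / 3
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    init <- ((ys - h / 2)^2 + (xs - w / 2)^2 <= r^2) * 1
  } else init <- maskLabels(init)
  if (!any(init > 0)) stop("empty initialization mask")
  if (iterations == 0) return(OrganoidMask(init))
  rng <- range(px)
  u <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  phi <- ifelse(init > 0, 1, -1)
  phi <- as.matrix(EBImage::gblur(phi, sigma = 2))
  eps <- 1
  for (it in seq_len(iterations)) {
    inside <- phi > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(u[inside])
    c2 <- mean(u[!inside])
    force <- lambda2 * (u - c2)^2 - lambda1 * (u - c1)^2
    delta <- eps / (pi * (eps^2 + phi^2))
    phi <- phi + dt * delta * force
    if (it %% 5 == 0 && smoothSigma > 0)
      phi <- as.matrix(EBImage::gblur(phi, sigma = smoothSigma))
  }
  OrganoidMask((phi > 0) * 1)
}

#' Marker-based watershed segmentation
#'
#' Floods the gradient-magnitude landscape from two marker sets — interior
#' markers at strong foreground-polarity extrema (intensities beyond
#' \code{markerQuantile}) and exterior markers on the image border — and
#' returns the union of the interior-marker basins. The interior and
#' exterior basins tile the whole image.
#'
#' @param img an [OrganoidImage-class] or matrix.
#' @param polarity \code{"dark"} or \code{"bright"} foreground.
#' @param markerQuantile intensity quantile defining interior markers
#'   (default 0.02).
#' @param smoothSigma Gaussian presmoothing of the image before the
#'   gradient (default 2).
#' @param details if \code{TRUE}, also return the full basin label image.
#' @return An [OrganoidMask-class], or \code{(mask, basins)} when
#'   \code{details = TRUE}.
#' @export
watershedSegment <- function(img, polarity = c("dark", "bright"),
                             markerQuantile = 0.02, smoothSigma = 2,
                             details = FALSE) {
  polarity <- match.arg(polarity)
  px <- pixels(img)
  h <- nrow(px); w <- ncol(px)
  sm <- as.matrix(EBImage::gblur(px, sigma = smoothSigma))
  gx <- cbind(sm[, 2] - sm[, 1], (sm[, -(1:2), drop = FALSE] -
              sm[, seq_len(w - 2), drop = FALSE]) / 2, sm[, w] - sm[, w - 1])
  gy <- rbind(sm[2, ] - sm[1, ], (sm[-(1:2), , drop = FALSE] -
              sm[seq_len(h - 2), , drop = FALSE]) / 2, sm[h, ] - sm[h - 1, ])
  grad <- sqrt(gx^2 + gy^2)
  q <- quantile(sm, if (polarity == "dark") markerQuantile
                    else 1 - markerQuantile)
  interior <- if (polarity == "dark") sm <= q else sm >= q
  seeds <- matrix(0L, h, w)
  seeds[interior] <- 2L
  seeds[1, ] <- 1L; seeds[h, ] <- 1L; seeds[, 1] <- 1L; seeds[, w] <- 1L
  if (!any(seeds == 2L)) stop("no interior marker found")
  basins <- EBImage::propagate(EBImage::Image(grad),
                               seeds = EBImage::Image(seeds),
                               lambda = 1e-4)
  lab <- matrix(EBImage::imageData(basins), h, w)
  mask <- OrganoidMask((lab == 2) * 1)
  if (details) list(mask = mask, basins = lab) else mask
}
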
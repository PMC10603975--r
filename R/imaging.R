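# Image/mask file I/O and the crop-resize preprocessing that maps raw
# acquisitions (e.g. 1088x1388 bright-field frames) to square network
# inputs. PNG and TIFF, 8- and 16-bit grayscale; multi-channel inputs are
# collapsed by luminance average. All intensities live on [0, 1] internally.

#' Load a grayscale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit PNG/TIFF, rescales intensities to \code{[0, 1]} by
#' dividing by the bit-depth maximum, and collapses multi-channel inputs by
#' averaging the channels (luminance average).
#'
#' @param path path to an existing PNG or TIFF file.
#' @return An [OrganoidImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' saveImage(OrganoidImage(matrix(runif(64), 8, 8)), f)
#' img <- loadImage(f)
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  res <- if (ext %in% c("tif", "tiff")) {
    tryCatch(tiff::readTIFF(path, info = TRUE),
             error = function(e) stop("not a readable TIFF: ", path))
  } else {
    tryCatch(png::readPNG(path, info = TRUE),
             error = function(e) stop("not a readable PNG: ", path))
  }
  info <- attr(res, "info")
  bits <- if (!is.null(info$bit.depth)) info$bit.depth
          else if (!is.null(attr(res, "bits.per.sample")))
            attr(res, "bits.per.sample")
          else 8L
  px <- unclass(res)
  attributes(px) <- list(dim = dim(res))
  if (length(dim(px)) == 3) {
    nc <- dim(px)[3]
    if (nc == 4) nc <- 3  # drop alpha from the luminance average
    px <- apply(px[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  OrganoidImage(clip01(px), bitDepth = as.integer(bits[1]))
}

#' Save an image, mask or RGB overlay as lossless PNG
#'
#' Images and overlays are written at their source bit depth (8-bit
#' default); masks are encoded as 0/255 8-bit PNG so that
#' \code{loadImage(path)} recovers the mask after dividing by 255.
#'
#' @param x an [OrganoidImage-class], [OrganoidMask-class], numeric matrix
#'   in \code{[0, 1]}, or an H x W x 3 RGB array (overlay).
#' @param path output path; the parent directory must exist.
#' @return Invisibly, \code{path}.
#' @export
saveImage <- function(x, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  if (is(x, "OrganoidMask")) {
    arr <- x@labels  # writePNG maps 1 -> 255 in 8-bit output
  } else if (is(x, "OrganoidImage")) {
    arr <- x@pixels
  } else if (is.array(x) || is.matrix(x)) {
    arr <- x
  } else stop("cannot save a ", class(x)[1])
  if (min(arr) < 0 || max(arr) > 1) stop("pixel values must lie in [0, 1]")
  ok <- tryCatch({png::writePNG(arr, target = path); TRUE},
                 error = function(e) stop("could not write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Load a binary mask stored as 0/255 PNG
#'
#' @param path path to the mask PNG.
#' @param threshold values strictly above this (on \code{[0, 1]}) become
#'   foreground.
#' @return An [OrganoidMask-class].
#' @export
loadMask <- function(path, threshold = 0.5) {
  img <- loadImage(path)
  OrganoidMask((img@pixels > threshold) * 1)
}

#' Crop and resize an image to a square network input
#'
#' Center-crops to the largest inscribed square (preserving the original
#' proportions) and resizes to \code{side} pixels with bilinear
#' interpolation. A \code{side} x \code{side} input is returned unchanged.
#'
#' @param img an [OrganoidImage-class] (or numeric matrix).
#' @param side target side in pixels (>= 8), default 250.
#' @return An [OrganoidImage-class] of shape \code{side} x \code{side}.
#' @export
preprocessImage <- function(img, side = 250L) {
  if (side < 8) stop("side must be >= 8")
  px <- pixels(img)
  sq <- cropSquare(px)
  if (nrow(sq) != side)
    sq <- clip01(as.matrix(EBImage::resize(sq, w = side, h = side,
                                           filter = "bilinear")))
  OrganoidImage(sq, bitDepth = if (is(img, "OrganoidImage")) img@bitDepth
                               else 8L)
}

#' Crop and resize a mask to match a preprocessed image
#'
#' Uses nearest-neighbor resampling and re-thresholds at 0.5 so the result
#' stays strictly binary.
#'
#' @param mask an [OrganoidMask-class] (or binary matrix).
#' @param side target side in pixels, default 250.
#' @return An [OrganoidMask-class] of shape \code{side} x \code{side}.
#' @export
preprocessMask <- function(mask, side = 250L) {
  if (side < 8) stop("side must be >= 8")
  lb <- maskLabels(mask)
  sq <- cropSquare(lb)
  if (nrow(sq) != side)
    sq <- (as.matrix(EBImage::resize(sq, w = side, h = side,
                                     filter = "none")) > 0.5) * 1
  OrganoidMask(sq)
}

# Center crop to the largest inscribed square.
cropSquare <- function(m) {
  h <- nrow(m); w <- ncol(m)
  s <- min(h, w)
  ro <- (h - s) %/% 2
  co <- (w - s) %/% 2
  m[ro + seq_len(s), co + seq_len(s), drop = FALSE]
}
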
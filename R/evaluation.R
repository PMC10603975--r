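# Confusion-matrix evaluation: pixel tallies, the six derived metrics,
# aggregation across images, FP/FN overlay rendering, and the tabular
# reports (architecture x strategy grids and the methods-comparison
# table).

#' Pixel confusion counts between predicted and ground-truth masks
#'
#' @param pred predicted [OrganoidMask-class] (or binary matrix).
#' @param gt ground-truth [OrganoidMask-class] (or binary matrix).
#' @return A [ConfusionCounts-class]; the four counts always sum to the
#'   pixel count.
#' @export
confusionCounts <- function(pred, gt) {
  p <- maskLabels(pred); g <- maskLabels(gt)
  if (!identical(dim(p), dim(g)))
    stop("prediction and ground truth shapes differ")
  new("ConfusionCounts",
      tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
      tn = sum(p == 0 & g == 0), fn = sum(p == 0 & g == 1))
}

#' Segmentation metrics from confusion counts
#'
#' Closed forms:
#' \deqn{Dice = 2TP / (2TP + FP + FN)}
#' \deqn{Accuracy = (TP + TN) / (TP + FP + TN + FN)}
#' \deqn{Sensitivity = TP / (TP + FN)}
#' \deqn{Specificity = TN / (TN + FP)}
#' \deqn{Precision = TP / (TP + FP)}
#' \deqn{F1 = 2 \cdot Precision \cdot Sensitivity / (Precision + Sensitivity)}
#' F1 and Dice are algebraically identical when computed from one counts
#' object (F1 takes the conventional value 0 when precision and
#' sensitivity are both 0). Ratios with a zero denominator are reported as
#' \code{NA} and listed in the \code{undefined} slot, never silently
#' coerced.
#'
#' @param counts a [ConfusionCounts-class].
#' @return A [MetricSet-class].
#' @export
segMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      NA_real_
    } else num / den
  }
  dice <- ratio(2 * tp, 2 * tp + fp + fn, "dice")
  acc <- ratio(tp + tn, tp + fp + tn + fn, "accuracy")
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens)) {
    undef <- c(undef, "f1")
    NA_real_
  } else if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  new("MetricSet", dice = dice, accuracy = acc, sensitivity = sens,
      specificity = spec, precision = prec, f1 = f1, undefined = undef)
}

#' Pool confusion counts across images
#'
#' Sums the four tallies, the "pooled" computation route (as opposed to
#' aggregating per-image metric values). The two routes can disagree;
#' reports produced by this package always label which one they used.
#'
#' @param countsList list of [ConfusionCounts-class] objects.
#' @return A [ConfusionCounts-class].
#' @export
poolCounts <- function(countsList) {
  stopifnot(length(countsList) >= 1)
  new("ConfusionCounts",
      tp = sum(vapply(countsList, slot, 0, "tp")),
      fp = sum(vapply(countsList, slot, 0, "fp")),
      tn = sum(vapply(countsList, slot, 0, "tn")),
      fn = sum(vapply(countsList, slot, 0, "fn")))
}

#' Aggregate per-image metric sets
#'
#' Componentwise median (default, as used by the per-strategy score
#' tables) or mean. Undefined (\code{NA}) entries are excluded and their
#' count reported in the \code{nExcluded} slot.
#'
#' @param metricsList non-empty list of [MetricSet-class] objects.
#' @param method \code{"median"} or \code{"mean"}.
#' @return A [MetricSet-class].
#' @export
aggregateMetrics <- function(metricsList, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!length(metricsList)) stop("empty metrics list")
  vals <- vapply(metricsList, metricValues,
                 numeric(6))  # 6 x n matrix
  agg <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_
    else if (method == "median") median(v) else mean(v)
  })
  nex <- rowSums(is.na(vals))
  undef <- names(agg)[is.na(agg)]
  new("MetricSet", dice = agg[["dice"]], accuracy = agg[["accuracy"]],
      sensitivity = agg[["sensitivity"]],
      specificity = agg[["specificity"]], precision = agg[["precision"]],
      f1 = agg[["f1"]], undefined = undef,
      nExcluded = nex[nex > 0])
}

#' Render a false-positive / false-negative overlay
#'
#' True positives are white, true negatives black (or the dimmed source
#' image when one is supplied); false positives and false negatives are
#' painted in the palette's two accent colors — \code{"pink_green"}
#' (light pink FP, light green FN, the default) or \code{"purple_cyan"}.
#'
#' @param gt ground-truth mask.
#' @param pred predicted mask.
#' @param img optional [OrganoidImage-class] shown dimmed under the true
#'   negatives.
#' @param palette accent palette name.
#' @return An H x W x 3 RGB array in \code{[0, 1]} (writable with
#'   [saveImage()]).
#' @export
overlayMask <- function(gt, pred, img = NULL,
                        palette = c("pink_green", "purple_cyan")) {
  palette <- match.arg(palette)
  g <- maskLabels(gt); p <- maskLabels(pred)
  if (!identical(dim(g), dim(p))) stop("mask shapes differ")
  cols <- switch(palette,
    pink_green = list(fp = c(1, 0.71, 0.76), fn = c(0.56, 0.93, 0.56)),
    purple_cyan = list(fp = c(0.63, 0.13, 0.94), fn = c(0, 0.8, 0.8)))
  base <- if (is.null(img)) matrix(0, nrow(g), ncol(g))
          else pixels(img) * 0.5
  out <- array(rep(base, 3), c(dim(g), 3))
  tpx <- p == 1 & g == 1
  fpx <- p == 1 & g == 0
  fnx <- p == 0 & g == 1
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[tpx] <- 1
    plane[fpx] <- cols$fp[ch]
    plane[fnx] <- cols$fn[ch]
    out[, , ch] <- plane
  }
  out
}

#' Architecture-by-strategy results grid
#'
#' Aggregates fold results into the per-strategy score table: one row per
#' architecture (or ablation preset), one column per strategy, with the
#' best value per row flagged (ties: all tied entries flagged).
#'
#' @param foldResults data.frame as returned by [runLoo()]; an
#'   \code{arch} column identifies the architecture (added automatically
#'   as \code{"model"} when absent).
#' @param value metric column to tabulate (default \code{"dice"}).
#' @param aggregate \code{"median"} or \code{"mean"} across folds.
#' @return A list with \code{values} (data.frame, architectures x
#'   strategies) and \code{best} (logical matrix of row-max flags).
#' @export
resultsTable <- function(foldResults, value = "dice",
                         aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!nrow(foldResults)) stop("empty fold results")
  if (is.null(foldResults$arch)) foldResults$arch <- "model"
  archs <- unique(foldResults$arch)
  strats <- unique(foldResults$strategy)
  fun <- if (aggregate == "median") median else mean
  values <- matrix(NA_real_, length(archs), length(strats),
                   dimnames = list(archs, strats))
  for (a in archs) for (s in strats) {
    v <- foldResults[foldResults$arch == a & foldResults$strategy == s,
                     value]
    v <- v[!is.na(v)]
    if (length(v)) values[a, s] <- fun(v)
  }
  best <- t(apply(values, 1, function(r) {
    !is.na(r) & r == max(r, na.rm = TRUE)
  }))
  dimnames(best) <- dimnames(values)
  list(values = as.data.frame(values), best = best)
}

#' Methods-comparison table
#'
#' The five-row comparison layout (Dice, F1-score, Sensitivity,
#' Specificity, Accuracy), one column per method. The \code{computation}
#' label records whether the metric sets came from per-image aggregation
#' or from pooled counts, since the two routes differ.
#'
#' @param metricsList named list of [MetricSet-class] objects, one per
#'   method.
#' @param computation label, \code{"per-image"} or \code{"pooled"}.
#' @return A data.frame with rownames \code{Dice}, \code{F1-score},
#'   \code{Sensitivity}, \code{Specificity}, \code{Accuracy} and a
#'   \code{"computation"} attribute.
#' @export
methodsTable <- function(metricsList, computation = c("per-image",
                                                      "pooled")) {
  computation <- match.arg(computation)
  stopifnot(length(metricsList) >= 1, !is.null(names(metricsList)))
  cols <- lapply(metricsList, function(m)
    c(Dice = m@dice, `F1-score` = m@f1, Sensitivity = m@sensitivity,
      Specificity = m@specificity, Accuracy = m@accuracy))
  df <- as.data.frame(cols, check.names = FALSE)
  attr(df, "computation") <- computation
  df
}
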
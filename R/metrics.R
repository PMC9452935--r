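# Segmentation evaluation measures. Masks are 0/1 matrices; A is the
# prediction, B the ground truth. Empty-denominator convention: a metric
# is 1 when both masks are empty and 0 when exactly one is.

.checkMaskPair <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape", call. = FALSE)
  if (any(a != 0 & a != 1) || any(b != 0 & b != 1))
    stop("masks must be strictly binary (0/1)", call. = FALSE)
  invisible(TRUE)
}

.overlapStats <- function(a, b) {
  list(inter = sum(a == 1 & b == 1), na = sum(a == 1), nb = sum(b == 1))
}

.ratioOrConvention <- function(num, den, na, nb) {
  if (den == 0) return(if (na == 0 && nb == 0) 1 else 0)
  num / den
}

#' Dice similarity coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}, a region-overlap score in [0, 1].
#' When both masks are empty the score is 1; when exactly one is empty it
#' is 0.
#'
#' @param a predicted binary mask (0/1 matrix).
#' @param b ground-truth binary mask of the same shape.
#' @return the coefficient in [0, 1].
#' @examples
#' m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
#' diceCoefficient(m, m) # 1
#' @export
diceCoefficient <- function(a, b) {
  .checkMaskPair(a, b)
  s <- .overlapStats(a, b)
  .ratioOrConvention(2 * s$inter, s$na + s$nb, s$na, s$nb)
}

#' Intersection over union (IoU)
#'
#' \eqn{|A \cap B| / |A \cup B|} for a single mask pair. The dataset-level
#' "mIoU" reported by [evaluateDataset()] is this foreground IoU averaged
#' over images. Same empty-mask convention as [diceCoefficient()].
#'
#' @inheritParams diceCoefficient
#' @return the coefficient in [0, 1].
#' @export
iouCoefficient <- function(a, b) {
  .checkMaskPair(a, b)
  s <- .overlapStats(a, b)
  .ratioOrConvention(s$inter, s$na + s$nb - s$inter, s$na, s$nb)
}

#' Positive predictive value (precision of foreground pixels)
#'
#' \eqn{|A \cap B| / |A|}: the fraction of predicted foreground that is
#' truly foreground.
#'
#' @inheritParams diceCoefficient
#' @return the value in [0, 1].
#' @export
positivePredictiveValue <- function(a, b) {
  .checkMaskPair(a, b)
  s <- .overlapStats(a, b)
  .ratioOrConvention(s$inter, s$na, s$na, s$nb)
}

#' Sensitivity (recall of foreground pixels)
#'
#' \eqn{|A \cap B| / |B|}: the fraction of true foreground that is
#' predicted.
#'
#' @inheritParams diceCoefficient
#' @return the value in [0, 1].
#' @export
sensitivityScore <- function(a, b) {
  .checkMaskPair(a, b)
  s <- .overlapStats(a, b)
  .ratioOrConvention(s$inter, s$nb, s$na, s$nb)
}

#' Hausdorff distance between two masks
#'
#' The directed distance
#' \eqn{h(A, B) = \max_{a \in A} \min_{b \in B} d(a, b)} with Euclidean
#' \eqn{d} over foreground pixel coordinates, which is the form the
#' evaluation protocol prints; set \code{symmetric = TRUE} for the
#' symmetric variant \eqn{\max(h(A, B), h(B, A))}. Computed via exact
#' Euclidean distance maps.
#'
#' @inheritParams diceCoefficient
#' @param symmetric return the symmetric Hausdorff distance?
#' @return the distance in pixels.
#' @examples
#' a <- matrix(0, 8, 8); b <- a
#' a[1, 1] <- 1; b[4, 5] <- 1
#' hausdorffDistance(a, b) # 5
#' @export
hausdorffDistance <- function(a, b, symmetric = FALSE) {
  .checkMaskPair(a, b)
  if (sum(a) == 0 || sum(b) == 0)
    stop("the Hausdorff distance is undefined for an empty mask",
         call. = FALSE)
  h <- .directedHausdorff(a, b)
  if (symmetric) max(h, .directedHausdorff(b, a)) else h
}

# max over A-pixels of the Euclidean distance to the nearest B-pixel:
# the distance map of the complement of B evaluated on A
.directedHausdorff <- function(a, b) {
  dt <- EBImage::distmap(1 - b, metric = "euclidean")
  max(dt[a == 1])
}

#' Evaluate a set of predicted masks against ground truth
#'
#' Computes Dice, IoU, PPV, sensitivity and the Hausdorff distance per
#' image pair, then their arithmetic means. Pairs where either mask is
#' empty get \code{NA} for the Hausdorff distance and are dropped from its
#' mean.
#'
#' @param preds list of predicted binary masks.
#' @param gts list of ground-truth binary masks, pairwise the same shapes.
#' @param symmetricHD use the symmetric Hausdorff variant?
#' @return a [MetricsReport-class] object.
#' @examples
#' m <- matrix(0, 6, 6); m[2:4, 2:4] <- 1
#' evaluateDataset(list(m), list(m))
#' @export
evaluateDataset <- function(preds, gts, symmetricHD = FALSE) {
  if (length(preds) == 0L)
    stop("need at least one mask pair", call. = FALSE)
  if (length(preds) != length(gts))
    stop("prediction and ground-truth lists must have equal length",
         call. = FALSE)
  rows <- lapply(seq_along(preds), function(i) {
    a <- preds[[i]]
    b <- gts[[i]]
    hd <- if (sum(a) > 0 && sum(b) > 0)
      hausdorffDistance(a, b, symmetric = symmetricHD) else NA_real_
    data.frame(dice = diceCoefficient(a, b), miou = iouCoefficient(a, b),
               ppv = positivePredictiveValue(a, b),
               sensitivity = sensitivityScore(a, b), hd = hd)
  })
  perImage <- do.call(rbind, rows)
  means <- c(dice = mean(perImage$dice), miou = mean(perImage$miou),
             ppv = mean(perImage$ppv),
             sensitivity = mean(perImage$sensitivity),
             hd = mean(perImage$hd, na.rm = TRUE))
  new("MetricsReport", perImage = perImage, means = means,
      nImages = length(preds))
}

#' Write a metrics report to CSV or JSON
#'
#' CSV output has one row per image plus a final \code{mean} row; JSON
#' output carries the per-image table and the means.
#'
#' @param report a [MetricsReport-class].
#' @param path output file; format chosen by extension (.csv or .json).
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(perImage = report@perImage, means = as.list(report@means),
           nImages = report@nImages),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    tab <- report@perImage
    tab$image <- seq_len(nrow(tab))
    meanRow <- data.frame(t(report@means))
    meanRow$image <- "mean"
    utils::write.csv(rbind(tab, meanRow), path, row.names = FALSE)
  }
  invisible(path)
}
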
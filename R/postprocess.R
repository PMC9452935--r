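# Morphological cleanup of thresholded network output: remove small
# non-cell fragments and fill small enclosed holes. Foreground components
# use 8-connectivity, background (hole) components 4-connectivity, the
# standard dual pair.

#' Binarize a probability map
#'
#' @param probMap matrix of probabilities in [0, 1].
#' @param threshold cut in (0, 1); a pixel is foreground iff
#'   \code{p >= threshold}.
#' @return a 0/1 integer matrix of the same shape.
#' @examples
#' binarize(matrix(c(0.2, 0.5, 0.9, 0.4), 2, 2), 0.5)
#' @export
binarize <- function(probMap, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  if (any(probMap < 0 | probMap > 1))
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  m <- matrix(as.integer(probMap >= threshold), nrow(probMap),
              ncol(probMap))
  m
}

#' Label connected components of a binary mask
#'
#' Flood-fill labelling with selectable pixel connectivity.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return an integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8) {
  storage.mode(mask) <- "integer"
  .label_components(mask, as.integer(connectivity))
}

#' Morphological cleanup of a binary mask
#'
#' Removes foreground connected components (8-connectivity) with area
#' below \code{minObjectArea(config)} pixels, then fills enclosed
#' background components (4-connectivity, not touching the image border)
#' of area at most \code{maxHoleArea(config)} pixels. Idempotent:
#' applying it twice equals applying it once.
#'
#' @param mask 0/1 matrix.
#' @param config a [CleanupConfig-class].
#' @return the cleaned 0/1 integer matrix.
#' @examples
#' m <- matrix(0L, 16, 16); m[4:12, 4:12] <- 1L; m[7:8, 7:8] <- 0L
#' m[2, 14] <- 1L # a 1-pixel speck
#' cleaned <- morphCleanup(m, cleanupConfig(minObjectArea = 4,
#'                                          maxHoleArea = 8))
#' sum(cleaned) - sum(m) # speck removed, hole filled
#' @export
morphCleanup <- function(mask, config = cleanupConfig()) {
  validObject(config)
  if (any(mask != 0 & mask != 1))
    stop("mask must be strictly binary (0/1)", call. = FALSE)
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0L) return(mask)
  # drop small foreground components
  lab <- labelComponents(mask, 8)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < config@minObjectArea)
    if (length(drop)) mask[lab %in% drop] <- 0L
  }
  # fill small enclosed holes
  bg <- 1L - mask
  lab <- labelComponents(bg, 4)
  if (max(lab) > 0L) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    areas <- tabulate(lab[lab > 0L])
    fill <- setdiff(which(areas <= config@maxHoleArea), border)
    if (length(fill)) mask[lab %in% fill] <- 1L
  }
  mask
}

#' Read a binary mask from a PNG file
#'
#' Single-channel 0/255 (or 0/1) PNG on disk, mapped to a 0/1 integer
#' matrix in memory.
#'
#' @param path PNG file path.
#' @return a 0/1 integer matrix.
#' @export
readMaskPNG <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) img <- img[, , 1]
  # EBImage stores images transposed (x, y); present masks as (row, col)
  m <- t(img)
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write a binary mask to a PNG file
#'
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  if (any(mask != 0 & mask != 1))
    stop("mask must be strictly binary (0/1)", call. = FALSE)
  EBImage::writeImage(EBImage::Image(t(mask)), path, type = "png")
  invisible(path)
}
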
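#' @import methods
#' @importFrom stats rnorm runif
#' @useDynLib leukoseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Network architecture configuration
#'
#' Holds every architectural knob of the segmentation network: the residual
#' encoder's block counts, the squeeze-and-excitation reduction ratio
#' \eqn{R}, the decoder's atrous dilation rate \eqn{d}, and a width
#' multiplier used to shrink every channel count proportionally for
#' desk-scale experiments.
#'
#' @slot inChannels number of input image channels (3 for RGB).
#' @slot inputSide input image side in pixels; must be divisible by 32 so
#'   that five successive halvings land on integer sizes.
#' @slot blockCounts integer vector of length 4: bottleneck residual blocks
#'   per encoder stage (default \code{c(3, 4, 6, 3)}, the ResNet50 plan).
#' @slot seReduction SE reduction ratio \eqn{R \ge 1} (default 6).
#' @slot dilationRate atrous dilation rate \eqn{d} for the decoder's
#'   dilated 3x3 convolutions; either one value for all four decoder units
#'   or a vector of length 4 (default 2).
#' @slot widthMultiplier positive scale on every channel count (default 1;
#'   values < 1 are intended for small CPU experiments).
#' @slot sigmoidOutput always \code{TRUE}: the head ends in a sigmoid.
#' @slot pretrainedSource optional path to an encoder weight archive.
#' @seealso [networkConfig()], [assembleNetwork()]
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(
    inChannels = "integer",
    inputSide = "integer",
    blockCounts = "integer",
    seReduction = "integer",
    dilationRate = "integer",
    widthMultiplier = "numeric",
    sigmoidOutput = "logical",
    pretrainedSource = "character"
  )
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (object@inChannels < 1L) msg <- c(msg, "inChannels must be >= 1")
  if (object@inputSide %% 32L != 0L || object@inputSide < 32L)
    msg <- c(msg, "inputSide must be a positive multiple of 32")
  if (length(object@blockCounts) != 4L || any(object@blockCounts < 1L))
    msg <- c(msg, "blockCounts must have exactly 4 entries, each >= 1")
  if (object@seReduction < 1L) msg <- c(msg, "seReduction must be >= 1")
  if (!length(object@dilationRate) %in% c(1L, 4L) ||
      any(object@dilationRate < 1L))
    msg <- c(msg, "dilationRate must be positive, length 1 or 4")
  if (object@widthMultiplier <= 0)
    msg <- c(msg, "widthMultiplier must be > 0")
  if (length(msg)) msg else TRUE
})

#' Focal loss parameters
#'
#' @slot alpha class-balancing weight in (0, 1); default 0.25.
#' @slot gamma focusing exponent >= 0; default 2. With \code{gamma = 0} and
#'   \code{alpha = 0.5} the focal loss reduces to half the binary
#'   cross-entropy.
#' @exportClass FocalParams
setClass("FocalParams",
  representation(alpha = "numeric", gamma = "numeric"))

setValidity("FocalParams", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie strictly in (0, 1)")
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Mask cleanup configuration
#'
#' @slot threshold probability cut used to binarize the sigmoid output
#'   (pixel is foreground iff p >= threshold); default 0.5.
#' @slot minObjectArea foreground components (8-connectivity) smaller than
#'   this many pixels are removed; default 64.
#' @slot maxHoleArea enclosed background components (4-connectivity) of at
#'   most this many pixels are filled; default 64.
#' @exportClass CleanupConfig
setClass("CleanupConfig",
  representation(threshold = "numeric", minObjectArea = "numeric",
                 maxHoleArea = "numeric"))

setValidity("CleanupConfig", function(object) {
  msg <- character()
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie strictly in (0, 1)")
  if (object@minObjectArea < 0 || object@maxHoleArea < 0)
    msg <- c(msg, "areas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic scene configuration
#'
#' Parameters of the synthetic single-cell image generator. Each rendered
#' scene contains exactly one roughly elliptical cell (cytoplasm plus 1-3
#' darker nucleus lobes) over a textured background, with a multiplicative
#' brightness gradient and Gaussian blur. \code{colorProximity} is the
#' Euclidean distance in normalized RGB between the cytoplasm color and the
#' background color: small values emulate lymphocyte/monocyte images whose
#' cytoplasm is nearly the background color, the hard case.
#'
#' @slot side image side in pixels.
#' @slot cellRadiusRange cell radius as a fraction of side, c(lo, hi).
#' @slot boundaryIrregularity amplitude in [0, 1] of the random radial
#'   perturbation of the cell outline (0 = exact ellipse).
#' @slot colorProximity cytoplasm-background RGB distance in [0, 1].
#' @slot nucleusContrast intensity offset of the nucleus lobes (darker).
#' @slot brightnessJitter amplitude of the multiplicative brightness field.
#' @slot blurSigma Gaussian blur standard deviation in pixels.
#' @slot seed integer seed; the generator is a pure function of it.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    side = "integer",
    cellRadiusRange = "numeric",
    boundaryIrregularity = "numeric",
    colorProximity = "numeric",
    nucleusContrast = "numeric",
    brightnessJitter = "numeric",
    blurSigma = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  r <- object@cellRadiusRange
  if (length(r) != 2L || r[1] <= 0 || r[2] <= r[1] || r[2] > 0.45)
    msg <- c(msg, "cellRadiusRange must be c(lo, hi) with 0 < lo < hi <= 0.45")
  if (object@side < 16L) msg <- c(msg, "side must be >= 16")
  if (object@boundaryIrregularity < 0 || object@boundaryIrregularity > 1)
    msg <- c(msg, "boundaryIrregularity must lie in [0, 1]")
  if (object@colorProximity < 0 || object@colorProximity > 1)
    msg <- c(msg, "colorProximity must lie in [0, 1]")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Augmentation specification
#'
#' An ordered list of augmentation operations drawn from rotation,
#' horizontal/vertical flips, scaling, and brightness/contrast adjustment.
#' Geometric operations are applied identically to image and mask (the mask
#' with nearest-neighbour interpolation so it stays binary); photometric
#' operations touch the image only.
#'
#' @slot ops character vector, subset of
#'   \code{c("rotation", "hflip", "vflip", "scaling", "brightness",
#'   "contrast")}, in application order.
#' @slot rotationRange degrees, c(lo, hi).
#' @slot scaleRange isotropic scale factor range.
#' @slot brightnessRange additive intensity offset range.
#' @slot contrastRange multiplicative contrast factor range.
#' @slot seed integer seed for parameter sampling.
#' @exportClass AugmentationSpec
setClass("AugmentationSpec",
  representation(
    ops = "character",
    rotationRange = "numeric",
    scaleRange = "numeric",
    brightnessRange = "numeric",
    contrastRange = "numeric",
    seed = "integer"
  )
)

.augOps <- c("rotation", "hflip", "vflip", "scaling", "brightness",
             "contrast")

setValidity("AugmentationSpec", function(object) {
  bad <- setdiff(object@ops, .augOps)
  if (length(bad))
    return(paste0("unknown augmentation op(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' Training configuration
#'
#' The optimization protocol: Adam, with the published full-scale settings
#' as defaults (learning rate 1e-4, batch size 8, 200 epochs). The loss is
#' either plain binary cross-entropy (\code{"bce"}) or the focal loss
#' (\code{"focal"}) for datasets dominated by hard examples.
#'
#' @slot optimizer only \code{"adam"}.
#' @slot learningRate positive step size.
#' @slot batchSize images per gradient step.
#' @slot epochs passes over the training set.
#' @slot loss \code{"bce"} or \code{"focal"}.
#' @slot focal [FocalParams-class] used when \code{loss == "focal"}.
#' @slot seed integer seed governing shuffling and initialization.
#' @slot device identifier, informational only (\code{"cpu"}).
#' @slot checkpointDir directory for checkpoints, or \code{""} to keep the
#'   best model in memory only.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    optimizer = "character",
    learningRate = "numeric",
    batchSize = "integer",
    epochs = "integer",
    loss = "character",
    focal = "FocalParams",
    seed = "integer",
    device = "character",
    checkpointDir = "character"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!identical(object@optimizer, "adam"))
    msg <- c(msg, "optimizer must be 'adam'")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (!object@loss %in% c("bce", "focal"))
    msg <- c(msg, "loss must be 'bce' or 'focal'")
  if (length(msg)) msg else TRUE
})

#' Segmentation evaluation report
#'
#' Per-image and dataset-mean values of the five segmentation measures:
#' Dice, mIoU, positive predictive value, sensitivity (all in [0, 1],
#' larger is better) and the Hausdorff distance in pixels (smaller is
#' better). Dataset values are arithmetic means of the per-image values.
#'
#' @slot perImage data.frame with columns dice, miou, ppv, sensitivity, hd.
#' @slot means named numeric vector of the five column means.
#' @slot nImages number of image pairs evaluated.
#' @seealso [evaluateDataset()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perImage = "data.frame", means = "numeric",
                 nImages = "integer"))

#' Assembled segmentation network
#'
#' The full encoder-decoder model: configuration plus every parameter
#' tensor (convolution kernels, batch-norm scales/shifts and running
#' statistics, SE weights) in a nested list mirroring the architecture.
#'
#' @slot config the [NetworkConfig-class] the network was built from.
#' @slot params nested parameter list (see [assembleNetwork()]).
#' @seealso [assembleNetwork()], [networkForward()], [countParameters()]
#' @exportClass SegmentationNetwork
setClass("SegmentationNetwork",
  representation(config = "NetworkConfig", params = "list"))
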
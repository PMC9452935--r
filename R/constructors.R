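#' Create a network configuration
#'
#' @param inChannels input channels (default 3, RGB).
#' @param inputSide input side in pixels, a multiple of 32 (default 256).
#' @param blockCounts residual blocks per encoder stage (default 3, 4, 6, 3).
#' @param seReduction SE reduction ratio R (default 6).
#' @param dilationRate decoder atrous dilation rate d, scalar or length 4
#'   (default 2).
#' @param widthMultiplier proportional scale on all channel counts
#'   (default 1; use e.g. 1/8 for CPU-scale experiments).
#' @param pretrainedSource optional path to an encoder weight archive.
#' @return a [NetworkConfig-class] object.
#' @examples
#' cfg <- networkConfig(widthMultiplier = 1 / 8, inputSide = 64)
#' cfg
#' @export
networkConfig <- function(inChannels = 3, inputSide = 256,
                          blockCounts = c(3, 4, 6, 3), seReduction = 6,
                          dilationRate = 2, widthMultiplier = 1,
                          pretrainedSource = character()) {
  new("NetworkConfig",
      inChannels = as.integer(inChannels),
      inputSide = as.integer(inputSide),
      blockCounts = as.integer(blockCounts),
      seReduction = as.integer(seReduction),
      dilationRate = as.integer(dilationRate),
      widthMultiplier = as.numeric(widthMultiplier),
      sigmoidOutput = TRUE,
      pretrainedSource = as.character(pretrainedSource))
}

#' Create focal loss parameters
#'
#' @param alpha balancing weight in (0, 1); default 0.25.
#' @param gamma focusing exponent >= 0; default 2.
#' @return a [FocalParams-class] object.
#' @export
focalParams <- function(alpha = 0.25, gamma = 2) {
  new("FocalParams", alpha = as.numeric(alpha), gamma = as.numeric(gamma))
}

#' Create a mask cleanup configuration
#'
#' @param threshold binarization cut in (0, 1); default 0.5.
#' @param minObjectArea smallest foreground component kept, pixels
#'   (default 64).
#' @param maxHoleArea largest enclosed hole filled, pixels (default 64).
#' @return a [CleanupConfig-class] object.
#' @export
cleanupConfig <- function(threshold = 0.5, minObjectArea = 64,
                          maxHoleArea = 64) {
  new("CleanupConfig", threshold = as.numeric(threshold),
      minObjectArea = as.numeric(minObjectArea),
      maxHoleArea = as.numeric(maxHoleArea))
}

#' Create a synthetic scene configuration
#'
#' @param side image side in pixels (default 256).
#' @param cellRadiusRange cell radius as a fraction of side (default
#'   0.15-0.35).
#' @param boundaryIrregularity radial perturbation amplitude in [0, 1]
#'   (default 0.15; 0 gives an exact ellipse).
#' @param colorProximity cytoplasm-background RGB distance (default 0.25;
#'   small values emulate the hard lymphocyte/monocyte case).
#' @param nucleusContrast darkening of the nucleus lobes (default 0.25).
#' @param brightnessJitter amplitude of the brightness gradient
#'   (default 0.15).
#' @param blurSigma Gaussian blur sigma in pixels (default 1.5).
#' @param seed integer seed (default 1).
#' @return a [SceneConfig-class] object.
#' @export
sceneConfig <- function(side = 256, cellRadiusRange = c(0.15, 0.35),
                        boundaryIrregularity = 0.15, colorProximity = 0.25,
                        nucleusContrast = 0.25, brightnessJitter = 0.15,
                        blurSigma = 1.5, seed = 1) {
  new("SceneConfig", side = as.integer(side),
      cellRadiusRange = as.numeric(cellRadiusRange),
      boundaryIrregularity = as.numeric(boundaryIrregularity),
      colorProximity = as.numeric(colorProximity),
      nucleusContrast = as.numeric(nucleusContrast),
      brightnessJitter = as.numeric(brightnessJitter),
      blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

#' Create an augmentation specification
#'
#' @param ops ordered character vector of operations, a subset of
#'   rotation, hflip, vflip, scaling, brightness, contrast.
#' @param rotationRange rotation angle range in degrees (default +/-180).
#' @param scaleRange isotropic scale range (default 0.8-1.2).
#' @param brightnessRange additive offset range (default +/-0.2).
#' @param contrastRange contrast factor range (default 0.8-1.2).
#' @param seed integer seed for parameter sampling.
#' @return an [AugmentationSpec-class] object.
#' @export
augmentationSpec <- function(ops = c("rotation", "hflip", "vflip",
                                     "scaling", "brightness", "contrast"),
                             rotationRange = c(-180, 180),
                             scaleRange = c(0.8, 1.2),
                             brightnessRange = c(-0.2, 0.2),
                             contrastRange = c(0.8, 1.2), seed = 1) {
  new("AugmentationSpec", ops = ops,
      rotationRange = as.numeric(rotationRange),
      scaleRange = as.numeric(scaleRange),
      brightnessRange = as.numeric(brightnessRange),
      contrastRange = as.numeric(contrastRange), seed = as.integer(seed))
}

#' Create a training configuration
#'
#' Defaults follow the published full-scale protocol: Adam with learning
#' rate 1e-4, batch size 8, 200 epochs, binary cross-entropy loss.
#'
#' @param learningRate Adam step size (default 1e-4).
#' @param batchSize images per gradient step (default 8).
#' @param epochs training epochs (default 200).
#' @param loss \code{"bce"} or \code{"focal"}.
#' @param focal [FocalParams-class], used when \code{loss == "focal"}.
#' @param seed integer seed (default 1).
#' @param device informational device tag (default \code{"cpu"}).
#' @param checkpointDir directory for checkpoints; \code{""} keeps the best
#'   model in memory only.
#' @return a [TrainConfig-class] object.
#' @seealso [deskScaleTrainConfig()]
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 8, epochs = 200,
                        loss = c("bce", "focal"), focal = focalParams(),
                        seed = 1, device = "cpu", checkpointDir = "") {
  loss <- match.arg(loss)
  new("TrainConfig", optimizer = "adam",
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      loss = loss, focal = focal, seed = as.integer(seed),
      device = device, checkpointDir = checkpointDir)
}

#' Desk-scale configuration profile
#'
#' A named small-compute profile used throughout the examples and tests: a
#' width-1/8 network at side 64, trained for up to 20 epochs with Adam at
#' its conventional default step size 1e-3 on a couple of hundred synthetic
#' images. The published full-scale protocol (full width, side 256, 200
#' epochs at 1e-4) is impractical on one CPU; this profile keeps every
#' architectural element intact while shrinking channels and data.
#'
#' @param loss \code{"bce"} or \code{"focal"}.
#' @param epochs training epochs (default 20).
#' @param seed integer seed.
#' @return a list with elements \code{network} ([NetworkConfig-class]),
#'   \code{train} ([TrainConfig-class]), \code{scene}
#'   ([SceneConfig-class]) and \code{cleanup} ([CleanupConfig-class]).
#' @examples
#' prof <- deskScaleTrainConfig(seed = 7)
#' prof$network
#' @export
deskScaleTrainConfig <- function(loss = "bce", epochs = 20, seed = 1) {
  list(
    network = networkConfig(inputSide = 64, widthMultiplier = 1 / 8),
    train = trainConfig(learningRate = 1e-3, batchSize = 8,
                        epochs = epochs, loss = loss, seed = seed),
    scene = sceneConfig(side = 64, blurSigma = 1.0, seed = seed),
    cleanup = cleanupConfig(minObjectArea = 32, maxHoleArea = 32)
  )
}

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig\n")
  cat("  input:", object@inChannels, "x", object@inputSide, "x",
      object@inputSide, "\n")
  cat("  encoder blocks:", paste(object@blockCounts, collapse = ", "), "\n")
  cat("  SE reduction R:", object@seReduction,
      " dilation d:", paste(object@dilationRate, collapse = ", "), "\n")
  cat("  width multiplier:", object@widthMultiplier, "\n")
})

setMethod("show", "SegmentationNetwork", function(object) {
  cfg <- object@config
  cat("SegmentationNetwork (residual encoder + SE/atrous decoder)\n")
  cat("  input:", cfg@inChannels, "x", cfg@inputSide, "x", cfg@inputSide,
      " width:", cfg@widthMultiplier, "\n")
  cat("  parameters:", format(countParameters(object), big.mark = ","),
      "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", object@nImages, "image(s)\n")
  print(round(object@means, 4))
})
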
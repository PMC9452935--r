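#' Run the desk-scale training experiment end to end
#'
#' The packaged small-compute counterpart of the full training protocol:
#' generate 200 synthetic scenes, split them 8:1:1 into train/val/test
#' (160/20/20) BEFORE any augmentation so no augmented copy of a test
#' source leaks into training, expand the training split threefold by
#' seeded augmentation (the same remedy for small-sample overfitting the
#' full protocol uses), train the width-1/8 side-64 network for up to 20
#' epochs, and evaluate the best-by-validation-Dice weights on the 20
#' held-out images with morphological cleanup.
#'
#' @param loss \code{"bce"} or \code{"focal"}.
#' @param colorProximity optional override of the scene's
#'   cytoplasm-background RGB distance (small = hard,
#'   lymphocyte/monocyte-like); default keeps the profile's 0.25.
#' @param seed master seed for generation, splitting, augmentation,
#'   initialization and training.
#' @param epochs training epochs (default 20).
#' @param expandFactor training-split expansion factor (default 3).
#' @param verbose print per-epoch progress?
#' @return a list: \code{report} ([MetricsReport-class] on the test
#'   split), \code{history}, \code{model}, \code{profile} (the resolved
#'   configuration objects).
#' @seealso [deskScaleTrainConfig()]
#' @export
runDeskScaleExperiment <- function(loss = "bce", colorProximity = NULL,
                                   seed = 1, epochs = 20,
                                   expandFactor = 3, verbose = FALSE) {
  prof <- deskScaleTrainConfig(loss = loss, epochs = epochs, seed = seed)
  if (!is.null(colorProximity))
    prof$scene@colorProximity <- as.numeric(colorProximity)
  ds <- generateDataset(200, prof$scene, seed = seed)
  sp <- splitDataset(ds, ratios = c(8, 1, 1), seed = seed)
  if (expandFactor > 1) {
    spec <- augmentationSpec(seed = seed)
    sp$train <- expandDataset(sp$train,
                              expandFactor * length(sp$train$images),
                              spec)
  }
  net <- assembleNetwork(prof$network, seed = seed)
  fit <- trainNetwork(net, sp$train, sp$val, prof$train,
                      verbose = verbose)
  report <- evaluateModel(fit$model, sp$test, prof$cleanup)
  list(report = report, history = fit$history, model = fit$model,
       bestEpoch = fit$bestEpoch, profile = prof, test = sp$test)
}
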
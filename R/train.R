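# Training with Adam, prediction and evaluation.

.adamB1 <- 0.9
.adamB2 <- 0.999
.adamEps <- 1e-8

# One Adam step over the nested parameter/gradient trees. `g` mirrors the
# trainable subset of `p` (by name where named, by position otherwise);
# entries of `p` absent from `g` (BN buffers, conv hyperparameters) are
# left untouched. Moment trees `m`/`v` are grown lazily.
.adamUpdate <- function(p, g, m, v, lr, bc1, bc2) {
  if (is.numeric(g)) {
    if (is.null(m)) {
      m <- g * 0
      v <- g * 0
    }
    m <- .adamB1 * m + (1 - .adamB1) * g
    v <- .adamB2 * v + (1 - .adamB2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + .adamEps)
    return(list(p = p, m = m, v = v))
  }
  if (is.null(m)) {
    m <- vector("list", length(g))
    v <- vector("list", length(g))
    names(m) <- names(g)
    names(v) <- names(g)
  }
  keys <- if (is.null(names(g))) seq_along(g) else names(g)
  for (k in keys) {
    if (is.null(g[[k]])) next
    r <- .adamUpdate(p[[k]], g[[k]], m[[k]], v[[k]], lr, bc1, bc2)
    p[[k]] <- r$p
    m[[k]] <- r$m
    v[[k]] <- r$v
  }
  list(p = p, m = m, v = v)
}

.stackBatch <- function(images, masks, idx) {
  d <- dim(images[[idx[1]]])
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  y <- array(0, c(d[1], d[2], 1, length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- images[[idx[j]]]
    y[, , 1, j] <- masks[[idx[j]]]
  }
  list(x = x, y = y)
}

#' Train the segmentation network
#'
#' Minimizes the configured loss (binary cross-entropy or focal) with
#' Adam. Per epoch the training set is reshuffled (seeded), the mean
#' training loss recorded and, when a validation set is given, the
#' validation loss and mean validation Dice (at threshold 0.5, no
#' cleanup) computed in eval mode. The returned model carries the
#' parameters of the epoch with the best validation Dice (best training
#' loss when there is no validation set). Fully deterministic for a fixed
#' configuration and seed.
#'
#' @param model a [SegmentationNetwork-class] to train.
#' @param train dataset with \code{images} and \code{masks} at the model's
#'   input size.
#' @param val optional validation dataset for model selection.
#' @param config a [TrainConfig-class].
#' @param verbose print one line per epoch?
#' @return a list with \code{model} (best weights), \code{history}
#'   (data.frame epoch/trainLoss/valLoss/valDice) and \code{bestEpoch}.
#' @export
trainNetwork <- function(model, train, val = NULL, config = trainConfig(),
                         verbose = FALSE) {
  stopifnot(is(model, "SegmentationNetwork"))
  validObject(config)
  n <- length(train$images)
  if (n == 0L) stop("training set is empty", call. = FALSE)
  params <- model@params
  mstate <- NULL
  vstate <- NULL
  step <- 0L
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), valDice = numeric())
  bestScore <- -Inf
  bestParams <- params
  bestEpoch <- 0L
  withSeed(config@seed, {
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      losses <- numeric()
      for (b0 in seq(1, n, by = config@batchSize)) {
        idx <- ord[b0:min(b0 + config@batchSize - 1L, n)]
        batch <- .stackBatch(train$images, train$masks, idx)
        fwd <- .netFwd(params, batch$x, training = TRUE, keep = TRUE)
        params <- fwd$params
        lg <- .lossGrad(fwd$probs, batch$y, config@loss, config@focal)
        if (!is.finite(lg$value))
          stop("non-finite training loss at epoch ", ep,
               " (step ", step + 1L, "); aborting", call. = FALSE)
        grads <- .netBwd(params, fwd$cache, lg$dz)
        step <- step + 1L
        bc1 <- 1 - .adamB1^step
        bc2 <- 1 - .adamB2^step
        upd <- .adamUpdate(params, grads, mstate, vstate,
                           config@learningRate, bc1, bc2)
        params <- upd$p
        mstate <- upd$m
        vstate <- upd$v
        losses <- c(losses, lg$value)
      }
      trainLoss <- mean(losses)
      valLoss <- NA_real_
      valDice <- NA_real_
      if (!is.null(val) && length(val$images) > 0) {
        ev <- .evalOnSet(params, val, config)
        valLoss <- ev$loss
        valDice <- ev$dice
        score <- valDice
      } else {
        score <- -trainLoss
      }
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = trainLoss,
                                     valLoss = valLoss,
                                     valDice = valDice))
      if (score > bestScore) {
        bestScore <- score
        bestParams <- params
        bestEpoch <- ep
      }
      if (verbose)
        message(sprintf(
          "epoch %3d  train %.4f  val %.4f  val Dice %.4f", ep,
          trainLoss, valLoss, valDice))
    }
  })
  best <- new("SegmentationNetwork", config = model@config,
              params = bestParams)
  if (nzchar(config@checkpointDir)) {
    dir.create(config@checkpointDir, recursive = TRUE,
               showWarnings = FALSE)
    saveCheckpoint(best, file.path(config@checkpointDir, "best.rds"))
  }
  list(model = best, history = hist, bestEpoch = bestEpoch)
}

.evalOnSet <- function(params, ds, config) {
  n <- length(ds$images)
  losses <- numeric()
  dices <- numeric(n)
  for (b0 in seq(1, n, by = config@batchSize)) {
    idx <- b0:min(b0 + config@batchSize - 1L, n)
    batch <- .stackBatch(ds$images, ds$masks, idx)
    fwd <- .netFwd(params, batch$x, training = FALSE)
    lg <- .lossGrad(fwd$probs, batch$y, config@loss, config@focal)
    losses <- c(losses, lg$value)
    for (j in seq_along(idx)) {
      pred <- binarize(fwd$probs[, , 1, j], 0.5)
      dices[idx[j]] <- diceCoefficient(pred, ds$masks[[idx[j]]])
    }
  }
  list(loss = mean(losses), dice = mean(dices))
}

#' Predict cleaned binary masks
#'
#' Forward pass (eval mode), binarization at the cleanup threshold, then
#' morphological cleanup per image. Results are identical whether images
#' are predicted singly or in a batch.
#'
#' @param model a [SegmentationNetwork-class].
#' @param images one (H, W, 3) array or a list of them.
#' @param cleanup a [CleanupConfig-class].
#' @param batchSize images per forward pass.
#' @return a list of 0/1 integer matrices (or one matrix for one array).
#' @export
predictMasks <- function(model, images, cleanup = cleanupConfig(),
                         batchSize = 8) {
  single <- !is.null(dim(images))
  if (single) images <- list(images)
  n <- length(images)
  out <- vector("list", n)
  for (b0 in seq(1, n, by = batchSize)) {
    idx <- b0:min(b0 + batchSize - 1L, n)
    d <- dim(images[[idx[1]]])
    x <- array(0, c(d[1], d[2], d[3], length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- images[[idx[j]]]
    probs <- networkForward(model, x)
    for (j in seq_along(idx)) {
      m <- binarize(probs[, , 1, j], cleanup@threshold)
      out[[idx[j]]] <- morphCleanup(m, cleanup)
    }
  }
  if (single) out[[1]] else out
}

#' Evaluate a model on a test set
#'
#' Predicts cleaned masks with [predictMasks()] and scores them with
#' [evaluateDataset()].
#'
#' @param model a [SegmentationNetwork-class].
#' @param testset dataset with \code{images} and ground-truth
#'   \code{masks}.
#' @param cleanup a [CleanupConfig-class].
#' @param reportPath optional path stem; writes \code{<stem>.csv} and
#'   \code{<stem>.json} reports.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, testset, cleanup = cleanupConfig(),
                          reportPath = NULL) {
  if (length(testset$images) == 0L)
    stop("test set is empty", call. = FALSE)
  preds <- predictMasks(model, testset$images, cleanup)
  rep <- evaluateDataset(preds, testset$masks)
  if (!is.null(reportPath)) {
    writeMetricsReport(rep, paste0(reportPath, ".csv"))
    writeMetricsReport(rep, paste0(reportPath, ".json"))
  }
  rep
}

# ---- checkpoints and pretrained encoder weights -----------------------

.configToList <- function(cfg) {
  list(inChannels = cfg@inChannels, inputSide = cfg@inputSide,
       blockCounts = cfg@blockCounts, seReduction = cfg@seReduction,
       dilationRate = cfg@dilationRate,
       widthMultiplier = cfg@widthMultiplier,
       sigmoidOutput = cfg@sigmoidOutput,
       pretrainedSource = cfg@pretrainedSource)
}

.configFromList <- function(x) {
  networkConfig(inChannels = x$inChannels, inputSide = x$inputSide,
                blockCounts = unlist(x$blockCounts),
                seReduction = x$seReduction,
                dilationRate = unlist(x$dilationRate),
                widthMultiplier = x$widthMultiplier,
                pretrainedSource = unlist(x$pretrainedSource) %||%
                  character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a model checkpoint
#'
#' Native serialization of configuration and parameters, with a JSON
#' sidecar (\code{<path>.json}) recording the [NetworkConfig-class].
#'
#' @param model a [SegmentationNetwork-class].
#' @param path checkpoint file path (.rds).
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "SegmentationNetwork"))
  saveRDS(list(config = .configToList(model@config),
               params = model@params), path)
  jsonlite::write_json(.configToList(model@config),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [saveCheckpoint()].
#' @return a [SegmentationNetwork-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path,
                               call. = FALSE)
  x <- readRDS(path)
  new("SegmentationNetwork", config = .configFromList(x$config),
      params = x$params)
}

#' Save the encoder weights of a model
#'
#' Writes the encoder parameters as a flat named archive loadable with
#' [loadPretrainedEncoder()], e.g. to transfer an encoder trained on one
#' dataset to another model of the same width.
#'
#' @param model a [SegmentationNetwork-class].
#' @param path output file (.rds).
#' @return \code{path}, invisibly.
#' @export
saveEncoderWeights <- function(model, path) {
  stopifnot(is(model, "SegmentationNetwork"))
  saveRDS(.flattenParams(list(encoder = model@params$encoder)), path)
  invisible(path)
}

#' Load pretrained encoder weights into a model
#'
#' Replaces encoder parameters whose names and shapes match the archive;
#' the decoder is untouched. Loading a full-width archive into a model
#' with \code{widthMultiplier != 1} is a configuration error because no
#' shape can match.
#'
#' @param model a [SegmentationNetwork-class].
#' @param source path to an archive from [saveEncoderWeights()].
#' @return a list with \code{model} (weights substituted) and
#'   \code{report}: character vectors \code{matched}, \code{unmatched}
#'   (archive entries with no counterpart) and \code{missing} (encoder
#'   parameters the archive does not cover).
#' @export
loadPretrainedEncoder <- function(model, source) {
  stopifnot(is(model, "SegmentationNetwork"))
  if (!file.exists(source))
    stop("pretrained weight archive not found: ", source, call. = FALSE)
  archive <- readRDS(source)
  flat <- .flattenParams(list(encoder = model@params$encoder))
  matched <- character()
  unmatched <- character()
  params <- model@params
  for (nm in names(archive)) {
    if (!nm %in% names(flat)) {
      unmatched <- c(unmatched, nm)
      next
    }
    a <- archive[[nm]]
    b <- flat[[nm]]
    if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
      stop("shape mismatch for '", nm, "': the archive does not fit ",
           "this model's width multiplier (",
           model@config@widthMultiplier, ")", call. = FALSE)
    }
    params <- .assignPath(params, .splitPath(nm), a)
    matched <- c(matched, nm)
  }
  list(model = new("SegmentationNetwork", config = model@config,
                   params = params),
       report = list(matched = matched, unmatched = unmatched,
                     missing = setdiff(names(flat), matched)))
}

.splitPath <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

.assignPath <- function(p, tokens, value) {
  key <- tokens[1]
  if (grepl("^\\[[0-9]+\\]$", key))
    key <- as.integer(sub("\\[([0-9]+)\\]", "\\1", key))
  if (length(tokens) == 1L) {
    dims <- dim(p[[key]])
    p[[key]] <- value
    if (!is.null(dims)) dim(p[[key]]) <- dims
  } else {
    p[[key]] <- .assignPath(p[[key]], tokens[-1], value)
  }
  p
}
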
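# Training losses. Probabilities are clamped to [eps, 1 - eps] before any
# logarithm so perfect predictions stay finite.

.lossEps <- 1e-7

.checkPredPair <- function(p, y) {
  if (!identical(dim(p), dim(y)) || length(p) != length(y))
    stop("prediction and label rasters must have identical shape",
         call. = FALSE)
  if (any(y != 0 & y != 1))
    stop("labels must be strictly binary (0/1)", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of \eqn{-[y \log p + (1 - y)\log(1 - p)]}, with
#' probabilities clamped to \eqn{[10^{-7}, 1 - 10^{-7}]} before the
#' logarithm. Non-negative and finite for any valid input.
#'
#' @param p predicted foreground probabilities in [0, 1] (vector, matrix
#'   or array).
#' @param y binary labels of the same shape.
#' @return the scalar loss.
#' @examples
#' bceLoss(0.5, 1) # log(2)
#' @export
bceLoss <- function(p, y) {
  .checkPredPair(p, y)
  pc <- pmin(pmax(p, .lossEps), 1 - .lossEps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Focal loss
#'
#' Cross-entropy down-weighted for easy pixels: per pixel
#' \eqn{-\alpha (1 - p)^\gamma \log p} where \eqn{y = 1} and
#' \eqn{-(1 - \alpha) p^\gamma \log(1 - p)} where \eqn{y = 0}, averaged
#' over pixels. With \eqn{\gamma = 0, \alpha = 0.5} this is exactly half
#' the binary cross-entropy. Defaults \eqn{\alpha = 0.25},
#' \eqn{\gamma = 2}.
#'
#' @inheritParams bceLoss
#' @param params a [FocalParams-class] object.
#' @return the scalar loss.
#' @examples
#' focalLoss(0.5, 1) # 0.25 * 0.25 * log(2)
#' @export
focalLoss <- function(p, y, params = focalParams()) {
  .checkPredPair(p, y)
  validObject(params)
  a <- params@alpha
  g <- params@gamma
  pc <- pmin(pmax(p, .lossEps), 1 - .lossEps)
  term <- ifelse(y == 1, -a * (1 - pc)^g * log(pc),
                 -(1 - a) * pc^g * log(1 - pc))
  mean(term)
}

# loss value and gradient w.r.t. the pre-sigmoid logits, given
# probabilities p = sigmoid(z). For BCE: dL/dz = (p - y) / N. For the
# focal loss the chain rule through p(1 - p) is applied analytically.
.lossGrad <- function(p, y, loss, focal) {
  n <- length(p)
  pc <- pmin(pmax(p, .lossEps), 1 - .lossEps)
  if (loss == "bce") {
    value <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
    dz <- (p - y) / n
  } else {
    a <- focal@alpha
    g <- focal@gamma
    pos <- y == 1
    term <- ifelse(pos, -a * (1 - pc)^g * log(pc),
                   -(1 - a) * pc^g * log(1 - pc))
    value <- mean(term)
    # d/dp of each branch, then * p(1-p) for d/dz
    dp <- ifelse(pos,
                 a * (g * (1 - pc)^(g - 1) * log(pc) - (1 - pc)^g / pc),
                 (1 - a) * (pc^g / (1 - pc) - g * pc^(g - 1) * log(1 - pc)))
    dz <- dp * pc * (1 - pc) / n
  }
  dim(dz) <- dim(p)
  list(value = value, dz = dz)
}
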
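# Layer primitives: thin R wrappers over the compiled conv/pool/upsample
# kernels, plus batch normalization and squeeze-excitation, which are
# cheap enough as vectorized R. Activations are (H, W, C, N) arrays.

.as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3-d or 4-d array")
  x
}

# broadcast a per-channel vector over an (H, W, C, N) array: the rep()
# output (length H*W*C) recycles exactly N times
.bcc <- function(v, hw) rep(v, each = hw)

.channelSum <- function(x) {
  d <- dim(x)
  s <- colSums(matrix(x, nrow = d[1] * d[2]))     # length C*N
  rowSums(matrix(s, nrow = d[3]))                  # length C
}

.convFwd <- function(x, W, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  .conv2d_fw(x, W, b, as.integer(stride), as.integer(pad),
             as.integer(dilation))
}

.convBwd <- function(x, W, dy, stride = 1L, pad = 0L, dilation = 1L,
                     needDx = TRUE, needDb = FALSE) {
  .conv2d_bw(x, W, dy, as.integer(stride), as.integer(pad),
             as.integer(dilation), needDx, needDb)
}

.bnInit <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       rmean = rep(0, channels), rvar = rep(1, channels))
}

.bnEps <- 1e-5
.bnMomentum <- 0.1

# Batch normalization over (H, W, N) per channel. In training mode batch
# statistics are used and the running estimates updated (biased variance
# in the normalization, unbiased in the running estimate); in eval mode
# the running estimates are used.
.bnFwd <- function(x, bn, training = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- hw * d[4]
  if (training) {
    mu <- .channelSum(x) / m
    xc <- x - .bcc(mu, hw)
    v <- .channelSum(xc * xc) / m
    istd <- 1 / sqrt(v + .bnEps)
    xhat <- xc * .bcc(istd, hw)
    y <- xhat * .bcc(bn$gamma, hw) + .bcc(bn$beta, hw)
    ub <- if (m > 1) v * m / (m - 1) else v
    bn$rmean <- (1 - .bnMomentum) * bn$rmean + .bnMomentum * mu
    bn$rvar <- (1 - .bnMomentum) * bn$rvar + .bnMomentum * ub
    list(y = y, bn = bn, cache = list(xhat = xhat, istd = istd, m = m,
                                      hw = hw, gamma = bn$gamma))
  } else {
    istd <- 1 / sqrt(bn$rvar + .bnEps)
    y <- (x - .bcc(bn$rmean, hw)) * .bcc(bn$gamma * istd, hw) +
      .bcc(bn$beta, hw)
    list(y = y, bn = bn, cache = NULL)
  }
}

.bnBwd <- function(cache, dy) {
  hw <- cache$hw
  m <- cache$m
  dbeta <- .channelSum(dy)
  dgamma <- .channelSum(dy * cache$xhat)
  dx <- .bcc(cache$gamma * cache$istd, hw) *
    (dy - .bcc(dbeta / m, hw) - cache$xhat * .bcc(dgamma / m, hw))
  dim(dx) <- dim(dy)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.reluFwd <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

.reluBwd <- function(x, dy) {
  dx <- dy * (x > 0)
  dim(dx) <- dim(dy)
  dx
}

.maxpoolFwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  .maxpool_fw(x, as.integer(k), as.integer(stride), as.integer(pad))
}

.maxpoolBwd <- function(dy, idx, xdim) {
  .maxpool_bw(dy, idx, as.integer(xdim))
}

.upFwd <- function(x) .upsample2x_fw(x)

.upBwd <- function(dy, xdim) .upsample2x_bw(dy, as.integer(xdim))

.sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- squeeze-and-excitation -------------------------------------------

#' Build a squeeze-and-excitation module
#'
#' Channel attention: a global average pool per channel (squeeze), a
#' fully connected bottleneck C -> floor(C/R) (clamped to >= 1) with ReLU,
#' a second fully connected layer back to C, and a sigmoid producing one
#' weight in (0, 1) per channel (excitation) that rescales the channels.
#'
#' @param channels number of input channels C.
#' @param reduction reduction ratio R >= 1; the bottleneck width is
#'   \code{max(1, floor(C / R))}.
#' @param seed optional integer seed for the weight initialization.
#' @return a parameter list with elements \code{W1}, \code{b1}, \code{W2},
#'   \code{b2}, \code{channels}, \code{reduction}.
#' @examples
#' se <- buildSEModule(64, 6, seed = 1)
#' nrow(se$W1) # bottleneck width floor(64/6) = 10
#' @export
buildSEModule <- function(channels, reduction, seed = NULL) {
  stopifnot(channels >= 1, reduction >= 1)
  mid <- max(1L, as.integer(channels %/% reduction))
  if (!is.null(seed)) {
    withSeed(seed, .seInitNew(channels, mid, reduction))
  } else {
    .seInitNew(channels, mid, reduction)
  }
}

.seInitNew <- function(channels, mid, reduction) {
  list(
    W1 = matrix(rnorm(mid * channels, sd = sqrt(2 / channels)), mid,
                channels),
    b1 = rep(0, mid),
    W2 = matrix(rnorm(channels * mid, sd = sqrt(2 / mid)), channels, mid),
    b2 = rep(0, channels),
    channels = as.integer(channels), reduction = as.integer(reduction)
  )
}

#' Apply squeeze-and-excitation channel recalibration
#'
#' @param x an (H, W, C) or (H, W, C, N) activation array.
#' @param se a module from [buildSEModule()] whose \code{channels} matches
#'   C.
#' @param returnWeights if \code{TRUE}, return a list with the rescaled
#'   array and the C x N matrix of channel weights (each strictly in
#'   (0, 1)).
#' @return the rescaled array (same shape as \code{x}), or a list when
#'   \code{returnWeights = TRUE}.
#' @examples
#' x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' se <- buildSEModule(4, 2, seed = 1)
#' y <- seRecalibrate(x, se)
#' dim(y)
#' @export
seRecalibrate <- function(x, se, returnWeights = FALSE) {
  x3 <- is.null(dim(x)) || length(dim(x)) == 3L
  x <- .as4d(x)
  if (dim(x)[3] != se$channels)
    stop("x has ", dim(x)[3], " channels but the SE module expects ",
         se$channels)
  fw <- .seFwd(x, se)
  y <- fw$y
  if (x3) dim(y) <- dim(y)[1:3]
  if (returnWeights) list(y = y, weights = fw$cache$wmat) else y
}

.seFwd <- function(x, se) {
  d <- dim(x)
  hw <- d[1] * d[2]
  smat <- matrix(colSums(matrix(x, nrow = hw)), d[3], d[4]) / hw # C x N
  z1 <- se$W1 %*% smat + se$b1
  a1 <- pmax(z1, 0)
  z2 <- se$W2 %*% a1 + se$b2
  wmat <- .sigmoid(z2)                                           # C x N
  y <- x * .bcc(as.vector(wmat), hw)
  dim(y) <- d
  list(y = y, cache = list(x = x, smat = smat, z1 = z1, a1 = a1,
                           wmat = wmat, hw = hw))
}

.seBwd <- function(cache, dy, se) {
  hw <- cache$hw
  d <- dim(cache$x)
  dwmat <- matrix(colSums(matrix(dy * cache$x, nrow = hw)), d[3], d[4])
  dx <- dy * .bcc(as.vector(cache$wmat), hw)
  dz2 <- dwmat * cache$wmat * (1 - cache$wmat)
  dW2 <- dz2 %*% t(cache$a1)
  db2 <- rowSums(dz2)
  dz1 <- (t(se$W2) %*% dz2) * (cache$z1 > 0)
  dW1 <- dz1 %*% t(cache$smat)
  db1 <- rowSums(dz1)
  dsmat <- t(se$W1) %*% dz1
  dx <- dx + .bcc(as.vector(dsmat), hw) / hw
  dim(dx) <- d
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# He fan-in initialization for a convolution kernel
.heConv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores
#' the previous RNG state afterwards, so seeded package operations do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
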
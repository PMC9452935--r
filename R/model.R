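# Network construction and the forward pass.
#
# Parameters live in nested lists mirroring the architecture:
#   params$encoder$stem          conv (7x7 stride 2) + bn
#   params$encoder$stages[[s]]   list of bottleneck blocks
#   params$decoder[[u]]          upsample/concat unit: reduce (1x1),
#                                conv3 (3x3), bn1, atrous (3x3 dilated),
#                                bn2, se
#   params$head                  1x1 conv to one channel + sigmoid
# Each conv entry carries its own stride/pad/dilation so the forward pass
# needs no external configuration.

.ch <- function(base, w) max(1L, as.integer(round(base * w)))

.channelPlan <- function(config) {
  w <- config@widthMultiplier
  list(
    stem = .ch(64, w),
    mids = vapply(c(64, 128, 256, 512), .ch, integer(1), w = w),
    outs = vapply(c(256, 512, 1024, 2048), .ch, integer(1), w = w),
    dec = vapply(c(1024, 512, 256, 64), .ch, integer(1), w = w)
  )
}

.convParam <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                       dilation = 1L, bias = FALSE) {
  p <- list(W = .heConv(kh, kw, cin, cout), stride = as.integer(stride),
            pad = as.integer(pad), dilation = as.integer(dilation))
  if (bias) p$b <- rep(0, cout)
  p
}

#' Build one bottleneck residual block
#'
#' The residual path is 1x1 conv -> BN -> ReLU -> 3x3 conv -> BN -> ReLU
#' -> 1x1 conv -> BN; the identity path is the input itself when channel
#' counts match and no downsampling occurs, otherwise a projection
#' (strided 1x1 conv + BN). The block output is
#' \code{ReLU(residual + identity)}. With \code{downsample = TRUE} the 3x3
#' conv and the projection use stride 2.
#'
#' @param inChannels,midChannels,outChannels channel counts (>= 1).
#' @param downsample halve the spatial size (stride 2)?
#' @param seed optional seed for weight initialization.
#' @return a block parameter list usable with [residualBlockForward()].
#' @examples
#' blk <- buildResidualBlock(8, 8, 32, seed = 1)
#' x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
#' dim(residualBlockForward(blk, x))
#' @export
buildResidualBlock <- function(inChannels, midChannels, outChannels,
                               downsample = FALSE, seed = NULL) {
  stopifnot(inChannels >= 1, midChannels >= 1, outChannels >= 1)
  build <- function() {
    s <- if (downsample) 2L else 1L
    blk <- list(
      conv1 = .convParam(1, 1, inChannels, midChannels),
      bn1 = .bnInit(midChannels),
      conv2 = .convParam(3, 3, midChannels, midChannels, stride = s,
                         pad = 1L),
      bn2 = .bnInit(midChannels),
      conv3 = .convParam(1, 1, midChannels, outChannels),
      bn3 = .bnInit(outChannels)
    )
    if (downsample || inChannels != outChannels) {
      blk$proj <- list(conv = .convParam(1, 1, inChannels, outChannels,
                                         stride = s),
                       bn = .bnInit(outChannels))
    }
    blk
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

.blockFwd <- function(p, x, training = FALSE, keep = FALSE) {
  c1 <- .convFwd(x, p$conv1$W)
  b1 <- .bnFwd(c1, p$bn1, training)
  r1 <- .reluFwd(b1$y)
  c2 <- .convFwd(r1, p$conv2$W, stride = p$conv2$stride, pad = p$conv2$pad)
  b2 <- .bnFwd(c2, p$bn2, training)
  r2 <- .reluFwd(b2$y)
  c3 <- .convFwd(r2, p$conv3$W)
  b3 <- .bnFwd(c3, p$bn3, training)
  if (!is.null(p$proj)) {
    pc <- .convFwd(x, p$proj$conv$W, stride = p$proj$conv$stride)
    pb <- .bnFwd(pc, p$proj$bn, training)
    idv <- pb$y
  } else {
    pc <- NULL
    pb <- NULL
    idv <- x
  }
  pre <- b3$y + idv
  y <- .reluFwd(pre)
  p$bn1 <- b1$bn; p$bn2 <- b2$bn; p$bn3 <- b3$bn
  if (!is.null(pb)) p$proj$bn <- pb$bn
  cache <- NULL
  if (keep) {
    cache <- list(x = x, b1c = b1$cache, r1in = b1$y, r1 = r1,
                  b2c = b2$cache, r2in = b2$y, r2 = r2, b3c = b3$cache,
                  pbc = if (is.null(pb)) NULL else pb$cache, pre = pre)
  }
  list(y = y, p = p, cache = cache)
}

.blockBwd <- function(p, cache, dy) {
  dpre <- .reluBwd(cache$pre, dy)
  # identity branch
  if (!is.null(p$proj)) {
    pb <- .bnBwd(cache$pbc, dpre)
    pc <- .convBwd(cache$x, p$proj$conv$W, pb$dx,
                   stride = p$proj$conv$stride)
    dxid <- pc$dx
    gproj <- list(conv = list(W = pc$dW),
                  bn = list(gamma = pb$dgamma, beta = pb$dbeta))
  } else {
    dxid <- dpre
    gproj <- NULL
  }
  b3 <- .bnBwd(cache$b3c, dpre)
  c3 <- .convBwd(cache$r2, p$conv3$W, b3$dx)
  dr2 <- .reluBwd(cache$r2in, c3$dx)
  b2 <- .bnBwd(cache$b2c, dr2)
  c2 <- .convBwd(cache$r1, p$conv2$W, b2$dx, stride = p$conv2$stride,
                 pad = p$conv2$pad)
  dr1 <- .reluBwd(cache$r1in, c2$dx)
  b1 <- .bnBwd(cache$b1c, dr1)
  c1 <- .convBwd(cache$x, p$conv1$W, b1$dx)
  dx <- c1$dx + dxid
  g <- list(conv1 = list(W = c1$dW),
            bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
            conv2 = list(W = c2$dW),
            bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
            conv3 = list(W = c3$dW),
            bn3 = list(gamma = b3$dgamma, beta = b3$dbeta))
  if (!is.null(gproj)) g$proj <- gproj
  list(dx = dx, g = g)
}

#' Run one residual block forward
#'
#' @param block a block from [buildResidualBlock()].
#' @param x an (H, W, C) or (H, W, C, N) activation array.
#' @param training use batch statistics in the BN layers?
#' @return the block output array.
#' @export
residualBlockForward <- function(block, x, training = FALSE) {
  x3 <- length(dim(x)) == 3L
  y <- .blockFwd(block, .as4d(x), training = training)$y
  if (x3) dim(y) <- dim(y)[1:3]
  y
}

#' Build the five-stage residual encoder
#'
#' Stage 1 is a 7x7 stride-2 convolution (+ BN + ReLU) followed by 3x3
#' stride-2 max pooling; the classifier's average pool and fully connected
#' layers are absent. Stages 2-5 are residual stages of
#' \code{blockCounts(config)} bottleneck blocks with output channels 256,
#' 512, 1024 and 2048 (times the width multiplier); stages 3-5 downsample
#' by 2 in their first block. The pre-pool stem output is retained as a
#' skip source for the decoder.
#'
#' @param config a [NetworkConfig-class].
#' @param seed optional initialization seed.
#' @return an encoder parameter list usable with [encoderForward()].
#' @export
buildEncoder <- function(config, seed = NULL) {
  validObject(config)
  plan <- .channelPlan(config)
  build <- function() {
    stages <- vector("list", 4L)
    cin <- plan$stem
    for (s in 1:4) {
      n <- config@blockCounts[s]
      blocks <- vector("list", n)
      for (b in seq_len(n)) {
        blocks[[b]] <- buildResidualBlock(
          if (b == 1L) cin else plan$outs[s], plan$mids[s], plan$outs[s],
          downsample = (s > 1L && b == 1L))
      }
      stages[[s]] <- blocks
      cin <- plan$outs[s]
    }
    list(stem = list(conv = .convParam(7, 7, config@inChannels, plan$stem,
                                       stride = 2L, pad = 3L),
                     bn = .bnInit(plan$stem)),
         stages = stages)
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

.encoderFwd <- function(p, x, training = FALSE, keep = FALSE) {
  sc <- .convFwd(x, p$stem$conv$W, stride = 2L, pad = 3L)
  sb <- .bnFwd(sc, p$stem$bn, training)
  s0 <- .reluFwd(sb$y)                       # pre-pool skip
  mp <- .maxpoolFwd(s0)
  p$stem$bn <- sb$bn
  outs <- vector("list", 5L)
  outs[[1]] <- mp$y
  caches <- if (keep) list(stem = list(x = x, bc = sb$cache, rin = sb$y,
                                       idx = mp$idx, s0dim = dim(s0)))
            else NULL
  cur <- mp$y
  for (s in 1:4) {
    bl <- vector("list", length(p$stages[[s]]))
    for (b in seq_along(p$stages[[s]])) {
      r <- .blockFwd(p$stages[[s]][[b]], cur, training, keep)
      p$stages[[s]][[b]] <- r$p
      if (keep) bl[[b]] <- r$cache
      cur <- r$y
    }
    if (keep) caches$stages[[s]] <- bl
    outs[[s + 1]] <- cur
  }
  list(outs = outs, prePool = s0, p = p, cache = caches)
}

# dOuts: list of gradients w.r.t. the five stage outputs; dPrePool:
# gradient flowing into the pre-pool stem activation from the decoder skip.
.encoderBwd <- function(p, cache, dOuts, dPrePool) {
  g <- list(stages = vector("list", 4L))
  dcur <- dOuts[[5]]
  for (s in 4:1) {
    nb <- length(p$stages[[s]])
    gb <- vector("list", nb)
    for (b in nb:1) {
      r <- .blockBwd(p$stages[[s]][[b]], cache$stages[[s]][[b]], dcur)
      gb[[b]] <- r$g
      dcur <- r$dx
    }
    g$stages[[s]] <- gb
    if (s > 1) dcur <- dcur + dOuts[[s]]
  }
  dcur <- dcur + dOuts[[1]]
  ds0 <- .maxpoolBwd(dcur, cache$stem$idx, cache$stem$s0dim) + dPrePool
  dr <- .reluBwd(cache$stem$rin, ds0)
  bb <- .bnBwd(cache$stem$bc, dr)
  cc <- .convBwd(cache$stem$x, p$stem$conv$W, bb$dx, stride = 2L, pad = 3L,
                 needDx = FALSE)
  g$stem <- list(conv = list(W = cc$dW),
                 bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  g
}

#' Run the encoder forward
#'
#' @param encoder an encoder from [buildEncoder()].
#' @param x input array (H, W, C) or (H, W, C, N); H = W divisible by 32.
#' @param training use batch statistics in BN layers?
#' @return a list with \code{stages} (the five stage outputs, the first
#'   being the post-pool stem output) and \code{prePool} (the pre-pool
#'   7x7-conv output used as the innermost skip connection).
#' @export
encoderForward <- function(encoder, x, training = FALSE) {
  x <- .as4d(x)
  if (dim(x)[1] %% 32 != 0 || dim(x)[2] %% 32 != 0)
    stop("input side must be divisible by 32")
  r <- .encoderFwd(encoder, x, training = training)
  list(stages = r$outs, prePool = r$prePool)
}

#' Build one decoder upsampling unit
#'
#' Bilinear 2x upsampling of the incoming map, concatenation with the skip
#' feature, then 1x1 conv -> 3x3 conv -> BN -> ReLU -> 3x3 atrous conv
#' (dilation \code{dilation}, padding preserving size) -> BN -> ReLU ->
#' squeeze-excitation.
#'
#' @param inChannels channels of the incoming (lower-resolution) map.
#' @param skipChannels channels of the encoder skip feature.
#' @param outChannels channels of the unit output.
#' @param dilation atrous dilation rate d (default 2).
#' @param reduction SE reduction ratio R (default 6).
#' @param seed optional initialization seed.
#' @return a unit parameter list usable with [decoderUnitForward()].
#' @export
buildDecoderUnit <- function(inChannels, skipChannels, outChannels,
                             dilation = 2, reduction = 6, seed = NULL) {
  stopifnot(inChannels >= 1, skipChannels >= 1, outChannels >= 1,
            dilation >= 1)
  build <- function() {
    list(
      reduce = .convParam(1, 1, inChannels + skipChannels, outChannels,
                          bias = TRUE),
      conv3 = .convParam(3, 3, outChannels, outChannels, pad = 1L),
      bn1 = .bnInit(outChannels),
      atrous = .convParam(3, 3, outChannels, outChannels,
                          pad = as.integer(dilation),
                          dilation = as.integer(dilation)),
      bn2 = .bnInit(outChannels),
      se = buildSEModule(outChannels, reduction)
    )
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

.catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

.decUnitFwd <- function(p, x, skip, training = FALSE, keep = FALSE) {
  up <- .upFwd(x)
  du <- dim(up); dsk <- dim(skip)
  if (du[1] != dsk[1] || du[2] != dsk[2])
    stop("skip spatial size (", dsk[1], "x", dsk[2],
         ") does not match the upsampled size (", du[1], "x", du[2], ")")
  z <- .catChannels(up, skip)
  r <- .convFwd(z, p$reduce$W, p$reduce$b)
  c3 <- .convFwd(r, p$conv3$W, pad = p$conv3$pad)
  b1 <- .bnFwd(c3, p$bn1, training)
  r1 <- .reluFwd(b1$y)
  at <- .convFwd(r1, p$atrous$W, pad = p$atrous$pad,
                 dilation = p$atrous$dilation)
  b2 <- .bnFwd(at, p$bn2, training)
  r2 <- .reluFwd(b2$y)
  se <- .seFwd(r2, p$se)
  p$bn1 <- b1$bn; p$bn2 <- b2$bn
  cache <- NULL
  if (keep) {
    cache <- list(xdim = dim(x), upC = du[3], z = z, r = r, b1c = b1$cache,
                  r1in = b1$y, r1 = r1, b2c = b2$cache, r2in = b2$y,
                  sec = se$cache)
  }
  list(y = se$y, p = p, cache = cache)
}

.decUnitBwd <- function(p, cache, dy) {
  se <- .seBwd(cache$sec, dy, p$se)
  dr2 <- .reluBwd(cache$r2in, se$dx)
  b2 <- .bnBwd(cache$b2c, dr2)
  at <- .convBwd(cache$r1, p$atrous$W, b2$dx, pad = p$atrous$pad,
                 dilation = p$atrous$dilation)
  dr1 <- .reluBwd(cache$r1in, at$dx)
  b1 <- .bnBwd(cache$b1c, dr1)
  c3 <- .convBwd(cache$r, p$conv3$W, b1$dx, pad = p$conv3$pad)
  rd <- .convBwd(cache$z, p$reduce$W, c3$dx, needDb = TRUE)
  dz <- rd$dx
  upC <- cache$upC
  dup <- dz[, , seq_len(upC), , drop = FALSE]
  dskip <- dz[, , upC + seq_len(dim(dz)[3] - upC), , drop = FALSE]
  dx <- .upBwd(dup, cache$xdim)
  g <- list(reduce = list(W = rd$dW, b = rd$db),
            conv3 = list(W = c3$dW),
            bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
            atrous = list(W = at$dW),
            bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
            se = se$grads)
  list(dx = dx, dskip = dskip, g = g)
}

#' Run one decoder unit forward
#'
#' @param unit a unit from [buildDecoderUnit()].
#' @param x the incoming lower-resolution map, (H, W, C) or (H, W, C, N).
#' @param skip the encoder skip feature at twice the spatial side of
#'   \code{x}.
#' @param training use batch statistics in BN layers?
#' @return the unit output array (out channels, twice the incoming side).
#' @export
decoderUnitForward <- function(unit, x, skip, training = FALSE) {
  x3 <- length(dim(x)) == 3L
  y <- .decUnitFwd(unit, .as4d(x), .as4d(skip), training = training)$y
  if (x3) dim(y) <- dim(y)[1:3]
  y
}

#' Assemble the full segmentation network
#'
#' Encoder (five downsampling units), four decoder units with skip
#' connections from the encoder (block3, block2, block1 outputs and the
#' pre-pool stem output, fused by concatenation after bilinear 2x
#' upsampling), and a head of bilinear 2x upsampling, a 1x1 convolution to
#' one channel and a sigmoid. Every convolution is padded so feature sizes
#' are preserved; all upsampling is bilinear (half-pixel convention),
#' never transposed convolution.
#'
#' @param config a [NetworkConfig-class].
#' @param seed initialization seed (He fan-in for convolutions, unit
#'   scale/zero shift for BN); default 1.
#' @return a [SegmentationNetwork-class] object.
#' @examples
#' net <- assembleNetwork(networkConfig(inputSide = 64,
#'                                      widthMultiplier = 1 / 8), seed = 1)
#' net
#' @export
assembleNetwork <- function(config, seed = 1) {
  validObject(config)
  plan <- .channelPlan(config)
  d <- config@dilationRate
  if (length(d) == 1L) d <- rep(d, 4L)
  params <- withSeed(seed, {
    enc <- buildEncoder(config)
    skips <- c(plan$outs[3], plan$outs[2], plan$outs[1], plan$stem)
    ins <- c(plan$outs[4], plan$dec[1], plan$dec[2], plan$dec[3])
    dec <- lapply(1:4, function(u) {
      buildDecoderUnit(ins[u], skips[u], plan$dec[u], dilation = d[u],
                       reduction = config@seReduction)
    })
    list(encoder = enc, decoder = dec,
         head = .convParam(1, 1, plan$dec[4], 1L, bias = TRUE))
  })
  new("SegmentationNetwork", config = config, params = params)
}

.netFwd <- function(params, x, training = FALSE, keep = FALSE) {
  enc <- .encoderFwd(params$encoder, x, training, keep)
  params$encoder <- enc$p
  skips <- list(enc$outs[[4]], enc$outs[[3]], enc$outs[[2]], enc$prePool)
  cur <- enc$outs[[5]]
  decOuts <- vector("list", 4L)
  decCaches <- if (keep) vector("list", 4L) else NULL
  for (u in 1:4) {
    r <- .decUnitFwd(params$decoder[[u]], cur, skips[[u]], training, keep)
    params$decoder[[u]] <- r$p
    if (keep) decCaches[[u]] <- r$cache
    cur <- r$y
    decOuts[[u]] <- cur
  }
  hu <- .upFwd(cur)
  z <- .convFwd(hu, params$head$W, params$head$b)
  probs <- .sigmoid(z)
  cache <- NULL
  if (keep)
    cache <- list(enc = enc$cache, dec = decCaches, hin = cur,
                  hu = hu, hudim = dim(hu))
  list(probs = probs, z = z, params = params, cache = cache,
       encOuts = enc$outs, prePool = enc$prePool, decOuts = decOuts)
}

# dz: gradient w.r.t. the pre-sigmoid logits
.netBwd <- function(params, cache, dz) {
  hd <- .convBwd(cache$hu, params$head$W, dz, needDb = TRUE)
  dcur <- .upBwd(hd$dx, dim(cache$hin))
  g <- list(head = list(W = hd$dW, b = hd$db), decoder = vector("list", 4L))
  dOuts <- vector("list", 5L)
  dPrePool <- NULL
  for (u in 4:1) {
    r <- .decUnitBwd(params$decoder[[u]], cache$dec[[u]], dcur)
    g$decoder[[u]] <- r$g
    if (u == 4L) dPrePool <- r$dskip
    else dOuts[[5 - u]] <- r$dskip     # u=1 -> stage 4, u=3 -> stage 2
    dcur <- r$dx
  }
  dOuts[[5]] <- dcur
  zero <- function(i) if (is.null(dOuts[[i]])) 0 else dOuts[[i]]
  dOuts[[1]] <- 0
  g$encoder <- .encoderBwd(params$encoder, cache$enc,
                           lapply(1:5, zero), dPrePool)
  g
}

#' Run the assembled network forward
#'
#' Maps a (H, W, 3) or (H, W, 3, N) image array to per-pixel foreground
#' probabilities in [0, 1] of shape (H, W, 1, N).
#'
#' @param model a [SegmentationNetwork-class].
#' @param x input image array; spatial side divisible by 32.
#' @param training use batch statistics in BN layers (for testing layer
#'   behaviour; [trainNetwork()] manages this internally)?
#' @param returnAll if \code{TRUE}, also return every intermediate stage
#'   output: \code{encoderStages} (post-pool stem then the four residual
#'   stages), \code{prePool} (the pre-pool stem activation) and
#'   \code{decoderStages}.
#' @return the probability array, or a list when \code{returnAll = TRUE}
#'   (element \code{probs} plus the stage lists).
#' @export
networkForward <- function(model, x, training = FALSE, returnAll = FALSE) {
  stopifnot(is(model, "SegmentationNetwork"))
  x <- .as4d(x)
  if (dim(x)[1] %% 32 != 0 || dim(x)[2] %% 32 != 0)
    stop("input side must be divisible by 32")
  if (dim(x)[3] != model@config@inChannels)
    stop("input has ", dim(x)[3], " channels; the network expects ",
         model@config@inChannels)
  r <- .netFwd(model@params, x, training = training)
  if (!returnAll) return(r$probs)
  list(probs = r$probs, encoderStages = r$encOuts, prePool = r$prePool,
       decoderStages = r$decOuts)
}

#' Count trainable parameters
#'
#' Convolution kernels and biases, BN scales and shifts, and SE weights;
#' BN running statistics are buffers, not parameters, and are excluded.
#'
#' @param model a [SegmentationNetwork-class].
#' @return the total number of trainable scalars.
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "SegmentationNetwork"))
  sum(vapply(.flattenParams(model@params), length, numeric(1)))
}

# named flat list of trainable leaves; paths like encoder.stem.conv.W or
# decoder.[2].se.W1 (unnamed list entries are indexed)
.nonTrainable <- c("rmean", "rvar", "stride", "pad", "dilation",
                   "channels", "reduction")

.flattenParams <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i]
          else paste0("[", i, "]")
    if (nm %in% .nonTrainable) next
    v <- p[[i]]
    path <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, .flattenParams(v, path))
    else if (is.numeric(v)) out[[path]] <- v
  }
  out
}
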
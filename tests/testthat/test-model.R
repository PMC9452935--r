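test_that("network configuration invariants are enforced", {
  expect_error(networkConfig(inputSide = 100), "32")
  expect_error(networkConfig(blockCounts = c(3, 4, 6)), "4 entries")
  expect_error(networkConfig(seReduction = 0), "seReduction")
  expect_error(networkConfig(widthMultiplier = 0), "widthMultiplier")
  cfg <- networkConfig()
  expect_equal(cfg@blockCounts, c(3L, 4L, 6L, 3L))
  expect_equal(cfg@seReduction, 6L)
  expect_equal(cfg@dilationRate, 2L)
  expect_true(cfg@sigmoidOutput)
})

test_that("a residual block reproduces the bottleneck contract", {
  set.seed(50)
  blk <- buildResidualBlock(8, 8, 32, seed = 1)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  y <- residualBlockForward(blk, x, training = TRUE)
  expect_equal(dim(y), c(16, 16, 32))
  expect_true(all(y >= 0))                      # final ReLU
  # channel plan of the first encoder stage (scaled): 1x1 -> 3x3 -> 1x1
  expect_equal(dim(blk$conv1$W), c(1, 1, 8, 8))
  expect_equal(dim(blk$conv2$W), c(3, 3, 8, 8))
  expect_equal(dim(blk$conv3$W), c(1, 1, 8, 32))
  # projection present because channels change
  expect_false(is.null(blk$proj))
  # stride-2 block halves the spatial side
  blk2 <- buildResidualBlock(8, 8, 16, downsample = TRUE, seed = 2)
  expect_equal(dim(residualBlockForward(blk2, x))[1:2], c(8, 8))
})

test_that("a zeroed residual path reduces the block to ReLU(identity)", {
  blk <- buildResidualBlock(6, 4, 6, seed = 3)   # in == out, no proj
  expect_null(blk$proj)
  blk$conv1$W[] <- 0
  blk$conv2$W[] <- 0
  blk$conv3$W[] <- 0
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  y <- residualBlockForward(blk, x, training = TRUE)
  expect_equal(y, pmax(x, 0), tolerance = 1e-12)
})

test_that("the encoder realizes the block counts and stage shapes", {
  cfg <- networkConfig(inputSide = 64, widthMultiplier = 1 / 8)
  enc <- buildEncoder(cfg, seed = 1)
  expect_equal(vapply(enc$stages, length, integer(1)), c(3L, 4L, 6L, 3L))
  expect_equal(sum(vapply(enc$stages, length, integer(1))), 16L)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- encoderForward(enc, x, training = TRUE)
  sides <- vapply(out$stages, function(s) dim(s)[1], numeric(1))
  expect_equal(sides, c(16, 16, 8, 4, 2))        # 64 / 2^i for i = 2..5
  chans <- vapply(out$stages, function(s) dim(s)[3], numeric(1))
  expect_equal(chans, c(8, 32, 64, 128, 256))    # 64,256,...,2048 / 8
  expect_equal(dim(out$prePool)[1:3], c(32, 32, 8))
  expect_error(encoderForward(enc, array(0, c(60, 60, 3))), "32")
})

test_that("width multiplier scales channels but not spatial sizes", {
  for (w in c(1 / 8, 1 / 4)) {
    cfg <- networkConfig(inputSide = 64, widthMultiplier = w)
    net <- assembleNetwork(cfg, seed = 1)
    out <- networkForward(net, array(runif(64 * 64 * 3), c(64, 64, 3, 1)),
                          training = TRUE, returnAll = TRUE)
    expect_equal(vapply(out$encoderStages, function(s) dim(s)[3],
                        numeric(1)),
                 pmax(1, round(c(64, 256, 512, 1024, 2048) * w)))
    expect_equal(vapply(out$encoderStages, function(s) dim(s)[1],
                        numeric(1)), c(16, 16, 8, 4, 2))
  }
})

test_that("a width-1/8 model has strictly fewer parameters than width 1", {
  n8 <- countParameters(assembleNetwork(
    networkConfig(inputSide = 64, widthMultiplier = 1 / 8), seed = 1))
  n4 <- countParameters(assembleNetwork(
    networkConfig(inputSide = 64, widthMultiplier = 1 / 4), seed = 1))
  expect_lt(n8, n4)
})

test_that("decoder units upsample, fuse skips and recalibrate", {
  unit <- buildDecoderUnit(32, 16, 16, dilation = 2, reduction = 6,
                           seed = 4)
  x <- array(rnorm(4 * 4 * 32), c(4, 4, 32))
  skip <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  y <- decoderUnitForward(unit, x, skip, training = TRUE)
  expect_equal(dim(y), c(8, 8, 16))
  # mismatched skip size is a shape error
  bad <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  expect_error(decoderUnitForward(unit, x, bad, training = TRUE),
               "skip spatial size")
})

test_that("the assembled network maps images to probabilities in [0,1]", {
  cfg <- tinyNetConfig()
  net <- assembleNetwork(cfg, seed = 5)
  for (s in 1:3) {
    set.seed(s)
    x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    p <- networkForward(net, x, training = TRUE)
    expect_equal(dim(p), c(32, 32, 1, 2))
    expect_true(all(is.finite(p)) && all(p >= 0) && all(p <= 1))
  }
  # all-zero input still yields finite probabilities
  p0 <- networkForward(net, array(0, c(32, 32, 3, 1)))
  expect_true(all(is.finite(p0)) && all(p0 >= 0 & p0 <= 1))
})

test_that("SE weights stay in (0,1) across the decoder on random inputs", {
  ns <- asNamespace("leukoseg")
  cfg <- tinyNetConfig()
  net <- assembleNetwork(cfg, seed = 6)
  for (s in 1:10) {
    set.seed(s)
    x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
    fwd <- ns$.netFwd(net@params, x, training = TRUE, keep = TRUE)
    for (u in 1:4) {
      w <- fwd$cache$dec[[u]]$sec$wmat
      expect_true(all(w > 0 & w < 1))
    }
  }
})

test_that("checkpoints round-trip through disk", {
  net <- assembleNetwork(tinyNetConfig(), seed = 7)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- loadCheckpoint(f)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(networkForward(back, x), networkForward(net, x))
  sidecar <- jsonlite::read_json(paste0(f, ".json"),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$widthMultiplier, 1 / 32)
  unlink(c(f, paste0(f, ".json")))
})

test_that("encoder weight archives load back into a matching model", {
  net <- assembleNetwork(tinyNetConfig(), seed = 8)
  f <- tempfile(fileext = ".rds")
  saveEncoderWeights(net, f)
  # perturb, reload: encoder restored, decoder untouched
  other <- assembleNetwork(tinyNetConfig(), seed = 9)
  res <- loadPretrainedEncoder(other, f)
  expect_length(res$report$unmatched, 0)
  expect_length(res$report$missing, 0)
  ns <- asNamespace("leukoseg")
  restored <- ns$.flattenParams(list(encoder = res$model@params$encoder))
  original <- ns$.flattenParams(list(encoder = net@params$encoder))
  expect_equal(restored, original)
  expect_equal(res$model@params$decoder, other@params$decoder)
  # forward contract unchanged after substitution
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p <- networkForward(res$model, x)
  expect_equal(dim(p), c(32, 32, 1, 1))
  # an archive from a different width cannot match
  wide <- assembleNetwork(networkConfig(inputSide = 32,
                                        widthMultiplier = 1 / 8,
                                        blockCounts = c(1, 1, 1, 1)),
                          seed = 10)
  f2 <- tempfile(fileext = ".rds")
  saveEncoderWeights(wide, f2)
  expect_error(loadPretrainedEncoder(net, f2), "width multiplier")
  expect_error(loadPretrainedEncoder(net, tempfile()), "not found")
  unlink(c(f, f2))
})

test_that("network configurations round-trip through YAML and JSON", {
  cfg <- networkConfig(inputSide = 64, widthMultiplier = 1 / 8,
                       dilationRate = c(2, 2, 1, 1), seReduction = 4)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writeNetworkConfig(cfg, f)
    back <- readNetworkConfig(f)
    expect_equal(back@inputSide, 64L)
    expect_equal(back@dilationRate, c(2L, 2L, 1L, 1L))
    expect_equal(back@seReduction, 4L)
    expect_equal(back@widthMultiplier, 1 / 8)
    unlink(f)
  }
})
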
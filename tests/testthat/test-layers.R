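ns <- asNamespace("leukoseg")

test_that("compiled convolution agrees with a direct-loop oracle", {
  set.seed(40)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  cases <- list(c(1, 1, 1), c(2, 1, 1), c(1, 0, 1), c(1, 2, 2),
                c(2, 3, 2))
  for (cs in cases) {
    got <- ns$.convFwd(x, W, b, cs[1], cs[2], cs[3])
    want <- naiveConv(x, W, b, cs[1], cs[2], cs[3])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("dilation spaces the kernel taps d pixels apart", {
  # impulse response: a centred delta reproduces the (flipped) kernel at
  # spacing d; at d = 1 the dilated conv is exactly the ordinary conv
  W <- array(rnorm(9), c(3, 3, 1, 1))
  x <- array(0, c(9, 9, 1, 1))
  x[5, 5, 1, 1] <- 1
  for (d in 1:3) {
    y <- ns$.convFwd(x, W, NULL, 1, d, d)
    expect_equal(dim(y), dim(x))
    for (i in -1:1) for (j in -1:1)
      expect_equal(y[5 - i * d, 5 - j * d, 1, 1], W[i + 2, j + 2, 1, 1],
                   tolerance = 1e-14)
    # taps only at multiples of d from the centre
    nz <- which(abs(y[, , 1, 1]) > 1e-14, arr.ind = TRUE)
    expect_true(all((nz[, 1] - 5) %% d == 0 & (nz[, 2] - 5) %% d == 0))
  }
  set.seed(41)
  xr <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  Wr <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  expect_identical(ns$.convFwd(xr, Wr, NULL, 1L, 1L, 1L),
                   ns$.convFwd(xr, Wr, NULL, 1L, 1L, 1L))
})

test_that("conv/pool/upsample backward passes match finite differences", {
  set.seed(42)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  W <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  fd <- function(f, v, eps = 1e-6) {
    g <- array(0, dim(v))
    for (i in seq_along(v)) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      g[i] <- (f(vp) - f(vm)) / (2 * eps)
    }
    g
  }
  y <- ns$.convFwd(x, W, b, 1, 1, 2)
  dy <- array(rnorm(length(y)), dim(y))
  bw <- ns$.convBwd(x, W, dy, 1, 1, 2, TRUE, TRUE)
  expect_equal(bw$dx, fd(function(v) sum(ns$.convFwd(v, W, b, 1, 1, 2) * dy), x),
               tolerance = 1e-6)
  expect_equal(bw$dW, fd(function(v) sum(ns$.convFwd(x, v, b, 1, 1, 2) * dy), W),
               tolerance = 1e-6)
  mp <- ns$.maxpoolFwd(x)
  dyp <- array(rnorm(length(mp$y)), dim(mp$y))
  expect_equal(ns$.maxpoolBwd(dyp, mp$idx, dim(x)),
               fd(function(v) sum(ns$.maxpoolFwd(v)$y * dyp), x),
               tolerance = 1e-5)
  u <- ns$.upFwd(x)
  dyu <- array(rnorm(length(u)), dim(u))
  expect_equal(ns$.upBwd(dyu, dim(x)),
               fd(function(v) sum(ns$.upFwd(v) * dyu), x),
               tolerance = 1e-6)
})

test_that("bilinear 2x upsampling preserves constants and doubles sides", {
  x <- array(3.5, c(5, 7, 2, 1))
  u <- ns$.upFwd(x)
  expect_equal(dim(u), c(10, 14, 2, 1))
  expect_true(all(abs(u - 3.5) < 1e-12))
})

test_that("batch norm normalizes in training mode and matches FD backward", {
  set.seed(43)
  x <- array(rnorm(5 * 5 * 3 * 4, mean = 2, sd = 3), c(5, 5, 3, 4))
  bn <- ns$.bnInit(3)
  fw <- ns$.bnFwd(x, bn, training = TRUE)
  for (c in 1:3) {
    expect_equal(mean(fw$y[, , c, ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(fw$y[, , c, ])) *
                   sqrt(99 / 100), 1, tolerance = 1e-3)
  }
  dy <- array(rnorm(length(x)), dim(x))
  bwd <- ns$.bnBwd(fw$cache, dy)
  eps <- 1e-5
  i <- 17
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  num <- (sum(ns$.bnFwd(xp, bn, TRUE)$y * dy) -
            sum(ns$.bnFwd(xm, bn, TRUE)$y * dy)) / (2 * eps)
  expect_equal(bwd$dx[i], num, tolerance = 1e-4)
})

test_that("SE weights lie strictly in (0,1) and rescale channels", {
  set.seed(44)
  for (s in 1:10) {
    x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
    se <- buildSEModule(6, 2, seed = s)
    out <- seRecalibrate(x, se, returnWeights = TRUE)
    expect_true(all(out$weights > 0 & out$weights < 1))
    expect_equal(dim(out$y), dim(x))
    # output is the channel-wise rescale of the input
    for (c in 1:6)
      expect_equal(out$y[, , c], x[, , c] * out$weights[c, 1],
                   tolerance = 1e-12)
  }
})

test_that("SE with zeroed weights halves every channel", {
  se <- buildSEModule(4, 2, seed = 1)
  se$W1[] <- 0; se$b1[] <- 0; se$W2[] <- 0; se$b2[] <- 0
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  expect_equal(seRecalibrate(x, se), 0.5 * x, tolerance = 1e-12)
})

test_that("SE bottleneck width floors C/R and clamps to >= 1", {
  expect_equal(nrow(buildSEModule(64, 6)$W1), 10)   # floor(64/6)
  expect_equal(nrow(buildSEModule(4, 6)$W1), 1)     # clamped
  expect_equal(nrow(buildSEModule(12, 4)$W1), 3)
})

test_that("SE backward matches finite differences", {
  set.seed(45)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  se <- buildSEModule(3, 2, seed = 2)
  fw <- ns$.seFwd(x, se)
  dy <- array(rnorm(length(x)), dim(x))
  bw <- ns$.seBwd(fw$cache, dy, se)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(ns$.seFwd(xp, se)$y * dy) -
              sum(ns$.seFwd(xm, se)$y * dy)) / (2 * eps)
    expect_equal(bw$dx[i], num, tolerance = 1e-5)
  }
  for (i in sample(length(se$W1), 3)) {
    sp <- se; sp$W1[i] <- sp$W1[i] + eps
    sm <- se; sm$W1[i] <- sm$W1[i] - eps
    num <- (sum(ns$.seFwd(x, sp)$y * dy) -
              sum(ns$.seFwd(x, sm)$y * dy)) / (2 * eps)
    expect_equal(bw$grads$W1[i], num, tolerance = 1e-5)
  }
})
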
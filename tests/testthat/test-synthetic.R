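test_that("scene generation is a pure function of its seed", {
  cfg <- sceneConfig(side = 64, seed = 123)
  a <- generateCellImage(cfg)
  b <- generateCellImage(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generateCellImage(sceneConfig(side = 64, seed = 124))
  expect_false(identical(a$image, c$image))
})

test_that("mask foreground fraction tracks the configured radius range", {
  # area of the generating ellipse: pi * r^2 with r in [0.15, 0.35] of
  # the side, so the foreground fraction must stay near [0.071, 0.385]
  fr <- vapply(1:20, function(s) {
    mean(generateCellImage(sceneConfig(side = 64, seed = s))$mask)
  }, numeric(1))
  expect_true(all(fr > 0.05 & fr < 0.42))
  expect_true(mean(fr >= 0.071 & fr <= 0.385) >= 0.9)
})

test_that("zero boundary irregularity yields an exact ellipse", {
  cfg <- sceneConfig(side = 64, boundaryIrregularity = 0, seed = 9)
  out <- generateCellImage(cfg)
  g <- out$meta
  recomputed <- matrix(0L, 64, 64)
  for (r in 1:64) for (c in 1:64) {
    recomputed[r, c] <- as.integer(
      ((c - g$center[1]) / g$axes[1])^2 +
        ((r - g$center[2]) / g$axes[2])^2 <= 1)
  }
  expect_equal(out$mask, recomputed)
})

test_that("one connected cell per image with mask = rendered support", {
  for (s in 1:5) {
    out <- generateCellImage(sceneConfig(side = 64, seed = s))
    expect_equal(oracleComponentCount(out$mask, 8), 1)
    expect_true(all(out$mask %in% c(0L, 1L)))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("lower color proximity weakens the mask-boundary contrast", {
  edgeContrast <- function(prox, seed) {
    out <- generateCellImage(sceneConfig(side = 64,
                                         colorProximity = prox,
                                         nucleusContrast = 0,
                                         seed = seed))
    m <- out$mask
    dil <- pmax(rbind(m[-1, ], 0), rbind(0, m[-nrow(m), ]),
                cbind(m[, -1], 0), cbind(0, m[, -ncol(m)]), m)
    outer <- dil == 1 & m == 0
    lum <- apply(out$image, c(1, 2), mean)
    abs(mean(lum[m == 1]) - mean(lum[outer]))
  }
  proxes <- c(0.30, 0.15, 0.05)
  mc <- vapply(proxes, function(p) {
    mean(vapply(1:10, function(s) edgeContrast(p, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mc) < 0))
})

test_that("geometric augmentations move image and mask together", {
  pair <- generateCellImage(sceneConfig(side = 64, seed = 31))
  # flips are involutions
  for (op in c("hflip", "vflip")) {
    once <- augmentPair(pair$image, pair$mask, augmentationSpec(ops = op))
    twice <- augmentPair(once$image, once$mask, augmentationSpec(ops = op))
    expect_identical(twice$image, pair$image)
    expect_identical(twice$mask, pair$mask)
  }
  # grid-aligned rotation preserves mask area exactly
  spec90 <- augmentationSpec(ops = "rotation", rotationRange = c(90, 90))
  rot <- augmentPair(pair$image, pair$mask, spec90)
  expect_equal(sum(rot$mask), sum(pair$mask))
  expect_true(all(rot$mask %in% c(0L, 1L)))
  # photometric ops leave the mask bit-identical
  bright <- augmentPair(pair$image, pair$mask,
                        augmentationSpec(ops = "brightness", seed = 5))
  expect_false(identical(bright$image, pair$image))
  expect_identical(bright$mask, pair$mask)
  contrast <- augmentPair(pair$image, pair$mask,
                          augmentationSpec(ops = "contrast", seed = 6))
  expect_identical(contrast$mask, pair$mask)
  # unknown ops are rejected at construction
  expect_error(augmentationSpec(ops = "shear"), "unknown")
  # augmentation is seed-deterministic
  s1 <- augmentPair(pair$image, pair$mask, augmentationSpec(seed = 77))
  s2 <- augmentPair(pair$image, pair$mask, augmentationSpec(seed = 77))
  expect_identical(s1, s2)
})

test_that("masks stay strictly binary through arbitrary augmentation", {
  pair <- generateCellImage(sceneConfig(side = 48, seed = 41))
  for (s in 1:10) {
    aug <- augmentPair(pair$image, pair$mask, augmentationSpec(seed = s))
    expect_true(all(aug$mask %in% c(0L, 1L)))
    expect_equal(dim(aug$image), dim(pair$image))
  }
})

test_that("dataset expansion cycles sources round-robin with provenance", {
  ds <- generateDataset(7, sceneConfig(side = 32), seed = 3)
  big <- expandDataset(ds, 23, augmentationSpec(seed = 1))
  expect_length(big$images, 23)
  counts <- table(big$meta$source)
  expect_true(all(counts %in% c(floor(23 / 7), ceiling(23 / 7))))
  expect_true(all(vapply(big$masks,
                         function(m) all(m %in% c(0L, 1L)), logical(1))))
  # target equal to input returns the originals unchanged
  same <- expandDataset(ds, 7, augmentationSpec(seed = 1))
  expect_identical(same$images, ds$images)
  expect_error(expandDataset(list(images = list(), masks = list()), 5),
               "empty")
})

test_that("the 8:1:1 split is disjoint, exhaustive and correctly sized", {
  ds <- generateDataset(10, sceneConfig(side = 32), seed = 4)
  sp <- splitDataset(ds, seed = 4)
  expect_equal(vapply(sp, function(d) length(d$images), integer(1)),
               c(train = 8L, val = 1L, test = 1L))
  idx <- unlist(lapply(sp, function(d) d$meta$index))
  expect_setequal(idx, 1:10)
  expect_equal(anyDuplicated(idx), 0)
  # proportions at larger n
  ds2 <- generateDataset(50, sceneConfig(side = 32), seed = 5)
  sp2 <- splitDataset(ds2, seed = 5)
  expect_equal(vapply(sp2, function(d) length(d$images), integer(1)),
               c(train = 40L, val = 5L, test = 5L))
  expect_error(splitDataset(list(images = list(1), masks = list(1))),
               "at least")
})

test_that("datasets survive a PNG round trip", {
  ds <- generateDataset(3, sceneConfig(side = 32), seed = 6)
  dir <- file.path(tempdir(), "lk-ds-test")
  writeDataset(ds, dir)
  back <- readDataset(dir)
  expect_length(back$images, 3)
  for (i in 1:3) {
    expect_identical(back$masks[[i]], ds$masks[[i]])
    # 8-bit PNG quantization: intensities within 1/255
    expect_lt(max(abs(back$images[[i]] - ds$images[[i]])), 1 / 254)
  }
  unlink(dir, recursive = TRUE)
})
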
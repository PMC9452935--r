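# Synthetic single-cell scenes: one roughly elliptical cell whose
# cytoplasm color sits a configurable RGB distance from the background
# (small distance = the hard lymphocyte/monocyte case), with 1-3 darker
# nucleus lobes, a textured background, a multiplicative brightness
# gradient and Gaussian blur. The ground-truth mask is the exact pre-blur
# cell support, so the label is unambiguous at blurred boundaries.
#
# Images are (H, W, 3) arrays in [0, 1]; masks are 0/1 integer matrices.

#' Generate one synthetic cell image with its mask
#'
#' Renders a star-convex perturbed ellipse (radius modulated by random
#' low-order harmonics, normalized to preserve area, clamped to
#' [0.7, 1.25] of the base radius) filled with cytoplasm color at
#' \code{colorProximity(config)} RGB distance from the background, plus
#' 1-3 darker nucleus lobes. The base ellipse is axis-aligned; orientation
#' diversity comes from rotation augmentation. The same seed always yields
#' a bit-identical pair.
#'
#' @param config a [SceneConfig-class].
#' @return a list with \code{image} (H, W, 3 array in [0, 1]), \code{mask}
#'   (0/1 integer matrix, the pre-blur cell support) and \code{meta}
#'   (sampled geometry and colors, for provenance).
#' @examples
#' pair <- generateCellImage(sceneConfig(side = 64, seed = 3))
#' mean(pair$mask) # foreground fraction
#' @export
generateCellImage <- function(config = sceneConfig()) {
  validObject(config)
  withSeed(config@seed, .renderScene(config))
}

.renderScene <- function(config) {
  s <- config@side
  prox <- config@colorProximity

  # colors: background base, cytoplasm at the configured RGB distance
  bgCol <- runif(3, 0.60, 0.85)
  cytoCol <- NULL
  for (i in 1:100) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    cand <- bgCol + prox * u
    if (all(cand >= 0.02 & cand <= 0.98)) {
      cytoCol <- cand
      break
    }
  }
  if (is.null(cytoCol)) cytoCol <- pmin(pmax(bgCol + prox * u, 0.02), 0.98)
  nucCol <- pmax(cytoCol - config@nucleusContrast * c(0.55, 0.8, 0.35),
                 0.02)

  # geometry: area-preserving eccentric ellipse, harmonically perturbed
  ctr <- s / 2 + runif(2, -0.05, 0.05) * s      # (cx, cy)
  r0 <- runif(1, config@cellRadiusRange[1], config@cellRadiusRange[2]) * s
  ecc <- runif(1, -0.2, 0.2)
  ax <- r0 * exp(ecc)
  ay <- r0 * exp(-ecc)
  nGrid <- 720L
  thGrid <- seq(-pi, pi, length.out = nGrid + 1L)[-(nGrid + 1L)]
  rho <- rep(1, nGrid)
  if (config@boundaryIrregularity > 0) {
    for (m in 2:6) {
      am <- rnorm(1, sd = 0.5 / m)
      bm <- rnorm(1, sd = 0.5 / m)
      rho <- rho + config@boundaryIrregularity *
        (am * cos(m * thGrid) + bm * sin(m * thGrid))
    }
    rho <- rho / sqrt(mean(rho^2))               # keep the enclosed area
    rho <- pmin(pmax(rho, 0.7), 1.25)
  }

  xs <- matrix(rep(seq_len(s), each = s), s, s) - ctr[1]   # column - cx
  ys <- matrix(rep(seq_len(s), s), s, s) - ctr[2]          # row - cy
  rad <- sqrt((xs / ax)^2 + (ys / ay)^2)
  th <- atan2(ys, xs)
  idx <- (round((th + pi) / (2 * pi) * nGrid) %% nGrid) + 1L
  inside <- rad <= rho[idx]
  mask <- matrix(as.integer(inside), s, s)

  # nucleus lobes, clipped to the cell support
  nLobes <- sample(1:3, 1)
  nucMask <- matrix(FALSE, s, s)
  for (k in seq_len(nLobes)) {
    om <- runif(1, 0, 2 * pi)
    dfrac <- runif(1, 0, 0.35) * r0
    lc <- ctr + dfrac * c(cos(om), sin(om))
    rn <- runif(1, 0.22, 0.40) * r0
    en <- runif(1, -0.15, 0.15)
    lobe <- ((xs + ctr[1] - lc[1]) / (rn * exp(en)))^2 +
      ((ys + ctr[2] - lc[2]) / (rn * exp(-en)))^2 <= 1
    nucMask <- nucMask | lobe
  }
  nucMask <- nucMask & inside

  # compose channels with texture, brightness field, blur
  coarse <- matrix(rnorm(36, sd = 0.025), 6, 6)
  lowFreq <- .bilinearResize(coarse, s, s)
  img <- array(0, c(s, s, 3))
  fine <- matrix(rnorm(s * s, sd = 0.01), s, s)
  cytoTex <- matrix(rnorm(s * s, sd = 0.015), s, s)
  for (ch in 1:3) {
    plane <- bgCol[ch] + lowFreq + fine
    plane[inside] <- cytoCol[ch] + cytoTex[inside]
    plane[nucMask] <- nucCol[ch] + cytoTex[nucMask]
    img[, , ch] <- plane
  }
  psi <- runif(1, 0, 2 * pi)
  ramp <- ((xs * cos(psi) + ys * sin(psi)) / s)   # roughly [-0.5, 0.5]
  field <- (1 + runif(1, -config@brightnessJitter,
                      config@brightnessJitter)) *
    (1 + 2 * config@brightnessJitter * ramp)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * field
  if (config@blurSigma > 0) {
    for (ch in 1:3)
      img[, , ch] <- EBImage::gblur(img[, , ch], sigma = config@blurSigma)
  }
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(s, s, 3)

  list(image = img, mask = mask,
       meta = list(bgCol = bgCol, cytoCol = cytoCol, nucCol = nucCol,
                   center = ctr, radius = r0, axes = c(ax, ay),
                   rho = rho, seed = config@seed))
}

.bilinearResize <- function(m, h, w) {
  sr <- (seq_len(h) - 0.5) / h * nrow(m) + 0.5
  sc <- (seq_len(w) - 0.5) / w * ncol(m) + 0.5
  r0 <- pmin(pmax(floor(sr), 1), nrow(m))
  r1 <- pmin(r0 + 1, nrow(m))
  wr <- pmin(pmax(sr - r0, 0), 1)
  c0 <- pmin(pmax(floor(sc), 1), ncol(m))
  c1 <- pmin(c0 + 1, ncol(m))
  wc <- pmin(pmax(sc - c0, 0), 1)
  top <- m[r0, c0, drop = FALSE] * (1 - wc)[col(matrix(0, h, w))] +
    m[r0, c1, drop = FALSE] * wc[col(matrix(0, h, w))]
  bot <- m[r1, c0, drop = FALSE] * (1 - wc)[col(matrix(0, h, w))] +
    m[r1, c1, drop = FALSE] * wc[col(matrix(0, h, w))]
  top * (1 - wr)[row(matrix(0, h, w))] + bot * wr[row(matrix(0, h, w))]
}

#' Generate a synthetic dataset
#'
#' Renders \code{n} independent scenes from per-image seeds derived
#' deterministically from \code{seed}.
#'
#' @param n number of image/mask pairs.
#' @param scene a [SceneConfig-class] template (its own seed is ignored).
#' @param seed integer master seed.
#' @return a dataset: list with \code{images}, \code{masks} (parallel
#'   lists) and \code{meta} (data.frame of per-image seeds).
#' @export
generateDataset <- function(n, scene = sceneConfig(), seed = 1) {
  stopifnot(n >= 1)
  seeds <- (as.numeric(seed) * 7919 + seq_len(n) * 104729) %% 2147483647
  pairs <- lapply(seeds, function(si) {
    scene@seed <- as.integer(si)
    generateCellImage(scene)
  })
  list(images = lapply(pairs, `[[`, "image"),
       masks = lapply(pairs, `[[`, "mask"),
       meta = data.frame(index = seq_len(n), seed = as.integer(seeds),
                         source = seq_len(n), augmented = FALSE))
}

# ---- augmentation ------------------------------------------------------

# inverse-mapped affine warp (rotation by `angle` degrees about the image
# center, isotropic `scale`), bilinear or nearest-neighbour sampling
.warpAffine <- function(img, angle = 0, scale = 1,
                        filter = c("bilinear", "nearest"), bg = 0) {
  filter <- match.arg(filter)
  d <- dim(img)
  h <- d[1]
  w <- d[2]
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  th <- angle * pi / 180
  u <- matrix(rep(seq_len(w), each = h), h, w) - cx
  v <- matrix(rep(seq_len(h), w), h, w) - cy
  # inverse of scale * R(th)
  su <- (cos(th) * u + sin(th) * v) / scale
  sv <- (-sin(th) * u + cos(th) * v) / scale
  sc <- su + cx
  sr <- sv + cy
  nchan <- if (length(d) == 3L) d[3] else 1L
  out <- array(bg, dim = if (length(d) == 3L) d else c(h, w))
  if (filter == "nearest") {
    rr <- round(sr)
    cc <- round(sc)
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- cbind(rr[ok], cc[ok])
    for (ch in seq_len(nchan)) {
      plane <- matrix(bg, h, w)
      src <- if (length(d) == 3L) img[, , ch] else img
      plane[ok] <- src[idx]
      if (length(d) == 3L) out[, , ch] <- plane else out <- plane
    }
  } else {
    r0 <- floor(sr)
    c0 <- floor(sc)
    wr <- sr - r0
    wc <- sc - c0
    for (ch in seq_len(nchan)) {
      src <- if (length(d) == 3L) img[, , ch] else img
      fetch <- function(r, c) {
        ok <- r >= 1 & r <= h & c >= 1 & c <= w
        val <- matrix(bg, h, w)
        val[ok] <- src[cbind(r[ok], c[ok])]
        val
      }
      plane <- (1 - wr) * ((1 - wc) * fetch(r0, c0) + wc * fetch(r0, c0 + 1)) +
        wr * ((1 - wc) * fetch(r0 + 1, c0) + wc * fetch(r0 + 1, c0 + 1))
      if (length(d) == 3L) out[, , ch] <- plane else out <- plane
    }
  }
  out
}

#' Augment an image/mask pair
#'
#' Applies the operations of \code{spec} in order. Geometric operations
#' (rotation, flips, scaling) transform image and mask identically, the
#' mask with nearest-neighbour sampling so it stays strictly binary;
#' photometric operations (brightness, contrast) change the image only.
#' Parameters are drawn from the spec's ranges under its seed, so the
#' same spec always produces the same augmentation.
#'
#' @param image (H, W, 3) array in [0, 1].
#' @param mask 0/1 matrix of matching spatial shape.
#' @param spec an [AugmentationSpec-class].
#' @return a list with the augmented \code{image} and \code{mask}.
#' @examples
#' pair <- generateCellImage(sceneConfig(side = 64, seed = 5))
#' aug <- augmentPair(pair$image, pair$mask,
#'                    augmentationSpec(ops = "hflip"))
#' @export
augmentPair <- function(image, mask, spec = augmentationSpec()) {
  validObject(spec)
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask shapes do not match", call. = FALSE)
  if (any(mask != 0 & mask != 1))
    stop("mask must be strictly binary (0/1)", call. = FALSE)
  withSeed(spec@seed, {
    for (op in spec@ops) {
      bgfill <- mean(c(image[1, , ], image[dim(image)[1], , ]))
      if (op == "rotation") {
        ang <- runif(1, spec@rotationRange[1], spec@rotationRange[2])
        image <- .warpAffine(image, angle = ang, bg = bgfill)
        mask <- .warpAffine(mask, angle = ang, filter = "nearest", bg = 0)
      } else if (op == "hflip") {
        image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
        mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
      } else if (op == "vflip") {
        image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
        mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
      } else if (op == "scaling") {
        sc <- runif(1, spec@scaleRange[1], spec@scaleRange[2])
        image <- .warpAffine(image, scale = sc, bg = bgfill)
        mask <- .warpAffine(mask, scale = sc, filter = "nearest", bg = 0)
      } else if (op == "brightness") {
        delta <- runif(1, spec@brightnessRange[1], spec@brightnessRange[2])
        image <- pmin(pmax(image + delta, 0), 1)
      } else if (op == "contrast") {
        f <- runif(1, spec@contrastRange[1], spec@contrastRange[2])
        mu <- mean(image)
        image <- pmin(pmax((image - mu) * f + mu, 0), 1)
      }
    }
    storage.mode(mask) <- "integer"
    list(image = image, mask = mask)
  })
}

#' Expand a dataset to a target size by seeded augmentation
#'
#' Keeps the original pairs, then cycles the sources round-robin through
#' augmentations (so every source is used \code{floor(targetN/n)} or
#' \code{ceiling(targetN/n)} times) until \code{targetN} pairs exist.
#' Provenance (source index, augmentation seed) is recorded per item.
#'
#' @param dataset a dataset from [generateDataset()] (lists \code{images},
#'   \code{masks}, data.frame \code{meta}).
#' @param targetN desired number of pairs, at least the input size.
#' @param spec an [AugmentationSpec-class]; item i uses seed
#'   \code{seed(spec) + i}.
#' @return the expanded dataset with provenance in \code{meta}.
#' @export
expandDataset <- function(dataset, targetN, spec = augmentationSpec()) {
  n0 <- length(dataset$images)
  if (n0 == 0L) stop("dataset is empty", call. = FALSE)
  if (targetN < n0)
    stop("targetN must be at least the input size", call. = FALSE)
  if (targetN == n0) return(dataset)
  images <- c(dataset$images, vector("list", targetN - n0))
  masks <- c(dataset$masks, vector("list", targetN - n0))
  src <- integer(targetN)
  sd <- integer(targetN)
  src[seq_len(n0)] <- seq_len(n0)
  for (i in (n0 + 1L):targetN) {
    s <- ((i - n0 - 1L) %% n0) + 1L
    ispec <- spec
    ispec@seed <- spec@seed + i
    aug <- augmentPair(dataset$images[[s]], dataset$masks[[s]], ispec)
    images[[i]] <- aug$image
    masks[[i]] <- aug$mask
    src[i] <- s
    sd[i] <- ispec@seed
  }
  list(images = images, masks = masks,
       meta = data.frame(index = seq_len(targetN), seed = sd,
                         source = src,
                         augmented = seq_len(targetN) > n0))
}

#' Split a dataset into train/validation/test partitions
#'
#' Seeded random shuffle, then a contiguous partition by the given
#' proportions with floor-then-distribute rounding (remainders go to the
#' partitions with the largest fractional parts, earlier partitions
#' first on ties). Partitions are disjoint and exhaustive.
#'
#' @param dataset a dataset (lists \code{images}, \code{masks}, data.frame
#'   \code{meta}).
#' @param ratios three positive weights, default \code{c(8, 1, 1)}.
#' @param seed shuffle seed.
#' @return a list with datasets \code{train}, \code{val}, \code{test};
#'   each carries its original indices in \code{meta$index}.
#' @examples
#' ds <- generateDataset(10, sceneConfig(side = 32), seed = 1)
#' sp <- splitDataset(ds, seed = 1)
#' vapply(sp, function(d) length(d$images), integer(1)) # 8, 1, 1
#' @export
splitDataset <- function(dataset, ratios = c(8, 1, 1), seed = 1) {
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("ratios must be three positive weights", call. = FALSE)
  n <- length(dataset$images)
  if (n < 3L)
    stop("need at least as many items as partitions", call. = FALSE)
  perm <- withSeed(seed, sample.int(n))
  raw <- n * ratios / sum(ratios)
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- raw - sizes
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  # every partition must be non-empty
  for (k in which(sizes == 0)) {
    donor <- which.max(sizes)
    sizes[donor] <- sizes[donor] - 1L
    sizes[k] <- sizes[k] + 1L
  }
  bounds <- cumsum(sizes)
  idx <- list(train = perm[seq_len(bounds[1])],
              val = perm[(bounds[1] + 1L):bounds[2]],
              test = perm[(bounds[2] + 1L):bounds[3]])
  lapply(idx, function(i) .subsetDataset(dataset, sort(i)))
}

.subsetDataset <- function(ds, idx) {
  list(images = ds$images[idx], masks = ds$masks[idx],
       meta = ds$meta[idx, , drop = FALSE])
}

#' Write a dataset to disk
#'
#' Layout: \code{images/NNNN.png} (RGB), \code{masks/NNNN.png}
#' (single-channel 0/255) and \code{manifest.json} with per-item
#' provenance.
#'
#' @param dataset a dataset.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  n <- length(dataset$images)
  for (i in seq_len(n)) {
    nm <- sprintf("%04d.png", i)
    img <- dataset$images[[i]]
    EBImage::writeImage(
      EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
      file.path(dir, "images", nm), type = "png")
    writeMaskPNG(dataset$masks[[i]], file.path(dir, "masks", nm))
  }
  jsonlite::write_json(list(n = n, meta = dataset$meta),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @return a dataset (lists \code{images}, \code{masks}, data.frame
#'   \code{meta}).
#' @export
readDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  n <- man$n
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- sprintf("%04d.png", i)
    raw <- EBImage::readImage(file.path(dir, "images", nm))
    images[[i]] <- aperm(raw, c(2, 1, 3))
    masks[[i]] <- readMaskPNG(file.path(dir, "masks", nm))
  }
  list(images = images, masks = masks, meta = as.data.frame(man$meta))
}
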
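# Independent brute-force oracles used to validate the package's
# vectorized/compiled implementations on small inputs.

# direct quadruple-loop 2-d convolution (cross-correlation) oracle
naiveConv <- function(x, W, b = NULL, stride = 1, pad = 0, dil = 1) {
  d <- dim(x)
  H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(W)
  kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  Ho <- (H + 2 * pad - ((kh - 1) * dil + 1)) %/% stride + 1
  Wo <- (W_ + 2 * pad - ((kw - 1) * dil + 1)) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (o in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (is.null(b)) 0 else b[o]
    for (c in 1:C) for (i in 1:kh) for (j in 1:kw) {
      hi <- (ho - 1) * stride - pad + (i - 1) * dil + 1
      wi <- (wo - 1) * stride - pad + (j - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W_)
        acc <- acc + x[hi, wi, c, n] * W[i, j, c, o]
    }
    y[ho, wo, o, n] <- acc
  }
  y
}

# pixel-set metric oracles over coordinate lists
oracleMetrics <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  safe <- function(num, den) {
    if (den == 0) {
      if (length(A) == 0 && length(B) == 0) 1 else 0
    } else num / den
  }
  list(dice = safe(2 * inter, length(A) + length(B)),
       iou = safe(inter, uni),
       ppv = safe(inter, length(A)),
       se = safe(inter, length(B)))
}

# double loop over all point pairs
oracleHausdorff <- function(a, b, symmetric = FALSE) {
  pa <- which(a == 1, arr.ind = TRUE)
  pb <- which(b == 1, arr.ind = TRUE)
  directed <- function(p, q) {
    m <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      m <- max(m, best)
    }
    m
  }
  h <- directed(pa, pb)
  if (symmetric) max(h, directed(pb, pa)) else h
}

# recursive flood fill component counter (independent of the package's
# compiled labeller)
oracleComponentCount <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else rbind(cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)),
             cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)))
  count <- 0
  for (sc in seq_len(w)) for (sr in seq_len(h)) {
    if (mask[sr, sc] == 0 || seen[sr, sc]) next
    count <- count + 1
    queue <- matrix(c(sr, sc), 1, 2)
    seen[sr, sc] <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] == 1 && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  count
}

randomMask <- function(side, p = 0.5) {
  matrix(rbinom(side * side, 1, p), side, side)
}

# a small blob mask: disc of radius r centred at (cy, cx)
discMask <- function(side, cy, cx, r) {
  m <- matrix(0L, side, side)
  for (i in seq_len(side)) for (j in seq_len(side))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
  m
}

tinyNetConfig <- function(side = 32, width = 1 / 32)
  networkConfig(inputSide = side, widthMultiplier = width,
                blockCounts = c(1, 1, 1, 1))
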
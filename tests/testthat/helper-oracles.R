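# Independent oracles and fixture builders shared across the suite.
# Everything is generated in code; no stored fixtures.

# Brute-force box count: scan every r-cell with a triple loop.
# Deliberately naive and independent of the package implementation.
bruteBoxCount <- function(arr, r) {
  d <- dim(arr)
  n <- 0L
  for (i in seq(1, d[1], by = r))
    for (j in seq(1, d[2], by = r))
      for (k in seq(1, d[3], by = r)) {
        sub <- arr[i:min(i + r - 1, d[1]),
                   j:min(j + r - 1, d[2]),
                   k:min(k + r - 1, d[3])]
        if (any(sub == 1)) n <- n + 1L
      }
  n
}

randomMask <- function(seed, maxDim = 32L, p = 0.2) {
  set.seed(seed)
  d <- sample(4:maxDim, 3, replace = TRUE)
  a <- array(as.integer(runif(prod(d)) < p), dim = d)
  if (sum(a) == 0L) a[1, 1, 1] <- 1L
  VoxelGrid(a, affineMeta = list(lrAxis = 1L))
}

mkBall <- function(n, rad, center = rep((n + 1) / 2, 3)) {
  d2x <- lapply(1:3, function(ax) (seq_len(n) - center[ax])^2)
  a <- array(0L, c(n, n, n))
  for (z in seq_len(n)) {
    rz <- rad^2 - d2x[[3]][z]
    if (rz < 0) next
    a[, , z] <- as.integer(outer(d2x[[1]], d2x[[2]], "+") <= rz)
  }
  a
}

# Random blobby phantom (union of balls and axis-aligned rods) for the
# skeletonization contract suite.
randomBlobPhantom <- function(seed, n = 24L) {
  set.seed(seed)
  a <- array(0L, c(n, n, n))
  for (b in seq_len(sample(2:3, 1))) {
    c0 <- runif(3, 7, n - 6)
    rad <- runif(1, 2.5, 5.5)
    a <- a | mkBall(n, rad, c0)
  }
  for (rr in seq_len(sample(1:2, 1))) {
    ax <- sample(1:3, 1)
    w <- sample(2:3, 1)
    lo <- sample(2:(n - 10), 2)
    span <- sample(2:(n - 1), 1):n
    idx <- list(lo[1]:(lo[1] + w), lo[2]:(lo[2] + w),
                pmin(span, n))
    idx <- idx[order(c(setdiff(1:3, ax), ax))]
    a[idx[[1]], idx[[2]], idx[[3]]] <- 1L
  }
  VoxelGrid(array(as.integer(a), dim = c(n, n, n)),
            affineMeta = list(lrAxis = 1L))
}

# TRUE when any 2x2x2 solid foreground block exists.
has2x2x2Block <- function(a) {
  d <- dim(a)
  if (any(d < 2)) return(FALSE)
  b <- a[-d[1], , , drop = FALSE] & a[-1, , , drop = FALSE]
  b <- b[, -d[2], , drop = FALSE] & b[, -1, , drop = FALSE]
  b <- b[, , -d[3], drop = FALSE] & b[, , -1, drop = FALSE]
  any(b)
}

# Number of skeleton voxels with >= 3 foreground 26-neighbors.
countBranchVoxels <- function(skel) {
  d <- dim(skel)
  nb <- array(0L, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- array(0L, d)
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    sh[sx, sy, sz] <- skel[sx - dx, sy - dy, sz - dz]
    nb <- nb + sh
  }
  sum(skel == 1L & nb >= 3L)
}

# Smooth separable Gaussian blob as a probability map, for resampling
# mass-conservation checks.
smoothBlobVolume <- function(dims = c(40, 40, 36),
                             voxelSize = c(0.9, 0.9, 1.0)) {
  cx <- (dims + 1) / 2
  g1 <- function(ax, sigma) exp(-((seq_len(dims[ax]) - cx[ax]) *
                                    voxelSize[ax])^2 / (2 * sigma^2))
  a <- outer(outer(g1(1, 6), g1(2, 6)), g1(3, 6))
  ProbabilityVolume(a, voxelSize = voxelSize,
                    affineMeta = list(lrAxis = 1L))
}

# Two parallel odd-diameter rods mirrored about the central sagittal
# plane; the thinning of each is its exact center line, so left/right
# feature counts must match exactly.
mirroredRodsVolume <- function() {
  a <- array(0L, c(40, 13, 30))
  rod <- function(cx) {
    for (x in 1:40) for (y in 1:13) {
      if ((x - cx)^2 + (y - 7)^2 <= 2.5^2) a[x, y, 5:26] <<- 1L
    }
  }
  rod(10); rod(31)
  VoxelGrid(a, affineMeta = list(lrAxis = 1L))
}
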
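test_that("box counts match analytic values on canonical sets", {
  a <- array(0L, c(4, 4, 4)); a[1, 1, 1] <- 1L
  cv <- boxCount(VoxelGrid(a), scales = c(1, 2, 4))
  expect_equal(boxCounts(cv), c(1, 1, 1))

  block <- makePhantom("solid_block", size = 4)
  expect_equal(boxCounts(boxCount(block, scales = c(1, 2, 4))),
               c(64, 8, 1))

  sponge <- makePhantom("menger", level = 3)
  expect_equal(boxCounts(boxCount(sponge, scales = c(1, 3, 9, 27))),
               c(8000, 400, 20, 1))

  expect_error(boxCount(block, scales = c(2, 1)), "increasing")
  expect_error(boxCount(block, scales = c(1, 8)), "grid dimension")
  empty <- VoxelGrid(array(0L, c(4, 4, 4)))
  expect_error(boxCount(empty), "non-empty")
})

test_that("box counting equals the brute-force cell scan on random masks", {
  for (seed in 1:10) {
    m <- randomMask(seed)
    scl <- c(1, 2, 4, 8)
    scl <- scl[scl <= max(gridDim(m))]
    got <- boxCounts(boxCount(m, scales = scl))
    want <- vapply(scl, function(r) bruteBoxCount(voxelData(m), r),
                   numeric(1))
    expect_equal(got, want)
  }
})

test_that("box counts are monotone, bounded, and scale-invariant", {
  for (seed in 1:100) {
    m <- randomMask(seed, maxDim = 16L, p = 0.25)
    scl <- c(1, 2, 4, 8)
    scl <- scl[scl <= max(gridDim(m))]
    cnt <- boxCounts(boxCount(m, scales = scl))
    v <- voxelCount(m)
    expect_true(all(diff(cnt) <= 0))
    expect_true(all(cnt <= v))
    expect_true(all(cnt >= ceiling(v / scl^3)))
  }
  # integer upsampling by s with scales multiplied by s leaves N unchanged
  m <- randomMask(5, maxDim = 12L, p = 0.3)
  a <- voxelData(m)
  for (s in c(2L, 3L)) {
    d <- dim(a)
    up <- a[rep(seq_len(d[1]), each = s),
            rep(seq_len(d[2]), each = s),
            rep(seq_len(d[3]), each = s)]
    scl <- c(1, 2, 4)
    scl <- scl[scl <= max(d)]
    expect_equal(
      boxCounts(boxCount(VoxelGrid(up), scales = scl * s)),
      boxCounts(boxCount(m, scales = scl)))
  }
})

test_that("scaling-range selection keeps collinear curves and drops corrupted tails", {
  collinear <- new("BoxCountCurve", scales = c(1, 2, 4, 8, 16),
                   counts = 4096 / c(1, 2, 4, 8, 16)^2, nOffsets = 1L)
  expect_equal(selectScalingRange(collinear), c(1, 16))

  # perfect r^-2 interior, flat (corrupted) largest scale
  corrupted <- new("BoxCountCurve", scales = c(1, 2, 4, 8, 16, 32),
                   counts = c(4096 / c(1, 2, 4, 8, 16)^2, 16),
                   nOffsets = 1L)
  expect_equal(selectScalingRange(corrupted), c(1, 16))

  two <- new("BoxCountCurve", scales = c(1, 2), counts = c(8, 2),
             nOffsets = 1L)
  expect_error(selectScalingRange(two, minPoints = 3), "at least 3")
  noisy <- new("BoxCountCurve", scales = c(1, 2, 4, 8),
               counts = c(5000, 4999, 4998, 1), nOffsets = 1L)
  expect_error(selectScalingRange(noisy), "non-fractal|R\\^2")
})

test_that("log-log regression recovers exact slopes to machine precision", {
  menger <- new("BoxCountCurve", scales = c(1, 3, 9, 27),
                counts = c(8000, 400, 20, 1), nOffsets = 1L)
  est <- estimateFD(menger)
  expect_equal(fdValue(est), log(20) / log(3), tolerance = 1e-12)
  expect_equal(fdRSquared(est), 1, tolerance = 1e-12)

  for (C in c(1, 5, 1000)) {
    cv <- new("BoxCountCurve", scales = c(1, 2, 4, 8),
              counts = C * c(1, 2, 4, 8)^(-2) * 64, nOffsets = 1L)
    expect_equal(fdValue(estimateFD(cv)), 2, tolerance = 1e-12)
  }

  cube <- new("BoxCountCurve", scales = c(1, 2, 4),
              counts = c(64, 8, 1), nOffsets = 1L)
  expect_equal(fdValue(estimateFD(cube)), 3, tolerance = 1e-12)
  expect_error(estimateFD(cube, c(1, 2)), "3 scales")
})

test_that("fractal dimensions of analytic phantoms are recovered through featureFD", {
  sponge <- makePhantom("menger", level = 3)
  fs <- new("ShapeFeatureSet", general = sponge, skeleton = sponge,
            surface = sponge, hemisphere = "whole")
  ests <- featureFD(fs)
  expect_lt(abs(fdValue(ests$general) - log(20) / log(3)), 0.05)

  emptySkel <- VoxelGrid(array(0L, gridDim(sponge)))
  fs2 <- new("ShapeFeatureSet", general = sponge, skeleton = emptySkel,
             surface = sponge, hemisphere = "whole")
  expect_error(featureFD(fs2), "skeleton")
})

test_that("a voxelized solid ball recovers volume and surface dimensions", {
  ball <- VoxelGrid(mkBall(256, 120), affineMeta = list(lrAxis = 1L))
  cv <- boxCount(ball)
  expect_lt(abs(fdValue(estimateFD(cv, selectScalingRange(cv))) - 3), 0.1)
  surf <- extractSurface(ball)
  cs <- boxCount(surf)
  expect_lt(abs(fdValue(estimateFD(cs, selectScalingRange(cs))) - 2), 0.15)
})

test_that("a long rod's skeleton has dimension near 1", {
  rod <- makePhantom("rod", radius = 2.5, size = 101)
  sk <- skeletonize3D(rod)
  cv <- boxCount(sk)
  expect_lt(abs(fdValue(estimateFD(cv, selectScalingRange(cv))) - 1), 0.1)
})

test_that("the automatic scale ladder adapts its base to the lattice", {
  expect_equal(autoBoxScales(c(27, 27, 27)), c(1, 3, 9, 27))
  expect_equal(autoBoxScales(c(64, 64, 64)), c(1, 2, 4, 8, 16, 32))
  expect_equal(autoBoxScales(c(10, 12, 45)), c(1, 2, 4, 8, 16, 32))
})
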
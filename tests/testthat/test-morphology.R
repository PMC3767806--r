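test_that("binarization follows the inclusive >= threshold convention", {
  a <- array(c(0.7, 0.5, 0.49999, 0.2, 1, 0, 0.5, 0.3), c(2, 2, 2))
  vg <- binarize(ProbabilityVolume(a), 0.5)
  expect_equal(as.vector(voxelData(vg)), c(1, 1, 0, 0, 1, 0, 1, 0))
  expect_warning(binarize(ProbabilityVolume(array(0, c(3, 3, 3)))),
                 "empty")
  pv <- ProbabilityVolume(a)
  expect_error(binarize(pv, 0), "strictly inside")
  expect_error(binarize(pv, 1), "strictly inside")
})

test_that("surface extraction matches analytic cube counts and the erosion oracle", {
  cube3 <- makePhantom("solid_block", size = 3)
  expect_equal(voxelCount(extractSurface(cube3, 6)), 26)
  cube5 <- makePhantom("solid_block", size = 5)
  expect_equal(voxelCount(extractSurface(cube5, 6)), 98)
  single <- VoxelGrid(array(1L, c(1, 1, 1)))
  expect_equal(voxelData(extractSurface(single)), voxelData(single))
  expect_error(extractSurface(cube3, 7), "connectivity")

  # oracle: surface_6 == mask \ erosion_6(mask)
  for (seed in 1:8) {
    m <- randomMask(seed, maxDim = 16L, p = 0.4)
    a <- voxelData(m)
    d <- dim(a)
    pad <- array(0L, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
    core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    eroded <- core &
      pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
      pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    oracle <- array(as.integer(a == 1L & !eroded), d)
    expect_identical(voxelData(extractSurface(m, 6)), oracle)
  }
})

test_that("thinning leaves single voxels and unit-width lines untouched", {
  single <- VoxelGrid(array(1L, c(1, 1, 1)))
  expect_identical(voxelData(skeletonize3D(single)), voxelData(single))
  line <- makePhantom("line", size = 21)
  sk <- skeletonize3D(line)
  expect_identical(voxelData(sk), voxelData(line))
  expect_identical(voxelData(skeletonize3D(sk)), voxelData(sk))
})

test_that("a solid rod thins to a single centered curve", {
  rod <- makePhantom("rod", radius = 2.5, size = 41)
  sk <- skeletonize3D(rod)
  nv <- voxelCount(sk)
  expect_true(abs(nv - 41) <= 0.2 * 41)
  expect_equal(countComponents(sk), 1)
  # ridge check: every skeleton voxel lies within 1 voxel of the rod axis
  idx <- which(voxelData(sk) == 1L, arr.ind = TRUE)
  cx <- (dim(voxelData(rod))[1] + 1) / 2
  axDist <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cx)^2)
  expect_true(all(axDist <= 1 + 1e-9))
})

test_that("thinning a solid torus preserves its loop", {
  tor <- makePhantom("torus", R = 10, r = 3)
  expect_equal(eulerNumber(tor), 0)
  sk <- skeletonize3D(tor)
  expect_equal(eulerNumber(sk), 0)  # one loop survives
  expect_equal(countComponents(sk), 1)
  expect_gt(voxelCount(sk), 10)
})

test_that("thinning contract holds on a randomized phantom suite", {
  for (seed in 1:12) {
    m <- randomBlobPhantom(seed)
    sk <- skeletonize3D(m)
    expect_true(all(voxelData(sk) <= voxelData(m)))
    expect_identical(voxelData(skeletonize3D(sk)), voxelData(sk))
    expect_equal(countComponents(sk), countComponents(m))
    expect_equal(eulerNumber(sk), eulerNumber(m))
    expect_false(has2x2x2Block(voxelData(sk)))
  }
})

test_that("hemisphere splitting partitions the grid and finds empty slabs", {
  # two blobs separated by an empty central slab
  a <- array(0L, c(32, 20, 20))
  a[4:10, 6:14, 6:14] <- 1L
  a[22:28, 6:14, 6:14] <- 1L
  m <- VoxelGrid(a, affineMeta = list(lrAxis = 1L))
  sp <- splitHemispheres(m)
  expect_true(sp$midline >= 12 && sp$midline <= 20)
  # exhaustive oracle: the chosen cut must have zero foreground crossing
  cross <- sum(a[sp$midline, , ] & a[sp$midline + 1, , ])
  expect_equal(cross, 0)
  expect_identical(voxelData(sp$left) + voxelData(sp$right), a)
  expect_equal(sum(voxelData(sp$left) & voxelData(sp$right)), 0)
  expect_equal(voxelCount(sp$left), voxelCount(sp$right))

  onesided <- array(0L, c(32, 8, 8))
  onesided[2:6, 2:6, 2:6] <- 1L
  expect_warning(
    sp2 <- splitHemispheres(VoxelGrid(onesided,
                                      affineMeta = list(lrAxis = 1L))),
    "empty")
  expect_equal(voxelCount(sp2$right), 0)

  noMeta <- VoxelGrid(a)
  expect_error(splitHemispheres(noMeta), "axis")
  expect_identical(voxelData(splitHemispheres(noMeta, axis = 1)$left),
                   voxelData(sp$left))
})

test_that("feature sets respect symmetry, subset structure and count ordering", {
  rods <- mirroredRodsVolume()
  pv <- ProbabilityVolume(array(voxelData(rods) * 0.9, dim = gridDim(rods)),
                          affineMeta = list(lrAxis = 1L))
  fs <- makeFeatureSet(pv)
  for (f in c("general", "skeleton", "surface")) {
    expect_equal(voxelCount(methods::slot(fs$left, f)),
                 voxelCount(methods::slot(fs$right, f)))
  }
  expect_true(validObject(fs$whole))
  # whole = left + right per feature
  expect_equal(voxelCount(fs$left@skeleton) + voxelCount(fs$right@skeleton),
               voxelCount(fs$whole@skeleton))

  expect_error(
    suppressWarnings(
      makeFeatureSet(ProbabilityVolume(array(0, c(8, 8, 8)),
                                       affineMeta = list(lrAxis = 1L)))),
    "empty WM mask")

  tree <- makeWMTreePhantom(seed = 2)
  fst <- makeFeatureSet(tree)
  expect_lt(voxelCount(fst$whole@skeleton), voxelCount(fst$whole@surface))
  expect_lt(voxelCount(fst$whole@surface), voxelCount(fst$whole@general))
})

test_that("Euler characteristic matches analytic solids", {
  expect_equal(eulerNumber(makePhantom("solid_block", size = 4)), 1)
  expect_equal(eulerNumber(makePhantom("torus")), 0)
  # hollow shell: ball minus smaller ball
  shell <- mkBall(20, 8) - mkBall(20, 5)
  expect_equal(eulerNumber(VoxelGrid(shell)), 2)
})
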
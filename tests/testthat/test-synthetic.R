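test_that("deterministic phantoms have their construction counts", {
  expect_equal(voxelCount(makePhantom("menger", level = 2)), 400)
  expect_equal(gridDim(makePhantom("menger", level = 2)), c(9L, 9L, 9L))
  expect_equal(voxelCount(makePhantom("solid_block", size = 4)), 64)
  expect_equal(voxelCount(makePhantom("plane", size = 8)), 64)
  expect_equal(voxelCount(makePhantom("line", size = 13)), 13)
})

test_that("fractal percolation degenerates, survives, and is seed-stable", {
  full <- makePhantom("percolation", levels = 4, p = 1, seed = 1)
  expect_equal(voxelCount(full), 16^3)
  expect_error(makePhantom("percolation", p = 0.1), "1/8")

  a <- makePhantom("percolation", levels = 5, p = 0.6, seed = 7)
  b <- makePhantom("percolation", levels = 5, p = 0.6, seed = 7)
  expect_identical(voxelData(a), voxelData(b))
  expect_gt(voxelCount(a), 0)

  counts <- vapply(1:20, function(s)
    voxelCount(makePhantom("percolation", levels = 4, p = 0.5, seed = s)),
    numeric(1))
  expect_gt(length(unique(counts)), 10)  # seeds genuinely differ
  expect_true(all(counts > 0))           # conditioned on survival
})

test_that("the WM tree phantom is reproducible, connected, and branch-rich", {
  p1 <- makeWMTreePhantom(seed = 3, nBranches = 6)
  p2 <- makeWMTreePhantom(seed = 3, nBranches = 6)
  expect_identical(voxelData(p1), voxelData(p2))
  expect_false(identical(voxelData(p1),
                         voxelData(makeWMTreePhantom(seed = 4))))

  mask <- binarize(p1)
  expect_equal(countComponents(mask), 1)
  sk <- skeletonize3D(mask)
  expect_gte(countBranchVoxels(voxelData(sk)), 5)  # >= nBranches - 1

  simple <- makeWMTreePhantom(seed = 5, nBranches = 1)
  sks <- skeletonize3D(binarize(simple))
  expect_equal(countBranchVoxels(voxelData(sks)), 0)
  expect_equal(countComponents(sks), 1)

  expect_error(makeWMTreePhantom(gridDim = c(32, 64, 64)), "64")
})

test_that("probability phantoms binarize back to the exact voxel set", {
  for (seed in c(1, 9)) {
    g <- makePhantom("percolation", levels = 5, p = 0.7, seed = seed)
    pv <- phantomProbability(g, seed = seed)
    expect_true(all(voxelData(pv) >= 0 & voxelData(pv) <= 1))
    rec <- binarize(pv, 0.5)
    recovered <- sum(voxelData(rec) & voxelData(g)) / voxelCount(g)
    expect_gte(recovered, 0.99)
    expect_equal(sum(voxelData(rec) & !voxelData(g)), 0)
  }
})

test_that("degenerate cohort spec reproduces group means exactly", {
  ref <- referenceCohortParams()
  sds0 <- ref$fdSds; sds0[] <- 0
  tab <- makeCohort(fdSds = sds0, ageSlope = 0, genderSd = 0, seed = 3)
  for (o in fdOutcomeNames()) {
    expect_equal(tab[[o]], unname(ref$fdMeans[o, tab$group]),
                 tolerance = 1e-12)
  }
})

test_that("cohort marginals converge to the generating parameters", {
  ref <- referenceCohortParams()
  gs <- setNames(rep(500L, 5), ref$groups)
  tab <- makeCohort(groupSizes = gs, seed = 9)
  m <- tapply(tab$fd_skeleton_wb, tab$group, mean)
  expect_lt(abs(m[["Control"]] - 2.487), 0.005)
  expect_true(all(abs(m - ref$fdMeans["fd_skeleton_wb", names(m)]) < 0.015))

  gs2 <- setNames(rep(2000L, 5), ref$groups)
  tab2 <- makeCohort(groupSizes = gs2, seed = 10)
  for (g in ref$groups) {
    i <- tab2$group == g
    expect_lt(abs(mean(tab2$fd_general_wb[i]) /
                    ref$fdMeans["fd_general_wb", g] - 1), 0.02)
    expect_lt(abs(mean(tab2$age[i]) / ref$ageMeans[g] - 1), 0.02)
  }
  # duration roughly matches the per-group medians on the log scale
  for (g in setdiff(ref$groups, "Control")) {
    i <- tab2$group == g
    expect_lt(abs(median(tab2$duration_months[i]) /
                    ref$durationMedian[g] - 1), 0.1)
  }
})

test_that("ALSFRS-R is rank-coupled to whole-brain skeleton FD as requested", {
  ref <- referenceCohortParams()
  gs <- setNames(rep(75L, 4), setdiff(ref$groups, "Control"))
  tab <- makeCohort(groupSizes = gs, alsfrsCoupling = 0.4, seed = 11)
  rho <- cor(tab$fd_skeleton_wb, tab$alsfrs_r, method = "spearman")
  expect_lt(abs(rho - 0.4), 0.1)
  expect_true(all(tab$alsfrs_r >= 0 & tab$alsfrs_r <= 48))
  expect_true(all(tab$ees %in% 1:4))
})

test_that("cohort generation respects field ranges and is seed-deterministic", {
  tab <- makeCohort(seed = 21)
  expect_identical(tab, makeCohort(seed = 21))
  expect_false(identical(tab$fd_skeleton_wb,
                         makeCohort(seed = 22)$fd_skeleton_wb))
  ctrl <- tab$group == "Control"
  expect_true(all(is.na(tab$alsfrs_r[ctrl])))
  expect_true(all(is.na(tab$duration_months[ctrl])))
  expect_true(all(is.na(tab$ees[ctrl])))
  expect_true(all(tab$duration_months[!ctrl] > 0))
  expect_true(all(tab$gender %in% c("M", "F")))
  expect_true(all(tab[, fdOutcomeNames()] >= 0 &
                    tab[, fdOutcomeNames()] <= 3.1))
  expect_error(makeCohort(groupSizes = c(Control = 0L)), ">= 1")
})
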
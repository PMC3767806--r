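#' @include AllClasses.R constants.R
NULL

.mengerSponge <- function(level) {
  a <- array(1L, c(1, 1, 1))
  for (i in seq_len(level)) {
    n <- dim(a)[1]
    b <- array(0L, rep(3L * n, 3))
    for (ix in 0:2) for (iy in 0:2) for (iz in 0:2) {
      if (sum(c(ix, iy, iz) == 1) >= 2) next
      b[ix * n + seq_len(n), iy * n + seq_len(n), iz * n + seq_len(n)] <- a
    }
    a <- b
  }
  a
}

# Fractal percolation with subdivision 2: each surviving cell splits
# into 8 octants retained independently with probability p. Conditioned
# on non-extinction by retrying with derived seeds; box dimension of the
# limit set is 3 + log2(p) for p > 1/8.
.fractalPercolation <- function(levels, p, seed) {
  retries <- 0L
  repeat {
    set.seed(.deriveSeed(seed + retries, "percolation"))
    a <- array(1L, c(1, 1, 1))
    for (i in seq_len(levels)) {
      n <- dim(a)[1]
      idx <- seq_len(2L * n)
      parent <- a[ceiling(idx / 2), ceiling(idx / 2), ceiling(idx / 2)]
      b <- array(parent, rep(2L * n, 3))
      alive <- which(b == 1L)
      b[alive] <- rbinom(length(alive), 1L, p)
      a <- b
      if (sum(a) == 0L) break
    }
    if (sum(a) > 0L) break
    retries <- retries + 1L
    if (retries > 1000L) stop("percolation phantom went extinct 1000 times")
  }
  attr(a, "retries") <- retries
  a
}

.solidRod <- function(radius, length, margin = 2L) {
  w <- 2L * ceiling(radius) + 1L + 2L * margin
  a <- array(0L, c(w, w, length + 2L * margin))
  cx <- (w + 1) / 2
  for (z in margin + seq_len(length)) {
    for (x in seq_len(w)) for (y in seq_len(w)) {
      if ((x - cx)^2 + (y - cx)^2 <= radius^2) a[x, y, z] <- 1L
    }
  }
  a
}

.solidTorus <- function(R, r, margin = 2L) {
  w <- 2L * ceiling(R + r) + 1L + 2L * margin
  h <- 2L * ceiling(r) + 1L + 2L * margin
  a <- array(0L, c(w, w, h))
  cx <- (w + 1) / 2; cz <- (h + 1) / 2
  coords <- expand.grid(x = seq_len(w), y = seq_len(w), z = seq_len(h))
  d <- sqrt((sqrt((coords$x - cx)^2 + (coords$y - cx)^2) - R)^2 +
            (coords$z - cz)^2)
  a[as.matrix(coords)] <- as.integer(d <= r)
  a
}

#' Generate a voxel phantom
#'
#' Deterministic voxel sets used to validate the pipeline, several with
#' analytically known box dimension (see [phantomExpectedFD()]):
#' \describe{
#'   \item{menger}{Level-L Menger sponge on a 3^L grid (20^L voxels).}
#'   \item{percolation}{Fractal percolation, subdivision 2, retention
#'     probability \code{p}, conditioned on survival; grid 2^levels.}
#'   \item{solid_block}{Solid cube of edge \code{size}.}
#'   \item{plane}{One-voxel-thick \code{size} x \code{size} sheet.}
#'   \item{line}{Straight 1-voxel-wide line of \code{size} voxels.}
#'   \item{rod}{Solid cylinder, radius \code{radius}, length
#'     \code{size}.}
#'   \item{torus}{Solid torus, major radius \code{R}, minor \code{r}.}
#' }
#'
#' @param kind Phantom kind (see above).
#' @param level Construction depth for \code{menger}.
#' @param size Edge length / line length (block, plane, line, rod).
#' @param levels Subdivision depth for \code{percolation}.
#' @param p Retention probability for \code{percolation}, in (1/8, 1].
#' @param radius Rod radius.
#' @param R,r Torus major/minor radius.
#' @param seed RNG seed (percolation only).
#' @return A \linkS4class{VoxelGrid} (left-right axis set to 1).
#' @export
#' @examples
#' voxelCount(makePhantom("menger", level = 2))  # 400
makePhantom <- function(kind = c("menger", "percolation", "solid_block",
                                 "plane", "line", "rod", "torus"),
                        level = 3L, size = 32L, levels = 6L, p = 0.7,
                        radius = 2.5, R = 10, r = 3, seed = 1L) {
  kind <- match.arg(kind)
  a <- switch(kind,
    menger = .mengerSponge(level),
    percolation = {
      if (p <= 1 / 8 || p > 1)
        stop("percolation retention p must lie in (1/8, 1]")
      .fractalPercolation(levels, p, seed)
    },
    solid_block = array(1L, rep(as.integer(size), 3)),
    plane = array(1L, c(as.integer(size), as.integer(size), 1L)),
    line = array(1L, c(1L, 1L, as.integer(size))),
    rod = .solidRod(radius, as.integer(size)),
    torus = .solidTorus(R, r))
  retries <- attr(a, "retries")
  attr(a, "retries") <- NULL
  g <- VoxelGrid(a, affineMeta = list(lrAxis = 1L))
  if (!is.null(retries)) attr(g, "retries") <- retries
  g
}

#' Analytic box dimension of a phantom kind
#'
#' @param kind A [makePhantom()] kind.
#' @param p Retention probability (percolation only).
#' @return The analytic dimension, or NA when none is defined.
#' @export
#' @examples
#' phantomExpectedFD("menger")        # log 20 / log 3
#' phantomExpectedFD("percolation", p = 0.8)
phantomExpectedFD <- function(kind, p = NULL) {
  switch(kind,
         menger = log(20) / log(3),
         percolation = {
           if (is.null(p)) stop("percolation dimension needs p")
           3 + log2(p)
         },
         solid_block = 3,
         plane = 2,
         line = 1,
         NA_real_)
}

#' Turn a binary phantom into a segmentation-like probability map
#'
#' Blurs the binary phantom mildly, mixes it with the crisp mask and
#' adds bounded uniform noise, clipped to [0, 1], such that binarizing
#' at 0.5 recovers the phantom voxels.
#'
#' @param grid A binary \linkS4class{VoxelGrid}.
#' @param seed RNG seed for the noise.
#' @param sigma Gaussian blur width in voxels.
#' @param noise Half-width of the uniform noise (kept < 0.25 so the 0.5
#'   level set cannot flip).
#' @return A \linkS4class{ProbabilityVolume}.
#' @export
phantomProbability <- function(grid, seed = 1L, sigma = 0.8,
                               noise = 0.05) {
  stopifnot(is(grid, "VoxelGrid"), noise >= 0, noise < 0.25)
  set.seed(.deriveSeed(seed, "phantom-noise"))
  b <- grid@data
  sm <- .gaussianSmooth3D(b + 0, sigma)
  pdat <- 0.8 * b + 0.2 * sm +
    noise * (2 * array(runif(length(b)), dim = dim(b)) - 1)
  ProbabilityVolume(.clip(pdat, 0, 1), voxelSize = grid@voxelSize,
                    affineMeta = grid@affineMeta)
}

# Rasterize a capsule (segment with radius) into a 0/1 array, in place.
.drawCapsule <- function(a, p0, p1, rad) {
  d <- dim(a)
  lo <- pmax(1L, floor(pmin(p0, p1) - rad))
  hi <- pmin(d, ceiling(pmax(p0, p1) + rad))
  if (any(lo > hi)) return(a)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- p1 - p0
  len2 <- sum(v^2)
  w <- cbind(g$x - p0[1], g$y - p0[2], g$z - p0[3])
  t <- if (len2 > 0) .clip(as.vector(w %*% v) / len2, 0, 1) else 0
  dx <- w - outer(t, v)
  inside <- rowSums(dx^2) <= rad^2
  a[as.matrix(g)[inside, , drop = FALSE]] <- 1L
  a
}

#' Branching white-matter-like tube phantom
#'
#' Emulates a WM probability map: a connected branching tubular tree
#' grown upward from the grid base, with random branch angles that
#' break left-right symmetry, rasterized as capsules and converted to a
#' probability map with [phantomProbability()]. Binarized at 0.5 the
#' phantom is connected, and its skeleton carries at least
#' \code{nBranches - 1} branch points.
#'
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @param nBranches Number of terminal branches (>= 1).
#' @param gridDim Grid dimensions, each >= 64.
#' @return A \linkS4class{ProbabilityVolume} (left-right axis 1).
#' @export
makeWMTreePhantom <- function(seed = 1L, nBranches = 6L,
                              gridDim = c(72L, 72L, 96L)) {
  if (any(gridDim < 64L))
    stop("WM tree phantom needs a grid of at least 64 voxels per axis")
  set.seed(.deriveSeed(seed, "wm-tree"))
  a <- array(0L, gridDim)
  base <- c(gridDim[1] / 2, gridDim[2] / 2, 6)
  # active leaves: position, direction (unit), radius, segment length
  leaves <- list(list(p = base, dir = c(0, 0, 1), rad = 3.2, len = 22))
  nSplits <- max(0L, nBranches - 1L)
  grow <- function(leaf) {
    p1 <- leaf$p + leaf$dir * leaf$len
    p1 <- .clip(p1, 5, gridDim - 5)
    a <<- .drawCapsule(a, leaf$p, p1, leaf$rad)
    p1
  }
  for (s in seq_len(nSplits)) {
    i <- ((s - 1L) %% length(leaves)) + 1L
    leaf <- leaves[[i]]
    tip <- grow(leaf)
    kids <- lapply(c(-1, 1), function(side) {
      ang <- runif(1, 0.45, 0.85) * side
      # first bifurcation opens along the left-right axis so both
      # hemispheres carry a lobe; later splits are random
      az <- if (s == 1L) 0 else runif(1, 0, 2 * pi)
      if (s == 1L) ang <- 0.8 * side
      lat <- c(cos(az), sin(az), 0)
      dirn <- cos(ang) * leaf$dir + sin(ang) * lat
      dirn[3] <- abs(dirn[3]) + 0.35  # keep growing upward
      dirn <- dirn / sqrt(sum(dirn^2))
      list(p = tip, dir = dirn, rad = max(1.6, leaf$rad * 0.8),
           len = max(10, leaf$len * 0.8))
    })
    leaves <- c(leaves[-i], kids)
  }
  for (leaf in leaves) grow(leaf)
  grid <- VoxelGrid(a, affineMeta = list(lrAxis = 1L))
  phantomProbability(grid, seed = .deriveSeed(seed, "wm-tree-prob"))
}

#' Simulate a cohort table of FD outcomes and clinical measures
#'
#' Generates one row per subject under the same structural model the
#' group comparison assumes: each FD outcome is its group mean plus a
#' linear age effect, a gender-specific effect, and Gaussian noise.
#' ALSFRS-R is rank-coupled to whole-brain skeleton FD through a
#' Gaussian copula, disease duration is log-normal matched to per-group
#' medians and quartiles, and the diagnostic-certainty category (EES) is
#' drawn from per-group frequencies. Controls carry no clinical
#' measures. All defaults come from [referenceCohortParams()].
#'
#' @param groupSizes Named integer vector of subjects per group.
#' @param fdMeans,fdSds 9 x nGroups matrices (rows = [fdOutcomeNames()]).
#' @param ageMeans,ageSds,maleProp Named per-group vectors.
#' @param alsfrsMeans,alsfrsSds Named per-group vectors (NA for Control).
#' @param durationMedian,durationQ1,durationQ3 Named per-group vectors.
#' @param eesProbs nGroups x 4 matrix of EES category probabilities.
#' @param ageSlope FD change per year of age (applied to every outcome).
#' @param genderSd SD of the gender-specific effect on each outcome.
#' @param alsfrsCoupling Target Spearman correlation between ALSFRS-R
#'   and whole-brain skeleton FD within groups.
#' @param seed Root seed; every component draws from a named substream.
#' @return Data frame in the FD report schema (see [writeFDReport()]).
#' @export
#' @examples
#' tab <- makeCohort(seed = 7)
#' table(tab$group)
makeCohort <- function(groupSizes = NULL, fdMeans = NULL, fdSds = NULL,
                       ageMeans = NULL, ageSds = NULL, maleProp = NULL,
                       alsfrsMeans = NULL, alsfrsSds = NULL,
                       durationMedian = NULL, durationQ1 = NULL,
                       durationQ3 = NULL, eesProbs = NULL,
                       ageSlope = -0.0005, genderSd = 0.005,
                       alsfrsCoupling = 0.431, seed = 1L) {
  ref <- referenceCohortParams()
  if (is.null(groupSizes)) groupSizes <- ref$groupSizes
  if (is.null(fdMeans)) fdMeans <- ref$fdMeans[, names(groupSizes),
                                               drop = FALSE]
  if (is.null(fdSds)) fdSds <- ref$fdSds[, names(groupSizes),
                                         drop = FALSE]
  if (is.null(ageMeans)) ageMeans <- ref$ageMeans[names(groupSizes)]
  if (is.null(ageSds)) ageSds <- ref$ageSds[names(groupSizes)]
  if (is.null(maleProp)) maleProp <- ref$maleProp[names(groupSizes)]
  if (is.null(alsfrsMeans)) alsfrsMeans <- ref$alsfrsMeans[names(groupSizes)]
  if (is.null(alsfrsSds)) alsfrsSds <- ref$alsfrsSds[names(groupSizes)]
  if (is.null(durationMedian))
    durationMedian <- ref$durationMedian[names(groupSizes)]
  if (is.null(durationQ1)) durationQ1 <- ref$durationQ1[names(groupSizes)]
  if (is.null(durationQ3)) durationQ3 <- ref$durationQ3[names(groupSizes)]
  if (is.null(eesProbs)) eesProbs <- ref$eesProbs[names(groupSizes), ,
                                                  drop = FALSE]
  groups <- names(groupSizes)
  if (any(groupSizes < 1L)) stop("all group sizes must be >= 1")
  if (any(fdSds < 0, na.rm = TRUE) || genderSd < 0)
    stop("standard deviations must be non-negative")
  grp <- rep(groups, groupSizes)
  n <- length(grp)
  outcomes <- fdOutcomeNames()

  set.seed(.deriveSeed(seed, "age"))
  age <- rnorm(n, ageMeans[grp], ageSds[grp])
  grandAge <- sum(ageMeans * groupSizes) / sum(groupSizes)

  set.seed(.deriveSeed(seed, "gender"))
  gender <- ifelse(rbinom(n, 1L, maleProp[grp]) == 1L, "M", "F")

  set.seed(.deriveSeed(seed, "gender-effect"))
  gEff <- matrix(rnorm(length(outcomes) * 2, 0, genderSd),
                 nrow = length(outcomes),
                 dimnames = list(outcomes, c("M", "F")))

  set.seed(.deriveSeed(seed, "fd-noise"))
  fd <- sapply(outcomes, function(o) {
    fdMeans[o, grp] + ageSlope * (age - grandAge) +
      gEff[o, gender] + rnorm(n, 0, fdSds[o, grp])
  })
  fd <- matrix(fd, nrow = n, dimnames = list(NULL, outcomes))

  isPatient <- grp != "Control"

  set.seed(.deriveSeed(seed, "alsfrs"))
  alsfrs <- rep(NA_real_, n)
  if (any(isPatient)) {
    # within-group normal score of wb skeleton FD, rank-coupled via a
    # Gaussian copula: Pearson rho on latents = 2 sin(pi * rho_s / 6)
    z <- rep(0, n)
    for (g in unique(grp[isPatient])) {
      i <- which(grp == g)
      s <- sd(fd[i, "fd_skeleton_wb"])
      z[i] <- if (is.na(s) || s < 1e-12) 0 else
        (fd[i, "fd_skeleton_wb"] - mean(fd[i, "fd_skeleton_wb"])) / s
    }
    aCop <- 2 * sin(pi * .clip(alsfrsCoupling, -1, 1) / 6)
    latent <- aCop * z + sqrt(max(0, 1 - aCop^2)) * rnorm(n)
    idx <- which(isPatient & !is.na(alsfrsMeans[grp]))
    alsfrs[idx] <- .clip(round(alsfrsMeans[grp[idx]] +
                               alsfrsSds[grp[idx]] * latent[idx]), 0, 48)
  }

  set.seed(.deriveSeed(seed, "duration"))
  duration <- rep(NA_real_, n)
  idx <- which(isPatient & !is.na(durationMedian[grp]))
  if (length(idx) > 0) {
    meanlog <- log(durationMedian[grp[idx]])
    sdlog <- (log(durationQ3[grp[idx]]) - log(durationQ1[grp[idx]])) /
      (2 * qnorm(0.75))
    duration[idx] <- rlnorm(length(idx), meanlog, sdlog)
  }

  set.seed(.deriveSeed(seed, "ees"))
  ees <- rep(NA_integer_, n)
  for (g in unique(grp[isPatient])) {
    pr <- eesProbs[g, ]
    if (anyNA(pr)) next
    i <- which(grp == g)
    ees[i] <- sample(1:4, length(i), replace = TRUE, prob = pr)
  }

  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = grp, age = age, gender = gender, alsfrs_r = alsfrs,
    duration_months = duration, ees = ees,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fd))
}
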
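#' @include AllClasses.R
NULL

#' Binarize a probability volume
#'
#' Thresholds a WM probability map into a binary occupancy grid. The
#' convention is inclusive: a voxel with p exactly equal to the
#' threshold is occupied, which keeps plateau inputs deterministic.
#'
#' @param prob A \linkS4class{ProbabilityVolume}.
#' @param threshold Threshold in the open interval (0, 1); default 0.5.
#' @return A \linkS4class{VoxelGrid} of voxels with p >= threshold.
#' @export
#' @examples
#' pv <- ProbabilityVolume(array(c(0.7, 0.5, 0.2, 0, 1, 0.4, 0.6, 0.1),
#'                               c(2, 2, 2)))
#' voxelCount(binarize(pv))
binarize <- function(prob, threshold = 0.5) {
  stopifnot(is(prob, "ProbabilityVolume"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  occ <- array(as.integer(prob@data >= threshold), dim = dim(prob@data))
  if (sum(occ) == 0L)
    warning("binarize: threshold produced an empty mask")
  VoxelGrid(occ, voxelSize = prob@voxelSize, affineMeta = prob@affineMeta)
}

#' Topology-preserving 3D thinning to a one-voxel-wide skeleton
#'
#' Removes simple boundary voxels in six fixed directional subiterations
#' until only a center line remains. A voxel is deleted only when its
#' removal changes neither the number of 26-connected foreground
#' components nor the number of 6-connected background components in its
#' neighborhood (simple-point criterion for the (26, 6) connectivity
#' pair), and curve endpoints (voxels with exactly one foreground
#' neighbor) are kept. Deletion within a subiteration is sequential in
#' raster order with re-checking, so topology is preserved exactly and
#' the result is bit-reproducible.
#'
#' @param mask A binary \linkS4class{VoxelGrid}.
#' @return A \linkS4class{VoxelGrid} skeleton, a subset of the input.
#' @export
skeletonize3D <- function(mask) {
  stopifnot(is(mask, "VoxelGrid"))
  d <- dim(mask@data)
  out <- .cpp_skeletonize(as.integer(mask@data), as.integer(d))
  VoxelGrid(array(out, dim = d), voxelSize = mask@voxelSize,
            affineMeta = mask@affineMeta)
}

.NEIGHBOR_OFFSETS <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = m == 1,
                 "18" = m >= 1 & m <= 2,
                 "26" = m >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Shift a 3D array by an integer offset, filling with `fill`.
.shift3D <- function(arr, dx, dy, dz, fill = 0L) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  if (any(d - abs(c(dx, dy, dz)) < 1)) return(out)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- arr[sx - dx, sy - dy, sz - dz]
  out
}

#' Extract the surface (WM/GM interface) of a binary mask
#'
#' Returns the foreground voxels that touch background: a voxel is on
#' the surface when at least one of its neighbors under the chosen
#' background connectivity is background or lies outside the grid.
#' Face adjacency (connectivity 6) is the default and strictest
#' definition.
#'
#' @param mask A binary \linkS4class{VoxelGrid}.
#' @param connectivity Background neighborhood: 6, 18 or 26.
#' @return A \linkS4class{VoxelGrid} of boundary voxels.
#' @export
#' @examples
#' cube <- makePhantom("solid_block", size = 5)
#' voxelCount(extractSurface(cube))  # 125 - 27 = 98
extractSurface <- function(mask, connectivity = 6) {
  stopifnot(is(mask, "VoxelGrid"))
  offs <- .NEIGHBOR_OFFSETS(connectivity)
  a <- mask@data
  touching <- array(FALSE, dim = dim(a))
  for (i in seq_len(nrow(offs))) {
    nb <- .shift3D(a, offs$dx[i], offs$dy[i], offs$dz[i], fill = 0L)
    touching <- touching | (nb == 0L)
  }
  VoxelGrid(array(as.integer(a == 1L & touching), dim = dim(a)),
            voxelSize = mask@voxelSize, affineMeta = mask@affineMeta)
}

.lrAxis <- function(mask) {
  ax <- mask@affineMeta$lrAxis
  if (!is.null(ax)) {
    ax <- as.integer(ax)
    if (ax %in% 1:3) return(ax)
  }
  hdr <- mask@affineMeta$header
  if (!is.null(hdr)) {
    orient <- tryCatch(RNifti::orientation(hdr), error = function(e) NULL)
    if (is.character(orient) && nchar(orient) == 3) {
      hit <- which(strsplit(orient, "")[[1]] %in% c("L", "R"))
      if (length(hit) == 1) return(hit)
    }
  }
  NULL
}

#' Split a mask into left and right hemispheres
#'
#' Partitions the grid along the left-right axis at a midline slice:
#' the left piece takes slices up to and including the midline index,
#' the right piece the rest, so the two outputs are disjoint and their
#' union is the input. With \code{midline = "auto"} the cut is searched
#' within the central 20\% of the axis and placed where the foreground
#' crossing the candidate plane (voxel pairs straddling it) is minimal;
#' ties go to the cut nearest the grid center, then to the smaller
#' index.
#'
#' @param mask A binary \linkS4class{VoxelGrid}.
#' @param midline "auto" or an integer slice index: the last slice
#'   assigned to the left piece.
#' @param axis Left-right axis (1, 2 or 3). When NULL it is taken from
#'   the metadata (\code{affineMeta$lrAxis} or the NIfTI orientation);
#'   an unidentifiable axis without an explicit index is an error.
#' @return List with elements \code{left}, \code{right}
#'   (\linkS4class{VoxelGrid}) and \code{midline} (the cut index used).
#' @export
splitHemispheres <- function(mask, midline = "auto", axis = NULL) {
  stopifnot(is(mask, "VoxelGrid"))
  if (is.null(axis)) axis <- .lrAxis(mask)
  if (is.null(axis))
    stop("left-right axis not identifiable from metadata; pass `axis`")
  a <- mask@data
  n <- dim(a)[axis]
  sliceSum <- function(i, j) {
    # foreground pairs straddling the plane between slices i and j
    ai <- switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
                 a[, , i, drop = FALSE])
    aj <- switch(axis, a[j, , , drop = FALSE], a[, j, , drop = FALSE],
                 a[, , j, drop = FALSE])
    sum(ai & aj)
  }
  if (identical(midline, "auto")) {
    lo <- max(1L, floor(0.4 * n)); hi <- min(n - 1L, ceiling(0.6 * n))
    cand <- lo:hi
    score <- vapply(cand, function(m) sliceSum(m, m + 1L), numeric(1))
    center <- n / 2
    ord <- order(score, abs(cand + 0.5 - (center + 0.5)), cand)
    m <- cand[ord[1]]
  } else {
    m <- as.integer(midline)
    if (m < 1L || m >= n)
      stop(sprintf("midline index %d outside [1, %d)", m, n))
  }
  leftSel <- seq_len(dim(a)[axis]) <= m
  pick <- function(keep) {
    out <- array(0L, dim = dim(a))
    idx <- which(keep)
    if (axis == 1) out[idx, , ] <- a[idx, , ]
    else if (axis == 2) out[, idx, ] <- a[, idx, ]
    else out[, , idx] <- a[, , idx]
    out
  }
  left <- VoxelGrid(pick(leftSel), voxelSize = mask@voxelSize,
                    affineMeta = mask@affineMeta)
  right <- VoxelGrid(pick(!leftSel), voxelSize = mask@voxelSize,
                     affineMeta = mask@affineMeta)
  if (sum(left@data) == 0L || sum(right@data) == 0L)
    warning("splitHemispheres: one hemisphere is empty")
  list(left = left, right = right, midline = m)
}

#' Build the three shape representations for whole brain and hemispheres
#'
#' Binarizes the probability map, computes the whole-brain general
#' structure, skeleton and surface, then applies hemisphere masks to
#' each — skeletonization happens once on the whole brain, before the
#' split, so hemisphere skeletons are restrictions of the whole-brain
#' skeleton.
#'
#' @param prob A \linkS4class{ProbabilityVolume}.
#' @param threshold Binarization threshold, default 0.5.
#' @param connectivity Surface background connectivity, default 6.
#' @param midline Hemisphere midline, "auto" or an integer slice.
#' @param axis Left-right axis override (see [splitHemispheres()]).
#' @return Named list of \linkS4class{ShapeFeatureSet}s: \code{whole},
#'   \code{left}, \code{right}.
#' @export
makeFeatureSet <- function(prob, threshold = 0.5, connectivity = 6,
                           midline = "auto", axis = NULL) {
  mask <- binarize(prob, threshold)
  if (voxelCount(mask) == 0L) stop("empty WM mask")
  skel <- skeletonize3D(mask)
  surf <- extractSurface(mask, connectivity)
  split <- splitHemispheres(mask, midline = midline, axis = axis)
  m <- split$midline
  ax <- if (is.null(axis)) .lrAxis(mask) else axis
  fs <- function(general, skeleton, surface, hemi) {
    new("ShapeFeatureSet", general = general, skeleton = skeleton,
        surface = surface, hemisphere = hemi)
  }
  restrict <- function(grid, side) {
    h <- splitHemispheres(grid, midline = m, axis = ax)
    suppressWarnings(h[[side]])
  }
  list(
    whole = fs(mask, skel, surf, "whole"),
    left = fs(split$left, suppressWarnings(restrict(skel, "left")),
              suppressWarnings(restrict(surf, "left")), "left"),
    right = fs(split$right, suppressWarnings(restrict(skel, "right")),
               suppressWarnings(restrict(surf, "right")), "right"))
}

#' Count connected components of a binary mask
#'
#' @param mask A binary \linkS4class{VoxelGrid}.
#' @param connectivity 6, 18 or 26 (default 26, the foreground
#'   convention used by the thinning).
#' @return Integer number of components.
#' @export
countComponents <- function(mask, connectivity = 26) {
  stopifnot(is(mask, "VoxelGrid"), connectivity %in% c(6, 18, 26))
  lab <- .cpp_label_components(as.integer(mask@data),
                               as.integer(dim(mask@data)),
                               as.integer(connectivity))
  attr(lab, "n_components")
}

# OR-reduction of voxel occupancy onto the lattice obtained by extending
# the grid by one along each axis in `axes`; cell v is occupied when any
# voxel adjacent to it across those axes is foreground.
.orLattice <- function(a, axes) {
  m <- a
  for (ax in axes) {
    d <- dim(m)
    perm <- c(ax, setdiff(1:3, ax))
    p <- aperm(m, perm)
    dp <- dim(p)
    ext <- array(0L, dim = c(dp[1] + 1L, dp[2], dp[3]))
    ext[seq_len(dp[1]), , ] <- p
    ext[seq_len(dp[1]) + 1L, , ] <- pmax(ext[seq_len(dp[1]) + 1L, , ,
                                             drop = FALSE],
                                         p)
    m <- aperm(ext, order(perm))
  }
  m
}

#' Euler characteristic of a voxel set
#'
#' Computes the Euler characteristic of the union of closed unit cubes
#' centered on foreground voxels, via the cubical complex counts
#' chi = V - E + F - C (vertices, edges, faces, cells). A solid block
#' gives 1, a solid torus 0, a hollow shell 2; thinning must preserve
#' this number.
#'
#' @param mask A binary \linkS4class{VoxelGrid}.
#' @return Integer Euler characteristic.
#' @export
eulerNumber <- function(mask) {
  stopifnot(is(mask, "VoxelGrid"))
  a <- mask@data
  nCell <- sum(a)
  nFace <- sum(vapply(1:3, function(ax) sum(.orLattice(a, ax)), numeric(1)))
  nEdge <- sum(vapply(1:3, function(ax) {
    sum(.orLattice(a, setdiff(1:3, ax)))
  }, numeric(1)))
  nVert <- sum(.orLattice(a, 1:3))
  as.integer(nVert - nEdge + nFace - nCell)
}
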
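#' @include AllClasses.R
NULL

#' Automatic box-counting scale ladder
#'
#' Chooses a geometric ladder of mesh sizes for a grid. The base adapts
#' to the lattice: when the largest grid dimension is an exact power of
#' 3 the ladder is powers of 3 up to the full dimension (every mesh then
#' tiles the grid exactly — the natural choice for triadic
#' constructions); otherwise the grid is padded to the next power of 2
#' and the ladder is powers of 2 from 1 up to half the padded dimension.
#'
#' @param dims Grid dimensions (integer length 3).
#' @return Increasing integer vector of mesh sizes.
#' @export
#' @examples
#' autoBoxScales(c(27, 27, 27))  # 1 3 9 27
#' autoBoxScales(c(64, 64, 64))  # 1 2 4 8 16 32
autoBoxScales <- function(dims) {
  n <- max(dims)
  k3 <- round(log(n) / log(3))
  if (n == 3^k3 && k3 >= 1) return(as.integer(3^(0:k3)))
  k2 <- ceiling(log2(max(n, 2)))
  as.integer(2^(0:max(2, k2 - 1)))
}

# Count occupied r x r x r cells of `arr` (0/1), origin shifted by
# `offset` (non-negative integer length 3). Grid is padded with zeros to
# a multiple of r after shifting.
.countBoxes <- function(arr, r, offset = c(0L, 0L, 0L)) {
  d <- dim(arr)
  nd <- ceiling((d + offset) / r) * r
  padded <- array(0L, dim = nd)
  padded[offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2]),
         offset[3] + seq_len(d[3])] <- arr
  blocks <- aperm(array(padded, dim = c(r, nd[1] / r, r, nd[2] / r,
                                        r, nd[3] / r)),
                  c(1, 3, 5, 2, 4, 6))
  dim(blocks) <- c(r^3, prod(nd) / r^3)
  sum(colSums(blocks) > 0)
}

#' 3D box counting of a voxel set
#'
#' For each mesh size r, counts the number of r x r x r grid cells
#' containing at least one foreground voxel. With \code{nOffsets > 1}
#' the count at each scale is averaged over a deterministic set of
#' lattice offsets (the zero offset first, then corners of the r-cell),
#' which reduces grid-placement bias at the cost of non-integer counts.
#'
#' @param mask A non-empty binary \linkS4class{VoxelGrid}.
#' @param scales Strictly increasing positive integer mesh sizes, each
#'   at most the largest grid dimension; NULL for [autoBoxScales()].
#' @param nOffsets Number of deterministic offsets per scale (>= 1;
#'   default 1, the zero offset only, for bit-reproducibility).
#' @return A \linkS4class{BoxCountCurve}.
#' @export
#' @examples
#' sponge <- makePhantom("menger", level = 2)
#' boxCount(sponge, scales = c(1, 3, 9))
boxCount <- function(mask, scales = NULL, nOffsets = 1L) {
  stopifnot(is(mask, "VoxelGrid"))
  if (voxelCount(mask) == 0L) stop("box counting needs a non-empty mask")
  d <- dim(mask@data)
  if (is.null(scales)) scales <- autoBoxScales(d)
  scales <- as.integer(scales)
  if (length(scales) < 1L || any(scales <= 0) ||
      any(diff(scales) <= 0) || any(scales > max(d)))
    stop("scales must be strictly increasing positive integers <= max grid dimension")
  nOffsets <- as.integer(nOffsets)
  if (nOffsets < 1L) nOffsets <- 1L
  a <- mask@data
  counts <- vapply(scales, function(r) {
    half <- r %/% 2L
    offs <- unique(as.matrix(expand.grid(c(0L, half), c(0L, half),
                                         c(0L, half))))
    offs <- offs[seq_len(min(nOffsets, nrow(offs))), , drop = FALSE]
    mean(apply(offs, 1, function(o) .countBoxes(a, r, as.integer(o))))
  }, numeric(1))
  new("BoxCountCurve", scales = as.numeric(scales),
      counts = counts, nOffsets = nOffsets)
}

.windowR2 <- function(lr, ln) {
  fit <- lm(ln ~ lr)
  ssTot <- sum((ln - mean(ln))^2)
  ssRes <- sum(fit$residuals^2)
  if (ssTot < 1e-24) return(list(r2 = 1, fit = fit))
  list(r2 = 1 - ssRes / ssTot, fit = fit)
}

#' Select the self-similar (linear) portion of a box-count curve
#'
#' Scans all contiguous windows of at least \code{minPoints} scales and
#' returns the one maximizing the R-squared of the log-log fit, subject
#' to R-squared >= \code{r2Floor}. Ties are broken toward the wider
#' window, then toward the smaller minimum scale. Failure to reach the
#' floor signals a degenerate or non-fractal input and is an error.
#'
#' @param curve A \linkS4class{BoxCountCurve}.
#' @param minPoints Minimum window length (default 4, capped at the
#'   number of available scales).
#' @param r2Floor Minimum acceptable R-squared (default 0.98).
#' @return Numeric length 2: (r_min, r_max).
#' @export
selectScalingRange <- function(curve, minPoints = 4L, r2Floor = 0.98) {
  stopifnot(is(curve, "BoxCountCurve"))
  n <- length(curve@scales)
  minPoints <- min(as.integer(minPoints), n)
  if (n < 3L || minPoints < 3L)
    stop("scaling-range selection needs at least 3 scales")
  lr <- log(curve@scales); ln <- log(curve@counts)
  best <- NULL
  for (len in minPoints:n) {
    for (start in seq_len(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      r2 <- .windowR2(lr[idx], ln[idx])$r2
      if (r2 < r2Floor) next
      cand <- list(r2 = r2, len = len, start = start)
      if (is.null(best) ||
          r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 &&
           (len > best$len ||
            (len == best$len && start < best$start))))
        best <- cand
    }
  }
  if (is.null(best))
    stop(sprintf(
      "no contiguous window of >= %d scales reaches R^2 >= %g; input looks non-fractal or degenerate",
      minPoints, r2Floor))
  idx <- best$start:(best$start + best$len - 1L)
  c(curve@scales[idx[1]], curve@scales[idx[length(idx)]])
}

#' Estimate fractal dimension from a box-count curve
#'
#' Ordinary least squares of log N against log r over the scales inside
#' \code{scaleRange}; the fractal dimension is the slope magnitude and
#' the intercept k is a nuisance parameter. Exactly collinear log-log
#' input is recovered to machine precision. A positive slope (box
#' counts growing with mesh size) is impossible for a valid curve and
#' raises an error rather than being clamped.
#'
#' @param curve A \linkS4class{BoxCountCurve}.
#' @param scaleRange Numeric (r_min, r_max); NULL uses the full curve.
#' @return An \linkS4class{FDEstimate}.
#' @export
#' @examples
#' curve <- new("BoxCountCurve", scales = c(1, 3, 9, 27),
#'              counts = c(8000, 400, 20, 1), nOffsets = 1L)
#' estimateFD(curve)  # log 20 / log 3
estimateFD <- function(curve, scaleRange = NULL) {
  stopifnot(is(curve, "BoxCountCurve"))
  if (is.null(scaleRange))
    scaleRange <- range(curve@scales)
  idx <- which(curve@scales >= scaleRange[1] - 1e-9 &
               curve@scales <= scaleRange[2] + 1e-9)
  if (length(idx) < 3L)
    stop("fewer than 3 scales inside the requested range")
  lr <- log(curve@scales[idx]); ln <- log(curve@counts[idx])
  w <- .windowR2(lr, ln)
  slope <- unname(coef(w$fit)[2])
  if (slope > 1e-9)
    stop("box counts increase with mesh size; invalid curve")
  new("FDEstimate", fd = max(0, -slope), k = unname(coef(w$fit)[1]),
      scaleRange = as.numeric(scaleRange), rSquared = w$r2,
      nPoints = length(idx))
}

#' Fractal dimensions of the three shape representations
#'
#' Runs box counting, scaling-range selection and the log-log fit for
#' the skeleton, surface and general structure of one
#' \linkS4class{ShapeFeatureSet}, with a shared configuration. The
#' computation is deterministic.
#'
#' @param features A \linkS4class{ShapeFeatureSet}.
#' @param scales Mesh sizes; NULL for [autoBoxScales()] on the grid.
#' @param nOffsets Offsets per scale (see [boxCount()]).
#' @param minPoints,r2Floor Passed to [selectScalingRange()].
#' @return Named list of \linkS4class{FDEstimate}s: \code{skeleton},
#'   \code{surface}, \code{general}.
#' @export
featureFD <- function(features, scales = NULL, nOffsets = 1L,
                      minPoints = 4L, r2Floor = 0.98) {
  stopifnot(is(features, "ShapeFeatureSet"))
  out <- lapply(.FD_FEATURES, function(f) {
    grid <- slot(features, f)
    if (voxelCount(grid) == 0L)
      stop(sprintf("feature '%s' (%s) is empty", f, features@hemisphere))
    curve <- boxCount(grid, scales = scales, nOffsets = nOffsets)
    rng <- selectScalingRange(curve, minPoints = minPoints,
                              r2Floor = r2Floor)
    estimateFD(curve, rng)
  })
  names(out) <- .FD_FEATURES
  out
}
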
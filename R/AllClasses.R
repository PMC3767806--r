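#' @include wmfractal-package.R
NULL

.FD_FEATURES <- c("skeleton", "surface", "general")
.FD_REGIONS <- c("lh", "rh", "wb")

#' Names of the nine FD outcome columns
#'
#' Three shape features (skeleton, surface, general structure) crossed with
#' three regions (left hemisphere, right hemisphere, whole brain), in the
#' fixed report order \code{fd_<feature>_<region>}.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' fdOutcomeNames()
fdOutcomeNames <- function() {
  as.vector(t(outer(.FD_FEATURES, .FD_REGIONS,
                    function(f, r) paste("fd", f, r, sep = "_"))))
}

.checkGrid3D <- function(data, voxelSize) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    return("data must be a 3D array")
  if (any(d < 1L))
    return("all grid dimensions must be >= 1")
  if (length(voxelSize) != 3L || any(!is.finite(voxelSize)) ||
      any(voxelSize <= 0))
    return("voxelSize must be 3 strictly positive finite values (mm)")
  TRUE
}

#' ProbabilityVolume: a 3D scalar field of tissue probabilities
#'
#' Holds a white-matter probability map: a 3D array with values in [0, 1]
#' (tolerance 1e-6), physical voxel edge lengths in mm, and an opaque
#' metadata list carried through I/O for round-tripping.
#'
#' @slot data 3D numeric array, values in [0, 1].
#' @slot voxelSize Numeric length 3, mm per axis, strictly positive.
#' @slot affineMeta List of spatial metadata (e.g. a NIfTI header, and
#'   optionally \code{lrAxis}, the index of the left-right axis).
#' @export
setClass("ProbabilityVolume",
         slots = c(data = "array", voxelSize = "numeric",
                   affineMeta = "list"))

setValidity("ProbabilityVolume", function(object) {
  ok <- .checkGrid3D(object@data, object@voxelSize)
  if (!isTRUE(ok)) return(ok)
  v <- object@data
  if (anyNA(v))
    return(sprintf("probability map contains %d NA/NaN voxels",
                   sum(is.na(v))))
  tol <- 1e-6
  bad <- sum(v < -tol | v > 1 + tol)
  if (bad > 0)
    return(sprintf("%d voxels outside [0, 1] beyond tolerance 1e-6", bad))
  TRUE
})

#' Construct a ProbabilityVolume
#'
#' @param data 3D numeric array with values in [0, 1].
#' @param voxelSize Voxel edge lengths in mm (length 3, or a scalar
#'   recycled to 3).
#' @param affineMeta Optional list of spatial metadata.
#' @return A \linkS4class{ProbabilityVolume}.
#' @export
#' @examples
#' pv <- ProbabilityVolume(array(runif(8), c(2, 2, 2)))
ProbabilityVolume <- function(data, voxelSize = c(1, 1, 1),
                              affineMeta = list()) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("ProbabilityVolume", data = data,
      voxelSize = as.numeric(voxelSize), affineMeta = affineMeta)
}

#' VoxelGrid: a 3D binary occupancy grid
#'
#' The universal shape representation in the pipeline: WM mask, skeleton,
#' surface, and hemisphere pieces are all VoxelGrids. Values are exactly
#' 0 or 1 (stored as integer).
#'
#' @slot data 3D integer array of 0/1.
#' @slot voxelSize Numeric length 3, mm per axis, strictly positive.
#' @slot affineMeta List of spatial metadata.
#' @export
setClass("VoxelGrid",
         slots = c(data = "array", voxelSize = "numeric",
                   affineMeta = "list"))

setValidity("VoxelGrid", function(object) {
  ok <- .checkGrid3D(object@data, object@voxelSize)
  if (!isTRUE(ok)) return(ok)
  v <- object@data
  if (anyNA(v) || !all(v == 0L | v == 1L))
    return("VoxelGrid data must be exactly 0 or 1")
  TRUE
})

#' Construct a VoxelGrid
#'
#' Non-integer input is accepted only when every value is exactly 0 or 1.
#'
#' @param data 3D array of 0/1 values (logical, integer or numeric).
#' @param voxelSize Voxel edge lengths in mm (length 3 or scalar).
#' @param affineMeta Optional list of spatial metadata.
#' @return A \linkS4class{VoxelGrid}.
#' @export
#' @examples
#' vg <- VoxelGrid(array(c(1, 0, 0, 1, 1, 0, 0, 0), c(2, 2, 2)))
#' voxelCount(vg)
VoxelGrid <- function(data, voxelSize = c(1, 1, 1), affineMeta = list()) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  d <- dim(data)
  storage <- array(as.integer(round(as.numeric(data))), dim = d)
  if (anyNA(data) || !all(data == 0 | data == 1))
    stop("VoxelGrid data must be exactly 0 or 1 (non-binary input)")
  new("VoxelGrid", data = storage, voxelSize = as.numeric(voxelSize),
      affineMeta = affineMeta)
}

#' BoxCountCurve: box counts over a ladder of mesh sizes
#'
#' Ordered pairs (r, N(r)) from one voxel set: for each mesh size r, the
#' number of r x r x r grid cells containing at least one foreground
#' voxel, optionally averaged over several deterministic lattice offsets
#' (in which case counts may be non-integer).
#'
#' @slot scales Strictly increasing positive integer mesh sizes (voxels).
#' @slot counts Positive box counts, non-increasing in r.
#' @slot nOffsets Number of lattice offsets averaged per scale.
#' @export
setClass("BoxCountCurve",
         slots = c(scales = "numeric", counts = "numeric",
                   nOffsets = "integer"))

setValidity("BoxCountCurve", function(object) {
  r <- object@scales; n <- object@counts
  if (length(r) != length(n) || length(r) < 1L)
    return("scales and counts must be non-empty and of equal length")
  if (any(r <= 0) || any(diff(r) <= 0))
    return("scales must be strictly increasing and positive")
  if (any(n <= 0))
    return("counts must be positive")
  if (any(diff(n) > 1e-9))
    return("counts must be non-increasing as the mesh size grows")
  if (object@nOffsets < 1L)
    return("nOffsets must be >= 1")
  TRUE
})

#' FDEstimate: a fitted fractal dimension
#'
#' Result of the log-log regression log N(r) = -FD * log r + k over a
#' contiguous window of scales. FD is reported as the slope magnitude;
#' k is a nuisance intercept.
#'
#' @slot fd Fitted fractal dimension, in [0, 3.1].
#' @slot k Regression intercept (nuisance).
#' @slot scaleRange Numeric length 2: (r_min, r_max) used in the fit.
#' @slot rSquared Coefficient of determination of the log-log fit.
#' @slot nPoints Number of scales inside the fitted window (>= 3).
#' @export
setClass("FDEstimate",
         slots = c(fd = "numeric", k = "numeric", scaleRange = "numeric",
                   rSquared = "numeric", nPoints = "integer"))

setValidity("FDEstimate", function(object) {
  if (!is.finite(object@fd) || object@fd < -1e-9 || object@fd > 3.1)
    return(sprintf("fd = %.4f outside the admissible range [0, 3.1]",
                   object@fd))
  if (object@nPoints < 3L)
    return("a fractal dimension fit needs at least 3 scales")
  if (length(object@scaleRange) != 2L ||
      object@scaleRange[1] > object@scaleRange[2])
    return("scaleRange must be (r_min, r_max) with r_min <= r_max")
  TRUE
})

#' ShapeFeatureSet: the three WM shape representations of one region
#'
#' Bundles the general structure (all WM voxels), the one-voxel-wide
#' skeleton, and the WM/GM interface surface of one region (left
#' hemisphere, right hemisphere, or whole brain). Skeleton and surface
#' are subsets of the general structure, and all three live on the same
#' grid.
#'
#' @slot general All-WM \linkS4class{VoxelGrid}.
#' @slot skeleton Thinned medial \linkS4class{VoxelGrid}.
#' @slot surface Boundary \linkS4class{VoxelGrid}.
#' @slot hemisphere One of "left", "right", "whole".
#' @export
setClass("ShapeFeatureSet",
         slots = c(general = "VoxelGrid", skeleton = "VoxelGrid",
                   surface = "VoxelGrid", hemisphere = "character"))

setValidity("ShapeFeatureSet", function(object) {
  g <- object@general@data; s <- object@skeleton@data; f <- object@surface@data
  if (!identical(dim(g), dim(s)) || !identical(dim(g), dim(f)))
    return("general, skeleton and surface must share grid dimensions")
  if (!isTRUE(all.equal(object@general@voxelSize,
                        object@skeleton@voxelSize)) ||
      !isTRUE(all.equal(object@general@voxelSize,
                        object@surface@voxelSize)))
    return("general, skeleton and surface must share voxel size")
  if (any(s > g)) return("skeleton must be a subset of the general structure")
  if (any(f > g)) return("surface must be a subset of the general structure")
  if (!(object@hemisphere %in% c("left", "right", "whole")))
    return("hemisphere must be one of 'left', 'right', 'whole'")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @param x An object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Accessors for volume, curve and estimate objects
#'
#' \code{voxelData} returns the raw 3D array; \code{voxelSize} the mm edge
#' lengths; \code{voxelCount} the number of foreground voxels;
#' \code{gridDim} the grid dimensions; \code{scales}/\code{boxCounts} the
#' box-counting curve; \code{fdValue}, \code{fdIntercept},
#' \code{fdScaleRange} and \code{fdRSquared} the components of an
#' \linkS4class{FDEstimate}.
#'
#' @name accessors
#' @aliases voxelData voxelSize voxelCount gridDim
NULL

#' @rdname accessors
setMethod("voxelData", "ProbabilityVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelData", "VoxelGrid", function(x) x@data)
#' @rdname accessors
setMethod("voxelSize", "ProbabilityVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelCount", "VoxelGrid", function(x) sum(x@data))
#' @rdname accessors
setMethod("gridDim", "ProbabilityVolume", function(x) dim(x@data))
#' @rdname accessors
setMethod("gridDim", "VoxelGrid", function(x) dim(x@data))

#' @rdname accessors
#' @export
scales <- function(x) {
  stopifnot(is(x, "BoxCountCurve")); x@scales
}
#' @rdname accessors
#' @export
boxCounts <- function(x) {
  stopifnot(is(x, "BoxCountCurve")); x@counts
}
#' @rdname accessors
#' @export
fdValue <- function(x) {
  stopifnot(is(x, "FDEstimate")); x@fd
}
#' @rdname accessors
#' @export
fdIntercept <- function(x) {
  stopifnot(is(x, "FDEstimate")); x@k
}
#' @rdname accessors
#' @export
fdScaleRange <- function(x) {
  stopifnot(is(x, "FDEstimate")); x@scaleRange
}
#' @rdname accessors
#' @export
fdRSquared <- function(x) {
  stopifnot(is(x, "FDEstimate")); x@rSquared
}

# ---- show ------------------------------------------------------------------

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityVolume %dx%dx%d, voxel %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
  cat(sprintf("  values in [%.3g, %.3g], mean %.4g\n",
              min(object@data), max(object@data), mean(object@data)))
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid %dx%dx%d, voxel %.3gx%.3gx%.3g mm, %d foreground voxels\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], sum(object@data)))
})

setMethod("show", "BoxCountCurve", function(object) {
  cat(sprintf("BoxCountCurve with %d scales (offsets averaged: %d)\n",
              length(object@scales), object@nOffsets))
  print(data.frame(r = object@scales, N = object@counts),
        row.names = FALSE)
})

setMethod("show", "FDEstimate", function(object) {
  cat(sprintf(
    "FDEstimate: fd = %.4f (k = %.3f), scales [%g, %g], %d points, R^2 = %.5f\n",
    object@fd, object@k, object@scaleRange[1], object@scaleRange[2],
    object@nPoints, object@rSquared))
})

setMethod("show", "ShapeFeatureSet", function(object) {
  cat(sprintf(
    "ShapeFeatureSet (%s): general %d, surface %d, skeleton %d voxels\n",
    object@hemisphere, sum(object@general@data), sum(object@surface@data),
    sum(object@skeleton@data)))
})
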
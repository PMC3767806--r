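#' @include AllClasses.R
NULL

#' Read a 3D probability volume from a NIfTI file
#'
#' Loads a white-matter probability map, squeezes trailing singleton
#' axes, validates values against [0, 1], and preserves the NIfTI header
#' for round-tripping. NaN voxels are an error (their count is reported).
#'
#' @param path Path to a NIfTI-1 file (.nii or .nii.gz).
#' @return A \linkS4class{ProbabilityVolume}.
#' @seealso [writeVolume()], [resampleIsotropic()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- .squeezeTo3D(array(as.numeric(img), dim = dim(img)))
  nbad <- sum(is.na(arr))
  if (nbad > 0)
    stop(sprintf("volume %s contains %d NaN/NA voxels", path, nbad))
  vs <- RNifti::pixdim(img)
  if (length(vs) < 3L || any(!is.finite(vs[1:3])) || any(vs[1:3] <= 0))
    vs <- c(1, 1, 1)
  ProbabilityVolume(arr, voxelSize = vs[1:3],
                    affineMeta = list(header = RNifti::niftiHeader(img)))
}

#' Write a volume or mask to a NIfTI file
#'
#' @param vol A \linkS4class{ProbabilityVolume} or \linkS4class{VoxelGrid}.
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ProbabilityVolume") || is(vol, "VoxelGrid"))
  arr <- vol@data
  if (is(vol, "VoxelGrid")) storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelSize(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# given per axis; coordinates are clamped to the grid.
.trilinear <- function(arr, xs, ys, zs) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  grid <- expand.grid(x = xs, y = ys, z = zs)
  x0 <- cl(floor(grid$x), d[1]); x1 <- cl(x0 + 1, d[1])
  y0 <- cl(floor(grid$y), d[2]); y1 <- cl(y0 + 1, d[2])
  z0 <- cl(floor(grid$z), d[3]); z1 <- cl(z0 + 1, d[3])
  fx <- .clip(grid$x - floor(grid$x), 0, 1)
  fy <- .clip(grid$y - floor(grid$y), 0, 1)
  fz <- .clip(grid$z - floor(grid$z), 0, 1)
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    at(x1, y1, z0) * fx       * fy       * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx       * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy       * fz +
    at(x1, y1, z1) * fx       * fy       * fz
  array(v, dim = c(length(xs), length(ys), length(zs)))
}

#' Resample a probability volume to isotropic voxels
#'
#' Box counting and thinning assume cubic cells; anisotropic inputs are
#' resampled by trilinear interpolation onto a grid of cubic voxels of
#' edge \code{targetMm}. Binarization should happen after resampling, so
#' interpolation is linear to preserve the 0.5 level set. Already
#' isotropic inputs at the target are returned unchanged, which makes
#' the operation idempotent.
#'
#' @param vol A \linkS4class{ProbabilityVolume}.
#' @param targetMm Target isotropic voxel edge in mm (default 1.0).
#' @return A \linkS4class{ProbabilityVolume} with equal voxel sizes.
#' @export
resampleIsotropic <- function(vol, targetMm = 1.0) {
  stopifnot(is(vol, "ProbabilityVolume"))
  if (!is.numeric(targetMm) || length(targetMm) != 1L || targetMm <= 0)
    stop("targetMm must be a single positive number")
  vs <- voxelSize(vol)
  if (all(abs(vs - targetMm) < 1e-9)) return(vol)
  d <- dim(vol@data)
  extent <- d * vs
  nd <- pmax(1L, as.integer(round(extent / targetMm)))
  # centers of the new voxels expressed in source voxel index coordinates
  coords <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 0.5) * targetMm) / vs[a] + 0.5
  })
  arr <- .trilinear(vol@data, coords[[1]], coords[[2]], coords[[3]])
  ProbabilityVolume(.clip(arr, 0, 1), voxelSize = rep(targetMm, 3),
                    affineMeta = vol@affineMeta)
}

.REPORT_COLUMNS <- function() {
  c("subject_id", "group", "age", "gender", "alsfrs_r",
    "duration_months", "ees", fdOutcomeNames())
}

#' Write a cohort FD report as TSV
#'
#' Writes one row per subject with the fixed column order: subject_id,
#' group, age, gender, alsfrs_r, duration_months, ees, then the nine FD
#' outcomes \code{fd_<feature>_<region>}. Missing FD columns are an
#' error; extra columns are appended after the fixed block.
#'
#' @param rows Data frame with at least the fixed columns.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @seealso [readFDReport()]
#' @export
writeFDReport <- function(rows, path) {
  need <- .REPORT_COLUMNS()
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0)
    stop(sprintf("FD report is missing required columns: %s",
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(rows), need)
  out <- rows[, c(need, extra), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort FD report written by [writeFDReport()]
#'
#' @param path TSV path.
#' @return Data frame with the report columns.
#' @export
readFDReport <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing <- setdiff(.REPORT_COLUMNS(), names(tab))
  if (length(missing) > 0)
    stop(sprintf("not an FD report, missing columns: %s",
                 paste(missing, collapse = ", ")))
  tab
}
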
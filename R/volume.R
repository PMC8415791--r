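#' Construct a 3D scalar volume
#'
#' A `scalar_volume` couples a 3D intensity grid with its voxel geometry:
#' per-axis spacing in mm and a 4x4 index-to-world affine (mm, RAS). The
#' affine maps 0-based voxel indices to world coordinates.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 index-to-world matrix; default is `diag(spacing)` with
#'   zero origin.
#' @return An object of class `scalar_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array; got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxel(s)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("affine must be a 4x4 matrix")
  }
  structure(list(data = data, spacing = spacing, affine = unname(affine)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], voxel volume %.5g mm^3\n",
              min(x$data), max(x$data), voxel_volume(x)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' Voxel volume in mm^3
#'
#' Product of the three voxel edge lengths. Vascular volume is defined as the
#' suprathreshold voxel count multiplied by this quantity.
#'
#' @param x a `scalar_volume`, `region_mask`, or numeric length-3 spacing.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(x) {
  sp <- if (is.numeric(x)) x else x$spacing
  stopifnot(length(sp) == 3L, all(sp > 0))
  prod(sp)
}

# 0-based voxel indices (n x 3) -> world mm (n x 3)
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# world mm (n x 3) -> 0-based continuous voxel indices (n x 3)
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Spacing is taken from the header `pixdim`, the affine from the sform when
#' set (qform otherwise).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions: ", path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  scalar_volume(array(as.numeric(img), dim = d),
                spacing = RNifti::pixdim(img)[1:3],
                affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Intensities are stored as float64 by default so that thresholds computed
#' on a reloaded volume match the in-memory pipeline bit-for-bit.
#'
#' @param vol a [scalar_volume()] or [region_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type (see [RNifti::writeNifti()]).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  dat <- if (inherits(vol, "region_mask")) vol$labels else vol$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  aff <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
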
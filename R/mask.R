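#' Construct an integer region label mask
#'
#' Labels subcortical regions (putamen, globus pallidus, caudate, internal
#' capsule, parent artery, ...) on a voxel grid. Background is label 0; the
#' legend maps region names to positive integer label ids. Labels are
#' pairwise disjoint by construction (one integer per voxel).
#'
#' @param labels 3D array of non-negative integers.
#' @param legend named integer vector or list, region-name -> label id.
#' @param spacing voxel spacing in mm.
#' @param affine 4x4 index-to-world affine; default `diag(spacing)`.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(labels, legend, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  legend <- unlist(legend)
  if (is.null(names(legend)) || any(names(legend) == ""))
    stop("legend must be a named region-name -> label mapping")
  if (anyDuplicated(legend)) stop("legend label ids must be unique")
  if (any(legend <= 0)) stop("legend ids must be positive (0 is background)")
  spacing <- as.numeric(spacing)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(labels = array(as.integer(round(labels)), dim = dim(labels)),
                 legend = vapply(legend, as.integer, integer(1)),
                 spacing = spacing, affine = unname(as.matrix(affine))),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<region_mask> %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], length(x$legend)))
  for (nm in names(x$legend))
    cat(sprintf("  %-18s label %d: %d voxels\n", nm, x$legend[[nm]],
                sum(x$labels == x$legend[[nm]])))
  invisible(x)
}

#' @export
dim.region_mask <- function(x) dim(x$labels)

#' Read a region label mask with its legend sidecar
#'
#' The legend is a YAML or JSON mapping `{region-name: label-int}` in a
#' sidecar file.
#'
#' @param path NIfTI-1 label image.
#' @param legend_path YAML (`.yaml`/`.yml`) or JSON legend sidecar.
#' @return a [region_mask()].
#' @export
read_region_mask <- function(path, legend_path) {
  vol <- read_volume(path)
  legend <- if (grepl("\\.ya?ml$", legend_path))
    yaml::read_yaml(legend_path)
  else jsonlite::read_json(legend_path, simplifyVector = TRUE)
  region_mask(vol$data, legend, spacing = vol$spacing, affine = vol$affine)
}

#' Write a region mask and its legend sidecar
#' @param mask a [region_mask()].
#' @param path output NIfTI path.
#' @param legend_path output legend path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path, legend_path = NULL) {
  write_volume(mask, path)
  if (!is.null(legend_path)) {
    if (grepl("\\.ya?ml$", legend_path))
      yaml::write_yaml(as.list(mask$legend), legend_path)
    else jsonlite::write_json(as.list(mask$legend), legend_path,
                              auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a 4x4 world-to-world affine from whitespace-delimited text
#' @param path text file with 4 rows of 4 numbers (mm).
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4, 4))) stop("affine file must contain a 4x4 matrix")
  unname(m)
}

#' Resample a label mask onto a target volume grid
#'
#' Brings an externally produced region mask onto the subject grid through a
#' world-to-world affine (e.g. a registration result), using
#' nearest-neighbour interpolation — labels are categorical, so no other
#' interpolant is admissible. Voxels that map outside the source grid become
#' background.
#'
#' @param mask a [region_mask()] on its own grid.
#' @param transform 4x4 world-to-world affine mapping mask-world coordinates
#'   into target-world coordinates (mm). Identity by default.
#' @param target a [scalar_volume()] defining the output grid.
#' @return a [region_mask()] on the target grid; legend preserved.
#' @export
resample_mask_to_grid <- function(mask, transform = diag(4), target) {
  stopifnot(inherits(mask, "region_mask"), inherits(target, "scalar_volume"))
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4, 4))) stop("transform must be 4x4")
  if (abs(det(transform)) < 1e-12)
    stop("transform is singular and cannot be inverted")
  d <- dim(target$data)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  world_t <- voxel_to_world(target$affine, ijk)
  world_m <- cbind(world_t, 1) %*% t(solve(transform))
  src <- round(world_to_voxel(mask$affine, world_m[, 1:3, drop = FALSE]))
  dm <- dim(mask$labels)
  ok <- src[, 1] >= 0 & src[, 1] < dm[1] &
        src[, 2] >= 0 & src[, 2] < dm[2] &
        src[, 3] >= 0 & src[, 3] < dm[3]
  out <- integer(nrow(src))
  lin <- 1L + src[ok, 1] + dm[1] * (src[ok, 2] + dm[2] * src[ok, 3])
  out[ok] <- mask$labels[lin]
  region_mask(array(out, dim = d), mask$legend,
              spacing = target$spacing, affine = target$affine)
}

# union binary mask of named regions (3D logical array)
region_union <- function(mask, region_names = names(mask$legend)) {
  unknown <- setdiff(region_names, names(mask$legend))
  if (length(unknown) > 0)
    stop("unknown region name(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(names(mask$legend), collapse = ", "))
  if (length(region_names) == 0)
    return(array(FALSE, dim = dim(mask$labels)))
  array(mask$labels %in% unlist(mask$legend[region_names]),
        dim = dim(mask$labels))
}

#' Restrict a volume to named regions
#'
#' Voxels outside the union of the named regions are set to 0; in-mask voxels
#' are unchanged. Used to extract the enhanced vasculature inside the LSA
#' supply territories before thresholding.
#'
#' @param volume a [scalar_volume()] aligned to `mask`.
#' @param mask a [region_mask()] on the same grid.
#' @param region_names character vector of legend names (default: all).
#' @return a [scalar_volume()].
#' @export
restrict_to_regions <- function(volume, mask,
                                region_names = names(mask$legend)) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(mask, "region_mask"))
  if (!all(dim(volume$data) == dim(mask$labels)))
    stop("volume and mask grids differ: ",
         paste(dim(volume$data), collapse = "x"), " vs ",
         paste(dim(mask$labels), collapse = "x"))
  keep <- region_union(mask, region_names)
  out <- volume$data
  out[!keep] <- 0
  scalar_volume(out, spacing = volume$spacing, affine = volume$affine)
}
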
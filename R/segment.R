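#' Adaptive threshold selection by the volume-ratio scheme
#'
#' Formalises threshold adjustment for binarising the enhanced angiogram:
#' candidate thresholds descend linearly over the in-ROI intensity range in
#' steps of `step_percent` percent of the range; at each step the
#' vessel-to-ROI volume ratio (suprathreshold voxels / total ROI voxels, in
#' percent) is recomputed. Walking down from the top, vessel voxels accrue
#' slowly; the first step whose ratio change exceeds `delta_star` marks the
#' onset of parenchymal tissue, and the previous candidate is selected,
#' after backing off any sub-threshold accrual contiguous with the onset
#' (bounded by one `delta_star` of cumulative mass) so the selection sits
#' at the top of the parenchyma mode. The full sweep curves are returned
#' for audit.
#'
#' @param enhanced a [scalar_volume()] of vesselness (or any contrast in
#'   which vessels are bright).
#' @param roi optional [region_mask()]; candidates and ratios are computed
#'   over the union of `region_names`. Without an ROI the whole grid is used.
#' @param region_names legend names defining the ROI union.
#' @param step_percent candidate spacing, percent of the in-ROI intensity
#'   range per step (0 < step <= 5; default 0.5).
#' @param delta_star stopping constant, percentage points of the volume
#'   ratio (default 0.2).
#' @return object of class `threshold_selection`: `candidates` (descending),
#'   `volume_curve` (suprathreshold voxel count per candidate),
#'   `ratio_change_curve` (per-step change of the volume ratio, percent),
#'   `selected_threshold`, `selected_step_index` (0-based into
#'   `candidates`), `n_roi`.
#' @export
select_threshold <- function(enhanced, roi = NULL,
                             region_names = if (!is.null(roi)) names(roi$legend),
                             step_percent = 0.5, delta_star = 0.2) {
  stopifnot(inherits(enhanced, "scalar_volume"),
            step_percent > 0, step_percent <= 5, delta_star > 0)
  vals <- if (is.null(roi)) as.numeric(enhanced$data)
  else enhanced$data[region_union(roi, region_names)]
  if (length(vals) == 0) stop("ROI selection is empty")
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo)
    stop("degenerate input: enhanced image is constant inside the ROI")
  nstep <- ceiling(100 / step_percent)
  candidates <- hi - (0:nstep) / nstep * (hi - lo)
  sorted <- sort(vals)
  n <- length(sorted)
  # count of voxels >= t for each candidate
  counts <- n - findInterval(candidates, sorted, left.open = TRUE)
  ratio <- 100 * counts / n
  dratio <- diff(ratio)                 # >= 0: candidates descend
  stop_at <- which(dratio > delta_star)[1]
  if (is.na(stop_at))
    stop("no threshold step changed the volume ratio by more than ",
         delta_star, "%; decrease step_percent or delta_star")
  # back off over sub-threshold accrual contiguous with the onset (it
  # belongs to the parenchyma mode), bounded by one delta_star of mass, so
  # the selected threshold sits at the top of the onset, not one step into it
  sel_idx <- stop_at
  cum <- 0
  while (sel_idx > 1 && dratio[sel_idx - 1] > 0 &&
         cum + dratio[sel_idx - 1] <= delta_star) {
    cum <- cum + dratio[sel_idx - 1]
    sel_idx <- sel_idx - 1
  }
  structure(list(candidates = candidates,
                 volume_curve = counts,
                 ratio_curve = ratio,
                 ratio_change_curve = dratio,
                 selected_threshold = candidates[sel_idx],
                 selected_step_index = sel_idx - 1L,
                 n_roi = n,
                 step_percent = step_percent,
                 delta_star = delta_star),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold_selection> threshold %.6g at step %d/%d (ratio %.3g%% of ROI)\n",
              x$selected_threshold, x$selected_step_index,
              length(x$candidates) - 1L,
              x$ratio_curve[x$selected_step_index + 1L]))
  invisible(x)
}

# one 26-dilation of a logical array
dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(1:d[1] + dx, 1), d[1])
    ys <- pmin(pmax(1:d[2] + dy, 1), d[2])
    zs <- pmin(pmax(1:d[3] + dz, 1), d[3])
    out <- out | m[xs, ys, zs]
  }
  out
}

#' Extract vessel voxels above the selected threshold
#'
#' Binarises the enhanced image at the selected threshold inside the ROI.
#' When a seed voxel is supplied, only 26-connected components belonging to
#' the seeded vessel tree are kept: the component containing (or nearest to)
#' the seed, plus components touching its 1-voxel dilation. Without a seed,
#' all suprathreshold in-ROI voxels are kept (fully automatic batch mode).
#'
#' @param enhanced a [scalar_volume()].
#' @param selection a [select_threshold()] result (or a bare numeric
#'   threshold).
#' @param roi optional [region_mask()] restricting the mask.
#' @param region_names legend names of the ROI union.
#' @param seed_voxel optional 1-based integer voxel index (length 3). If it
#'   falls below the threshold, the nearest suprathreshold voxel within 5
#'   voxels is used with a warning.
#' @return 3D logical vessel mask.
#' @export
extract_vessels <- function(enhanced, selection, roi = NULL,
                            region_names = if (!is.null(roi)) names(roi$legend),
                            seed_voxel = NULL) {
  stopifnot(inherits(enhanced, "scalar_volume"))
  thr <- if (inherits(selection, "threshold_selection"))
    selection$selected_threshold else as.numeric(selection)
  mask <- enhanced$data >= thr
  if (!is.null(roi)) mask <- mask & region_union(roi, region_names)
  if (is.null(seed_voxel) || !any(mask)) return(mask)

  d <- dim(mask)
  seed_voxel <- as.integer(seed_voxel)
  stopifnot(length(seed_voxel) == 3L)
  if (any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed voxel ", paste(seed_voxel, collapse = ","), " outside grid")
  if (!mask[seed_voxel[1], seed_voxel[2], seed_voxel[3]]) {
    idx <- which(mask, arr.ind = TRUE)
    d2 <- colSums((t(idx) - seed_voxel)^2)
    if (min(d2) > 25)
      stop("no suprathreshold voxel within 5 voxels of the seed")
    warning("seed voxel is below threshold; using nearest suprathreshold ",
            "voxel at distance ", round(sqrt(min(d2)), 2), " voxels")
    seed_voxel <- idx[which.min(d2), ]
  }
  lab <- array(.cpp_label_components(mask, d, 26L), dim = d)
  seed_comp <- lab[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  near <- dilate26(dilate26(lab == seed_comp))
  keep_ids <- unique(lab[near & lab > 0])
  mask & array(lab %in% keep_ids, dim = d)
}

#' Per-region vascular volume report
#'
#' Vascular volume is the suprathreshold voxel count multiplied by the voxel
#' volume (product of the three voxel edge lengths). Counts are intersected
#' with each named region; fractions are taken over all vessel voxels in the
#' region union, and flagged undefined (NA) when that total is zero.
#'
#' @param vessel_mask 3D logical array.
#' @param roi a [region_mask()] on the same grid.
#' @param region_names regions to report (default: all legend entries).
#' @param spacing optional mm spacing override; must agree with the ROI
#'   carrier's spacing when both are available.
#' @return object of class `region_volume_report` with `per_region` (data
#'   frame: region, voxels, volume_mm3, fraction), `total_voxel_count`,
#'   `total_volume_mm3`, `voxel_volume_mm3`.
#' @export
quantify_region_volumes <- function(vessel_mask, roi,
                                    region_names = names(roi$legend),
                                    spacing = NULL) {
  stopifnot(inherits(roi, "region_mask"))
  if (!all(dim(vessel_mask) == dim(roi$labels)))
    stop("vessel mask and ROI grids differ")
  if (!is.null(spacing)) {
    if (max(abs(spacing - roi$spacing)) > 1e-6)
      stop("spacing mismatch: supplied ", paste(spacing, collapse = "x"),
           " vs ROI ", paste(roi$spacing, collapse = "x"))
  } else spacing <- roi$spacing
  vv <- voxel_volume(spacing)
  counts <- vapply(region_names, function(nm)
    sum(vessel_mask & roi$labels == roi$legend[[nm]]), numeric(1))
  total <- sum(vessel_mask & region_union(roi, region_names))
  per <- data.frame(region = region_names,
                    voxels = as.integer(counts),
                    volume_mm3 = counts * vv,
                    fraction = if (total > 0) counts / total
                               else rep(NA_real_, length(counts)),
                    row.names = NULL)
  stopifnot(all(per$volume_mm3 == per$voxels * vv))   # exact arithmetic
  structure(list(per_region = per,
                 total_voxel_count = as.integer(total),
                 total_volume_mm3 = total * vv,
                 voxel_volume_mm3 = vv,
                 fractions_defined = total > 0),
            class = "region_volume_report")
}

#' @export
print.region_volume_report <- function(x, ...) {
  cat(sprintf("<region_volume_report> %d vessel voxels, %.4g mm^3 (voxel %.5g mm^3)\n",
              x$total_voxel_count, x$total_volume_mm3, x$voxel_volume_mm3))
  print(x$per_region, row.names = FALSE)
  invisible(x)
}

#' Flag large-artery contamination
#'
#' Components of the vessel mask whose maximum inscribed radius (from the
#' Euclidean distance transform) exceeds half the maximum expected vessel
#' diameter are flagged: they indicate large parent arteries leaking into
#' the subcortical ROI, which contaminate the vascular volume and exclude
#' the case from analysis.
#'
#' @param vessel_mask 3D logical array.
#' @param spacing mm voxel spacing.
#' @param d_max maximum expected vessel diameter, voxels (default 5);
#'   converted to mm via the mean spacing.
#' @return object of class `vessel_qc`: `pass`, `radius_limit_mm`,
#'   `components` (data frame id / voxels / max_radius_mm / flagged).
#' @export
flag_large_vessels <- function(vessel_mask, spacing, d_max = 5) {
  stopifnot(length(spacing) == 3L, d_max > 0)
  limit <- d_max / 2 * mean(spacing)
  d <- dim(vessel_mask)
  if (!any(vessel_mask))
    return(structure(list(pass = TRUE, radius_limit_mm = limit,
                          components = data.frame(id = integer(),
                                                  voxels = integer(),
                                                  max_radius_mm = numeric(),
                                                  flagged = logical())),
                     class = "vessel_qc"))
  lab <- .cpp_label_components(vessel_mask, d, 26L)
  ncomp <- attr(lab, "n_components")
  edt <- sqrt(.cpp_edt_sq(as.logical(vessel_mask), d, as.numeric(spacing)))
  maxr <- vapply(seq_len(ncomp), function(i) max(edt[lab == i]), numeric(1))
  nv <- tabulate(lab[lab > 0], ncomp)
  comp <- data.frame(id = seq_len(ncomp), voxels = nv,
                     max_radius_mm = maxr, flagged = maxr > limit)
  structure(list(pass = !any(comp$flagged), radius_limit_mm = limit,
                 components = comp),
            class = "vessel_qc")
}

#' @export
print.vessel_qc <- function(x, ...) {
  cat(sprintf("<vessel_qc> %s (inscribed-radius limit %.3g mm, %d component(s), %d flagged)\n",
              if (x$pass) "PASS" else "FAIL: large-artery contamination",
              x$radius_limit_mm, nrow(x$components), sum(x$components$flagged)))
  invisible(x)
}

#' Dice overlap between two binary masks
#' @param a,b logical arrays of equal dimension.
#' @return Dice coefficient in [0, 1]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
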
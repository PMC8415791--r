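#' Specification of a synthetic vessel tree
#'
#' Parameters of a recursive binary branching tree emulating lenticulostriate
#' artery morphology: thin (~1-5 voxel diameter) perforators arising from a
#' parent artery and fanning upwards through the basal ganglia.
#'
#' @param root_position mm coordinates (length 3) of the trunk origin.
#' @param root_direction initial unit growth direction (default superior).
#' @param root_radius trunk radius in mm (> 0). The default 0.4 mm (0.8 mm
#'   diameter, 2 voxels at the default grid) matches the caliber of the
#'   larger lenticulostriate perforators visible on 7T TOF-MRA.
#' @param n_generations number of branching generations (>= 0); 0 gives a
#'   single unbranched trunk.
#' @param n_trunks number of independent trunks sharing the root region.
#' @param branching_angle_range degrees, c(min, max) half-angle at each
#'   bifurcation.
#' @param length_range mm, c(min, max) segment length.
#' @param radius_ratio child/parent radius factor in (0, 1].
#' @param curvature maximal bend in degrees per mm of arc.
#' @param step_mm polyline sampling step in mm.
#' @param seed integer RNG seed; all randomness in tree generation flows
#'   from it.
#' @return an object of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(root_position = c(19.2, 19.2, 4),
                             root_direction = c(0, 0, 1),
                             root_radius = 0.4,
                             n_generations = 2L,
                             n_trunks = 1L,
                             branching_angle_range = c(25, 50),
                             length_range = c(8, 14),
                             radius_ratio = 0.8,
                             curvature = 5,
                             step_mm = 0.4,
                             seed = 1L) {
  stopifnot(root_radius > 0, n_generations >= 0,
            radius_ratio > 0, radius_ratio <= 1,
            length_range[1] > 0, diff(length_range) >= 0,
            curvature >= 0, step_mm > 0, n_trunks >= 1)
  structure(list(root_position = as.numeric(root_position),
                 root_direction = as.numeric(root_direction) /
                   sqrt(sum(root_direction^2)),
                 root_radius = root_radius,
                 n_generations = as.integer(n_generations),
                 n_trunks = as.integer(n_trunks),
                 branching_angle_range = as.numeric(branching_angle_range),
                 length_range = as.numeric(length_range),
                 radius_ratio = radius_ratio,
                 curvature = curvature,
                 step_mm = step_mm,
                 seed = as.integer(seed)),
            class = "vessel_tree_spec")
}

# Rodrigues rotation of vector v about unit axis a by angle (radians)
rotate_about <- function(v, a, angle) {
  a <- a / sqrt(sum(a^2))
  v * cos(angle) + c(a[2] * v[3] - a[3] * v[2],
                     a[3] * v[1] - a[1] * v[3],
                     a[1] * v[2] - a[2] * v[1]) * sin(angle) +
    a * sum(a * v) * (1 - cos(angle))
}

random_perpendicular <- function(u) {
  repeat {
    r <- rnorm(3)
    p <- r - sum(r * u) * u
    n <- sqrt(sum(p^2))
    if (n > 1e-6) return(p / n)
  }
}

#' Generate a synthetic vessel centerline tree
#'
#' Deterministic given the spec seed. Each segment is a smooth polyline with
#' per-step bend bounded by the curvature limit; child radii follow the
#' radius ratio. Growth is clipped to `bounds` with a warning (never silent
#' growth outside the grid).
#'
#' @param spec a [vessel_tree_spec()].
#' @param bounds optional 2x3 matrix, rows = c(min, max) world mm per axis.
#' @return object of class `vessel_tree`: list with `segments` (each with
#'   `id`, `parent` (NA for trunks), `generation`, `trunk`, `points` (m x 3
#'   mm polyline), `radius` mm) and the originating `spec`.
#' @export
generate_vessel_tree <- function(spec, bounds = NULL) {
  stopifnot(inherits(spec, "vessel_tree_spec"))
  segments <- list()
  truncated <- FALSE

  grow_segment <- function(start, dir, radius, generation, parent, trunk) {
    len <- runif(1, spec$length_range[1], spec$length_range[2])
    nstep <- max(2L, as.integer(ceiling(len / spec$step_mm)))
    pts <- matrix(0, nstep + 1, 3)
    pts[1, ] <- start
    u <- dir
    max_bend <- spec$curvature * spec$step_mm * pi / 180
    for (s in seq_len(nstep)) {
      if (max_bend > 0)
        u <- rotate_about(u, random_perpendicular(u), runif(1, 0, max_bend))
      p <- pts[s, ] + u * spec$step_mm
      if (!is.null(bounds) &&
          (any(p < bounds[1, ] + radius) || any(p > bounds[2, ] - radius))) {
        pts <- pts[seq_len(s), , drop = FALSE]
        truncated <<- TRUE
        break
      }
      pts[s + 1, ] <- p
    }
    id <- length(segments) + 1L
    segments[[id]] <<- list(id = id, parent = parent,
                            generation = generation, trunk = trunk,
                            points = pts, radius = radius)
    if (generation < spec$n_generations && nrow(pts) > 2) {
      ang <- runif(2, spec$branching_angle_range[1],
                   spec$branching_angle_range[2]) * pi / 180
      axis <- random_perpendicular(u)
      for (child in 1:2) {
        cdir <- rotate_about(u, axis, if (child == 1) ang[1] else -ang[2])
        grow_segment(pts[nrow(pts), ], cdir, radius * spec$radius_ratio,
                     generation + 1L, id, trunk)
      }
    }
    invisible(NULL)
  }

  with_local_seed(spec$seed, {
    for (tr in seq_len(spec$n_trunks)) {
      offset <- if (spec$n_trunks == 1) c(0, 0, 0) else
        c((tr - (spec$n_trunks + 1) / 2) * 6, 0, 0)
      d0 <- spec$root_direction
      if (spec$n_trunks > 1) {
        d0 <- d0 + c(runif(1, -0.15, 0.15), runif(1, -0.15, 0.15), 0)
        d0 <- d0 / sqrt(sum(d0^2))
      }
      grow_segment(spec$root_position + offset, d0, spec$root_radius, 0L,
                   NA_integer_, tr)
    }
  })
  if (truncated)
    warning("vessel tree truncated at the stated bounding box")
  structure(list(segments = segments, spec = spec, truncated = truncated),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  gen <- vapply(x$segments, `[[`, integer(1), "generation")
  cat(sprintf("<vessel_tree> %d segments, %d trunk(s), %d generation(s), %d leaf tip(s)\n",
              length(x$segments), x$spec$n_trunks, max(gen),
              n_leaf_segments(x)))
  invisible(x)
}

# leaf segments = segments that are nobody's parent
n_leaf_segments <- function(tree) {
  parents <- vapply(tree$segments, `[[`, integer(1), "parent")
  sum(!(vapply(tree$segments, `[[`, integer(1), "id") %in% parents))
}

#' Render a vessel tree into a synthetic TOF-like angiogram
#'
#' Voxels within a tube radius of the centerline receive the vessel
#' intensity with a linear soft-edge falloff of width `edge_softness`; a
#' smooth multiplicative bias field in `[1 - a, 1 + a]` and Rician (or
#' Gaussian) noise are applied afterwards. The ground-truth vessel mask is a
#' hard geometric rule evaluated before noise: voxel centers within the tube
#' radius.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param dims grid dimensions (length 3).
#' @param spacing voxel spacing, mm.
#' @param vessel_intensity,background_intensity image intensities (vessel >
#'   background >= 0).
#' @param edge_softness mm width of the intensity falloff at the tube wall.
#' @param bias_amplitude a in `[0, 1)`: bias field range `[1 - a, 1 + a]`.
#' @param bias_smoothness mm smoothing scale of the bias field.
#' @param noise_sigma Rician noise parameter (intensity units).
#' @param noise_type `"rician"` (magnitude-MR default) or `"gaussian"`.
#' @param seed RNG seed for bias and noise.
#' @return list with `volume` (a [scalar_volume()]) and `truth` (class
#'   `phantom_truth`: `vessel_mask`, `centerline` segments, `bias_field`,
#'   generator parameters).
#' @export
render_angiogram <- function(tree, dims = c(96, 96, 96),
                             spacing = c(0.4, 0.4, 0.4),
                             vessel_intensity = 300,
                             background_intensity = 100,
                             edge_softness = 0.4,
                             bias_amplitude = 0,
                             bias_smoothness = 20,
                             noise_sigma = 0,
                             noise_type = c("rician", "gaussian"),
                             seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"),
            vessel_intensity > background_intensity,
            background_intensity >= 0, bias_amplitude >= 0, bias_amplitude < 1,
            noise_sigma >= 0)
  noise_type <- match.arg(noise_type)
  dims <- as.integer(dims)
  radii <- vapply(tree$segments, `[[`, numeric(1), "radius")
  if (any(radii < 0.5 * min(spacing)))
    warning("sub-voxel vessel: some tube radii are below half the smallest ",
            "voxel spacing; rendered anyway")

  # signed surface margin field: min over tube segments of (distance - radius)
  margin <- array(Inf, dim = dims)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  for (seg in tree$segments) {
    pts <- seg$points
    r <- seg$radius
    pad <- r + edge_softness + max(spacing)
    for (s in seq_len(nrow(pts) - 1)) {
      p <- pts[s, ]; q <- pts[s + 1, ]
      lo <- pmin(p, q) - pad; hi <- pmax(p, q) + pad
      ir <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
      if (any(vapply(ir, length, integer(1)) == 0)) next
      g <- expand.grid(x = ax[[1]][ir[[1]]], y = ax[[2]][ir[[2]]],
                       z = ax[[3]][ir[[3]]])
      v <- q - p
      vv <- sum(v^2)
      w <- cbind(g$x - p[1], g$y - p[2], g$z - p[3])
      t_ <- if (vv > 0) pmin(1, pmax(0, (w %*% v) / vv)) else 0
      dist <- sqrt((w[, 1] - t_ * v[1])^2 + (w[, 2] - t_ * v[2])^2 +
                   (w[, 3] - t_ * v[3])^2)
      sub <- margin[ir[[1]], ir[[2]], ir[[3]]]
      margin[ir[[1]], ir[[2]], ir[[3]]] <-
        pmin(sub, array(dist - r, dim = dim(sub)))
    }
  }

  vessel_mask <- margin <= 0
  s_edge <- if (edge_softness > 0)
    pmin(1, pmax(0, 0.5 - margin / edge_softness))
  else as.numeric(vessel_mask)
  img <- background_intensity +
    (vessel_intensity - background_intensity) * array(s_edge, dim = dims)

  bias_field <- array(1, dim = dims)
  with_local_seed(seed, {
    if (bias_amplitude > 0) {
      wn <- array(rnorm(prod(dims)), dim = dims)
      sm <- gauss_smooth_3d(wn, bias_smoothness, spacing)
      rg <- range(sm)
      bias_field <- 1 - bias_amplitude +
        2 * bias_amplitude * (sm - rg[1]) / (rg[2] - rg[1])
      img <- img * bias_field
    }
    if (noise_sigma > 0) {
      n <- prod(dims)
      img <- if (noise_type == "rician")
        sqrt((img + array(rnorm(n, 0, noise_sigma), dim = dims))^2 +
             array(rnorm(n, 0, noise_sigma), dim = dims)^2)
      else img + array(rnorm(n, 0, noise_sigma), dim = dims)
    }
  })

  truth <- structure(list(vessel_mask = vessel_mask,
                          centerline = tree$segments,
                          bias_field = bias_field,
                          spec = tree$spec,
                          spacing = spacing,
                          noise_sigma = noise_sigma,
                          bias_amplitude = bias_amplitude,
                          render_seed = as.integer(seed)),
                     class = "phantom_truth")
  list(volume = scalar_volume(img, spacing = spacing), truth = truth)
}

#' Generate subcortical-like region label masks
#'
#' Four pairwise-disjoint ellipsoidal regions emulating the LSA supply
#' territories: putamen (1), globus pallidus (2), caudate (3), internal
#' capsule (4). The putamen is centred on the path of a default vessel tree
#' so that a standard phantom crosses it predominantly. Disjointness is
#' enforced by assignment priority (putamen first).
#'
#' @param dims grid dimensions (each >= 24).
#' @param spacing voxel spacing, mm.
#' @param layout_seed seed for small jitter of region centres.
#' @return a [region_mask()] with the four-region legend.
#' @export
generate_region_masks <- function(dims = c(96, 96, 96),
                                  spacing = c(0.4, 0.4, 0.4),
                                  layout_seed = 1L) {
  dims <- as.integer(dims)
  if (any(dims < 24))
    stop("grid too small for the subcortical layout; need >= 24 voxels per axis")
  ext <- dims * spacing
  # centres and semi-axes as fractions of the grid extent
  layout <- list(
    putamen          = list(c = c(0.50, 0.50, 0.45), s = c(0.26, 0.22, 0.30)),
    globus_pallidus  = list(c = c(0.22, 0.36, 0.45), s = c(0.11, 0.11, 0.16)),
    caudate          = list(c = c(0.78, 0.62, 0.62), s = c(0.11, 0.11, 0.16)),
    internal_capsule = list(c = c(0.50, 0.82, 0.50), s = c(0.30, 0.09, 0.28)))
  jitter <- with_local_seed(layout_seed,
                            matrix(runif(12, -0.02, 0.02), 4, 3))
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  labels <- array(0L, dim = dims)
  for (i in seq_along(layout)) {
    ctr <- (layout[[i]]$c + jitter[i, ]) * ext
    sa <- layout[[i]]$s * ext
    u2 <- outer(outer((ax[[1]] - ctr[1])^2 / sa[1]^2,
                      (ax[[2]] - ctr[2])^2 / sa[2]^2, `+`),
                (ax[[3]] - ctr[3])^2 / sa[3]^2, `+`)
    inside <- u2 <= 1 & labels == 0L
    labels[inside] <- i
  }
  legend <- c(putamen = 1L, globus_pallidus = 2L, caudate = 3L,
              internal_capsule = 4L)
  if (any(vapply(legend, function(l) sum(labels == l), integer(1)) == 0))
    stop("grid too small: a region ended up empty")
  region_mask(labels, legend, spacing = spacing)
}

#' Generate a complete synthetic LSA phantom case
#'
#' Couples a rendered angiogram with its region masks, a parent-artery
#' rooting region (label 5, a sphere at each trunk origin), and full ground
#' truth including per-region true vascular volumes.
#'
#' @param seed master seed; sub-seeds for tree, layout and rendering derive
#'   from it.
#' @param dims,spacing grid geometry.
#' @param n_generations,n_trunks,root_radius tree parameters, see
#'   [vessel_tree_spec()].
#' @param noise_sigma,bias_amplitude image degradation levels (defaults
#'   emulate 7T TOF-MRA: moderate Rician noise, 20% bias).
#' @param ... further arguments passed to [render_angiogram()].
#' @return object of class `lsa_phantom`: `volume`, `regions` (with
#'   parent_artery label), `tree`, `truth` (including
#'   `per_region_true_volume` in mm^3).
#' @export
lsa_phantom <- function(seed = 1L, dims = c(96, 96, 96),
                        spacing = c(0.4, 0.4, 0.4),
                        n_generations = 2L, n_trunks = 1L,
                        root_radius = 0.4,
                        noise_sigma = 15, bias_amplitude = 0.2, ...) {
  seed <- as.integer(seed)
  ext <- dims * spacing
  spec <- vessel_tree_spec(root_position = c(0.5, 0.5, 0.10) * ext,
                           root_radius = root_radius,
                           n_generations = n_generations,
                           n_trunks = n_trunks,
                           seed = seed)
  bounds <- rbind(c(0, 0, 0), ext - spacing)
  tree <- generate_vessel_tree(spec, bounds = bounds)
  rendered <- render_angiogram(tree, dims = dims, spacing = spacing,
                               noise_sigma = noise_sigma,
                               bias_amplitude = bias_amplitude,
                               seed = seed + 1L, ...)
  regions <- generate_region_masks(dims, spacing, layout_seed = seed + 2L)

  # parent-artery rooting region: sphere at each trunk origin
  labels <- regions$labels
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  for (seg in rendered$truth$centerline) {
    if (!is.na(seg$parent)) next
    ctr <- seg$points[1, ]
    rr <- max(2 * seg$radius, 1.6)
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                (ax[[3]] - ctr[3])^2, `+`)
    labels[d2 <= rr^2 & labels == 0L] <- 5L
  }
  regions <- region_mask(labels, c(regions$legend, parent_artery = 5L),
                         spacing = spacing)

  truth <- rendered$truth
  vv <- voxel_volume(spacing)
  subcortical <- c("putamen", "globus_pallidus", "caudate", "internal_capsule")
  truth$per_region_true_volume <- vapply(subcortical, function(nm)
    sum(truth$vessel_mask & regions$labels == regions$legend[[nm]]) * vv,
    numeric(1))
  structure(list(volume = rendered$volume, regions = regions, tree = tree,
                 truth = truth, seed = seed,
                 subcortical_regions = subcortical),
            class = "lsa_phantom")
}

#' Export a phantom case to disk
#'
#' Writes the angiogram, truth mask and region mask as NIfTI plus a JSON
#' truth record (centerline polylines, true volumes, parameters, seed).
#'
#' @param phantom an [lsa_phantom()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(phantom, dir) {
  stopifnot(inherits(phantom, "lsa_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, "angiogram.nii.gz"))
  sp <- phantom$volume$spacing
  write_volume(scalar_volume(array(as.numeric(phantom$truth$vessel_mask),
                                   dim = dim(phantom$truth$vessel_mask)),
                             spacing = sp),
               file.path(dir, "truth_mask.nii.gz"))
  write_region_mask(phantom$regions, file.path(dir, "regions.nii.gz"),
                    file.path(dir, "legend.yaml"))
  rec <- list(seed = phantom$seed,
              spec = unclass(phantom$tree$spec),
              noise_sigma = phantom$truth$noise_sigma,
              bias_amplitude = phantom$truth$bias_amplitude,
              per_region_true_volume =
                as.list(phantom$truth$per_region_true_volume),
              centerline = lapply(phantom$truth$centerline, function(s)
                list(id = s$id, parent = s$parent, radius = s$radius,
                     points = unname(s$points))))
  jsonlite::write_json(rec, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
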
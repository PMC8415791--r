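test_that("a straight tube reduces to two nodes and one edge of known length", {
  sp <- c(0.4, 0.4, 0.4)
  mask <- tube_mask(c(32, 32, 32), axis = 3, radius_vox = 1.3,
                    span = c(6, 25))                     # 20 slices
  parent <- array(FALSE, dim(mask)); parent[, , 1:7] <- TRUE
  g <- skeletonize_to_graph(mask, sp, parent_mask = parent)
  expect_identical(nrow(g$nodes), 2L)
  expect_identical(nrow(g$edges), 1L)
  expect_lt(abs(g$edges$length_mm - 20 * 0.4) / (20 * 0.4), 0.10)
  expect_identical(unname(count_stems_branches(g)), c(1L, 1L))
})

test_that("a Y-shaped vessel yields one junction, three endpoints, (1,2)", {
  case <- clean_tree_case(seed = 5, n_generations = 1L,
                          dims = c(64, 64, 64), root_radius = 0.7,
                          branching_angle_range = c(35, 50))
  g <- skeletonize_to_graph(case$truth$vessel_mask, case$spacing,
                            parent_mask = case$parent)
  deg <- g$nodes$degree[g$nodes$degree > 0]
  expect_identical(sort(deg), c(1L, 1L, 1L, 3L))
  expect_identical(sum(g$nodes$degree > 0), 4L)
  expect_identical(nrow(g$edges), 3L)
  expect_identical(unname(count_stems_branches(g)), c(1L, 2L))
})

test_that("skeleton endpoints match the leaf tips of the generating tree", {
  case <- clean_tree_case(seed = 3, n_generations = 2L)
  g <- skeletonize_to_graph(case$truth$vessel_mask, case$spacing,
                            parent_mask = case$parent)
  leaves <- sum(g$nodes$degree == 1 & !g$nodes$is_root)
  expect_identical(leaves, lsavol:::n_leaf_segments(case$tree))
})

test_that("three independent bifurcating trunks give (3, 6)", {
  case <- clean_tree_case(seed = 2, n_generations = 1L, n_trunks = 3L,
                          dims = c(96, 96, 72), root_radius = 0.7,
                          branching_angle_range = c(35, 50))
  g <- skeletonize_to_graph(case$truth$vessel_mask, case$spacing,
                            parent_mask = case$parent)
  expect_identical(unname(count_stems_branches(g)), c(3L, 6L))
})

test_that("the skeleton is a subset of the mask and preserves components", {
  for (seed in c(1, 9)) {
    case <- clean_tree_case(seed = seed, dims = c(64, 64, 64))
    mask <- case$truth$vessel_mask
    skel <- array(lsavol:::.cpp_thin(as.logical(mask), dim(mask)), dim(mask))
    expect_true(all(mask[skel]))
    lab_m <- lsavol:::.cpp_label_components(mask, dim(mask), 26L)
    lab_s <- lsavol:::.cpp_label_components(skel, dim(mask), 26L)
    expect_identical(attr(lab_s, "n_components"), attr(lab_m, "n_components"))
  }
})

test_that("rooting fails informatively when the parent is out of reach", {
  mask <- tube_mask(c(32, 32, 32), radius_vox = 1.2, span = c(20, 30))
  parent <- array(FALSE, dim(mask)); parent[1:3, 1:3, 1:3] <- TRUE
  expect_error(skeletonize_to_graph(mask, rep(0.4, 3), parent_mask = parent),
               "rooting")
  g <- skeletonize_to_graph(mask, rep(0.4, 3))   # unrooted is allowed
  expect_error(count_stems_branches(g), "root")
  expect_error(longest_vessel_length(g), "root")
})

test_that("maximal length is the root-to-tip geodesic in cm", {
  sp <- c(0.4, 0.4, 0.4)
  # straight 30 mm trunk: 75 slices + tube caps
  mask <- tube_mask(c(24, 24, 90), axis = 3, radius_vox = 1.3,
                    span = c(6, 81))
  parent <- array(FALSE, dim(mask)); parent[, , 1:7] <- TRUE
  g <- skeletonize_to_graph(mask, sp, parent_mask = parent)
  expect_lt(abs(longest_vessel_length(g) - 3.0), 0.15)

  # asymmetric Y: an oblique side branch extends past the trunk tip, so the
  # maximum geodesic must pick the branch
  maskY <- tube_mask(c(48, 40, 80), axis = 3, radius_vox = 1.3, span = c(6, 56))
  for (s in 0:20) {
    maskY[20 + s, 20, 46 + s] <- TRUE
    maskY[21 + s, 20, 46 + s] <- TRUE
    maskY[20 + s, 21, 46 + s] <- TRUE
  }
  parentY <- array(FALSE, dim(maskY)); parentY[, , 1:7] <- TRUE
  gY <- skeletonize_to_graph(maskY, sp, parent_mask = parentY)
  trunk_cm <- (56 - 6) * 0.4 / 10
  branch_cm <- ((46 - 6) * 0.4 + 20 * 0.4 * sqrt(2)) / 10
  got <- longest_vessel_length(gY)
  expect_gt(got, trunk_cm)
  expect_lt(abs(got - branch_cm) / branch_cm, 0.15)
})

test_that("a curved trunk's centerline length matches the generating polyline", {
  sp <- c(0.4, 0.4, 0.4)
  ext <- c(96, 96, 96) * sp
  spec <- vessel_tree_spec(root_position = c(0.45, 0.5, 0.06) * ext,
                           root_radius = 0.7, n_generations = 0L,
                           length_range = c(34.4, 34.4), curvature = 4,
                           seed = 31)
  tree <- suppressWarnings(
    generate_vessel_tree(spec, bounds = rbind(c(0, 0, 0), ext - sp)))
  pts <- tree$segments[[1]]$points
  arc_mm <- sum(sqrt(rowSums(diff(pts)^2)))            # analytic oracle
  rend <- render_angiogram(tree, dims = c(96, 96, 96), spacing = sp,
                           noise_sigma = 0, bias_amplitude = 0)
  parent <- array(FALSE, c(96, 96, 96))
  ax <- lapply(1:3, function(a) (seq_len(96) - 1) * sp[a])
  ctr <- pts[1, ]
  d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
              (ax[[3]] - ctr[3])^2, `+`)
  parent[d2 <= 1.6^2] <- TRUE
  g <- skeletonize_to_graph(rend$truth$vessel_mask, sp, parent_mask = parent)
  got_cm <- longest_vessel_length(g)
  expect_lt(abs(got_cm - arc_mm / 10) / (arc_mm / 10), 0.10)
})

test_that("counts are invariant to node relabelling and edge order", {
  case <- clean_tree_case(seed = 6, n_generations = 2L, dims = c(64, 64, 64))
  g <- skeletonize_to_graph(case$truth$vessel_mask, case$spacing,
                            parent_mask = case$parent)
  set.seed(1)
  perm <- sample(nrow(g$nodes))
  g2 <- g
  g2$nodes <- g$nodes[perm, ]
  g2$edges <- g$edges[sample(nrow(g$edges)), ]
  expect_identical(count_stems_branches(g2), count_stems_branches(g))
  expect_equal(longest_vessel_length(g2), longest_vessel_length(g))
})

test_that("MIP slabs reduce to single slices and global maxima correctly", {
  set.seed(8)
  dims <- c(20, 24, 28)
  vol <- scalar_volume(array(rnorm(prod(dims)), dim = dims),
                       spacing = c(0.5, 0.5, 0.5))
  # one-slice slab in the coronal (y) direction: world 5.0 mm = index 11
  one <- project_mip(vol, "coronal", slab_thickness = 0.4,
                     slab_center = 10 * 0.5)
  expect_equal(as.numeric(one), as.numeric(vol$data[, 11, ]))

  # whole-axis slab equals the global per-line maximum (brute-force oracle)
  full <- project_mip(vol, "coronal", slab_thickness = 1000)
  oracle <- matrix(0, dims[1], dims[3])
  for (i in seq_len(dims[1])) for (k in seq_len(dims[3]))
    oracle[i, k] <- max(vol$data[i, , k])
  expect_equal(as.numeric(full), as.numeric(oracle))

  ax <- project_mip(vol, "axial", slab_thickness = 1000)
  expect_equal(dim(ax), dims[1:2])

  expect_error(project_mip(vol, "coronal", slab_thickness = 1,
                           slab_center = 100), "does not intersect")
})

test_that("default MIP is the 28 mm coronal slab", {
  dims <- c(16, 120, 16)
  vol <- scalar_volume(array(runif(prod(dims)), dim = dims),
                       spacing = c(0.4, 0.4, 0.4))
  m <- project_mip(vol)
  expect_identical(attr(m, "axis"), "coronal")
  got <- diff(attr(m, "slab_range"))
  expect_lte(got, 28)
  expect_gte(got, 28 - 2 * 0.4)
})
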
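test_that("binary branching recursion yields the forced segment counts", {
  s0 <- vessel_tree_spec(n_generations = 0L, seed = 3)
  expect_length(generate_vessel_tree(s0)$segments, 1L)

  s2 <- vessel_tree_spec(n_generations = 2L, seed = 3)
  t2 <- generate_vessel_tree(s2)
  expect_length(t2$segments, 7L)                 # 2^(g+1) - 1
  expect_identical(lsavol:::n_leaf_segments(t2), 4L)
})

test_that("tree generation is deterministic in the seed and bounded growth warns", {
  s <- vessel_tree_spec(n_generations = 2L, seed = 11)
  a <- generate_vessel_tree(s)
  b <- generate_vessel_tree(s)
  expect_identical(lapply(a$segments, `[[`, "points"),
                   lapply(b$segments, `[[`, "points"))
  c_ <- generate_vessel_tree(vessel_tree_spec(n_generations = 2L, seed = 12))
  expect_false(identical(a$segments[[1]]$points, c_$segments[[1]]$points))

  tight <- rbind(c(0, 0, 0), c(10, 10, 6))
  expect_warning(generate_vessel_tree(s, bounds = tight), "truncated")
})

test_that("rendered cylinder mask volume approximates the analytic volume", {
  # axis off voxel centers and tilted so voxelization error averages out
  spec <- vessel_tree_spec(root_position = c(12.93, 12.71, 3.1),
                           root_direction = c(0.06, -0.04, 1),
                           root_radius = 0.6, n_generations = 0L,
                           length_range = c(20, 20), curvature = 0, seed = 1)
  ph <- render_angiogram(generate_vessel_tree(spec), dims = c(64, 64, 64),
                         spacing = c(0.4, 0.4, 0.4),
                         noise_sigma = 0, bias_amplitude = 0)
  vol <- sum(ph$truth$vessel_mask) * 0.4^3
  expect_lt(abs(vol - pi * 0.6^2 * 20) / (pi * 0.6^2 * 20), 0.10)
})

test_that("noise-free zero-background intensities stay near the true tube", {
  spec <- vessel_tree_spec(root_position = c(6.5, 6.4, 2), root_radius = 0.6,
                           n_generations = 0L, length_range = c(8, 8),
                           curvature = 0, seed = 2)
  ph <- render_angiogram(generate_vessel_tree(spec), dims = c(32, 32, 32),
                         spacing = c(0.4, 0.4, 0.4), background_intensity = 0,
                         noise_sigma = 0, bias_amplitude = 0,
                         edge_softness = 0.4)
  nz <- ph$volume$data > 0
  # every nonzero voxel lies within edge-softness of the true mask
  d_out <- array(sqrt(lsavol:::.cpp_edt_sq(!ph$truth$vessel_mask,
                                           dim(nz), rep(0.4, 3))), dim(nz))
  expect_lte(max(d_out[nz]), 0.4 + 1e-9)
})

test_that("multiplicative bias keeps lateral intensity means within forced bounds", {
  spec <- vessel_tree_spec(root_position = c(12.8, 12.8, 3), root_radius = 0.6,
                           n_generations = 1L, seed = 5)
  ph <- render_angiogram(generate_vessel_tree(spec), dims = c(48, 48, 48),
                         spacing = c(0.4, 0.4, 0.4), noise_sigma = 0,
                         bias_amplitude = 0.3, seed = 5)
  m <- ph$truth$vessel_mask
  half <- seq_len(24)
  left <- mean(ph$volume$data[half, , ][m[half, , ]])
  right <- mean(ph$volume$data[-half, , ][m[-half, , ]])
  expect_gte(left / right, 0.7 / 1.3)
  expect_lte(left / right, 1.3 / 0.7)
  expect_true(all(ph$truth$bias_field >= 0.7 - 1e-9 &
                  ph$truth$bias_field <= 1.3 + 1e-9))
})

test_that("sub-voxel tube radii are rendered with a warning", {
  spec <- vessel_tree_spec(root_position = c(6.4, 6.4, 2), root_radius = 0.1,
                           n_generations = 0L, length_range = c(6, 6),
                           curvature = 0, seed = 1)
  expect_warning(render_angiogram(generate_vessel_tree(spec),
                                  dims = c(32, 32, 32),
                                  spacing = c(0.4, 0.4, 0.4)),
                 "sub-voxel")
})

test_that("region masks are disjoint, complete and deterministic", {
  m1 <- generate_region_masks(c(48, 48, 48), c(0.4, 0.4, 0.4), layout_seed = 9)
  m2 <- generate_region_masks(c(48, 48, 48), c(0.4, 0.4, 0.4), layout_seed = 9)
  expect_identical(m1$labels, m2$labels)
  expect_setequal(names(m1$legend),
                  c("putamen", "globus_pallidus", "caudate",
                    "internal_capsule"))
  counts <- vapply(m1$legend, function(l) sum(m1$labels == l), integer(1))
  expect_true(all(counts > 0))
  # one label per voxel makes overlap impossible; totals must be consistent
  expect_identical(sum(counts), sum(m1$labels > 0))
  expect_error(generate_region_masks(c(10, 10, 10)), "too small")
})

test_that("phantom truth volumes are additive over regions and runs are seeded", {
  ph <- suppressWarnings(lsa_phantom(seed = 4, dims = c(48, 48, 48)))
  vv <- voxel_volume(ph$volume)
  union <- ph$regions$labels %in% 1:4
  expect_equal(sum(ph$truth$per_region_true_volume),
               sum(ph$truth$vessel_mask & union) * vv)
  ph2 <- suppressWarnings(lsa_phantom(seed = 4, dims = c(48, 48, 48)))
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$truth$vessel_mask, ph2$truth$vessel_mask)
})

test_that("vessel-to-background contrast rises with vessel intensity", {
  spec <- vessel_tree_spec(root_position = c(9.6, 9.6, 2.5), root_radius = 0.6,
                           n_generations = 0L, length_range = c(10, 10),
                           curvature = 0, seed = 6)
  tree <- generate_vessel_tree(spec)
  con <- vapply(c(200, 300, 450), function(vi) {
    r <- render_angiogram(tree, dims = c(40, 40, 40),
                          spacing = c(0.4, 0.4, 0.4), vessel_intensity = vi,
                          noise_sigma = 10, seed = 3)
    mean(r$volume$data[r$truth$vessel_mask]) /
      mean(r$volume$data[!r$truth$vessel_mask])
  }, numeric(1))
  expect_true(all(diff(con) > 0))
})

test_that("phantom cases export to NIfTI + JSON and read back consistently", {
  ph <- suppressWarnings(lsa_phantom(seed = 8, dims = c(32, 32, 32),
                                     noise_sigma = 5, bias_amplitude = 0.1))
  dir <- withr::local_tempdir()
  write_phantom_case(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("angiogram.nii.gz", "truth_mask.nii.gz", "regions.nii.gz",
      "legend.yaml", "truth.json")))))
  back <- read_volume(file.path(dir, "angiogram.nii.gz"))
  expect_equal(back$data, ph$volume$data, tolerance = 1e-6)
  rec <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)
  expect_equal(rec$seed, 8)
  expect_equal(sum(unlist(rec$per_region_true_volume)),
               sum(ph$truth$per_region_true_volume))
})
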
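test_that("selected threshold falls in the intensity gap of a bimodal ROI", {
  for (seed in 1:3) {
    case <- bimodal_case(seed)
    sel <- select_threshold(case$enhanced, case$roi)
    gap_lo <- max(case$enhanced$data[!case$vessel])
    gap_hi <- min(case$enhanced$data[case$vessel])
    expect_gt(sel$selected_threshold, gap_lo)
    expect_lte(sel$selected_threshold, gap_hi)
    # every threshold in the gap yields the identical (true) vessel set
    in_gap <- sel$candidates > gap_lo & sel$candidates <= gap_hi
    for (t_ in sel$candidates[in_gap])
      expect_identical(unname(case$enhanced$data >= t_), unname(case$vessel))
  }
})

test_that("threshold sweep curves behave as superlevel-set theory forces", {
  for (seed in 4:6) {
    case <- bimodal_case(seed)
    sel <- select_threshold(case$enhanced, case$roi)
    expect_true(all(diff(sel$volume_curve) >= 0))  # candidates descend
    expect_true(all(sel$ratio_change_curve >= 0))
    expect_true(sel$selected_threshold %in% sel$candidates)
  }
})

test_that("unreachable stopping bound and degenerate ROI raise errors", {
  case <- bimodal_case(1)
  expect_error(select_threshold(case$enhanced, case$roi, delta_star = 100),
               "decrease")
  flat <- scalar_volume(array(1, dim = dim(case$enhanced$data)),
                        spacing = case$enhanced$spacing)
  expect_error(select_threshold(flat, case$roi), "constant")
})

test_that("selection is invariant under affine intensity rescaling", {
  case <- bimodal_case(2)
  sel1 <- select_threshold(case$enhanced, case$roi)
  resc <- scalar_volume(3 * case$enhanced$data + 2,
                        spacing = case$enhanced$spacing)
  sel2 <- select_threshold(resc, case$roi)
  expect_identical(sel1$selected_step_index, sel2$selected_step_index)
  expect_identical(case$enhanced$data >= sel1$selected_threshold,
                   resc$data >= sel2$selected_threshold)
})

test_that("extraction keeps the true vessel set on a bimodal phantom", {
  case <- bimodal_case(3)
  sel <- select_threshold(case$enhanced, case$roi)
  m <- extract_vessels(case$enhanced, sel, case$roi)
  expect_gte(dice(m, case$vessel), 0.9)
})

test_that("seeded extraction removes isolated specks but keeps the tree", {
  dims <- c(24, 24, 24)
  vessel <- tube_mask(dims, radius_vox = 1.4)
  vals <- array(0, dim = dims)
  vals[vessel] <- 0.9
  specks <- rbind(c(3, 3, 3), c(21, 3, 20), c(3, 21, 12), c(21, 21, 4),
                  c(2, 12, 21))
  for (r in seq_len(nrow(specks)))
    vals[specks[r, 1], specks[r, 2], specks[r, 3]] <- 0.95
  vol <- scalar_volume(vals, spacing = c(0.4, 0.4, 0.4))
  seed_voxel <- which(vessel, arr.ind = TRUE)[10, ]
  m <- extract_vessels(vol, 0.5, seed_voxel = seed_voxel)

  # oracle: independent component labelling says the kept set is exactly the
  # component containing the seed
  lab <- label_components_oracle(vals >= 0.5)
  expect_identical(unname(m),
                   unname(lab == lab[seed_voxel[1], seed_voxel[2],
                                     seed_voxel[3]]))
  expect_identical(sum(m), sum(vessel))
})

test_that("seed handling warns off-threshold and errors when hopeless", {
  dims <- c(16, 16, 16)
  vals <- array(0, dim = dims); vals[8, 8, 4:12] <- 1
  vol <- scalar_volume(vals)
  expect_warning(m <- extract_vessels(vol, 0.5, seed_voxel = c(9, 9, 8)),
                 "nearest")
  expect_identical(sum(m), 9L)
  expect_error(suppressWarnings(
    extract_vessels(vol, 0.5, seed_voxel = c(16, 16, 16))), "within 5 voxels")
  expect_error(extract_vessels(vol, 0.5, seed_voxel = c(20, 1, 1)), "outside")
})

test_that("threshold above the global maximum yields an empty mask", {
  case <- bimodal_case(1)
  m <- extract_vessels(case$enhanced, 2, case$roi)
  expect_identical(sum(m), 0L)
})

test_that("volumes are exact count-times-voxel-volume arithmetic", {
  dims <- c(20, 20, 20)
  mask <- array(FALSE, dims); mask[1:10, 1:10, 1:10] <- TRUE  # 1000 voxels
  roi <- region_mask(array(1L, dims), c(all = 1L), spacing = c(1, 1, 1))
  rep <- quantify_region_volumes(mask, roi)
  expect_identical(rep$total_voxel_count, 1000L)
  expect_equal(rep$total_volume_mm3, 1000)
  expect_equal(rep$per_region$fraction, 1)

  empty <- quantify_region_volumes(array(FALSE, dims), roi)
  expect_identical(empty$total_voxel_count, 0L)
  expect_true(all(empty$per_region$volume_mm3 == 0))
  expect_true(all(is.na(empty$per_region$fraction)))
  expect_false(empty$fractions_defined)

  expect_error(quantify_region_volumes(mask, roi, spacing = c(2, 1, 1)),
               "spacing mismatch")
})

test_that("per-region volumes are additive over a partition", {
  ph <- suppressWarnings(lsa_phantom(seed = 13, dims = c(48, 48, 48),
                                     noise_sigma = 0, bias_amplitude = 0))
  subc <- ph$subcortical_regions
  rep <- quantify_region_volumes(ph$truth$vessel_mask, ph$regions, subc)
  expect_equal(sum(rep$per_region$volume_mm3), rep$total_volume_mm3)
  expect_equal(sum(rep$per_region$voxels), rep$total_voxel_count)
  if (rep$fractions_defined)
    expect_equal(sum(rep$per_region$fraction), 1)
  expect_equal(rep$per_region$volume_mm3,
               unname(ph$truth$per_region_true_volume[subc]))
})

test_that("large-vessel QC flags oversized tubes via the distance transform", {
  sp <- c(0.4, 0.4, 0.4)
  ok <- tube_mask(c(32, 32, 32), radius_vox = 2.2)      # d ~ 4.4 voxels
  qc <- flag_large_vessels(ok, sp, d_max = 5)
  expect_true(qc$pass)

  big <- tube_mask(c(40, 40, 40), radius_vox = 6)       # d = 12 voxels
  qc2 <- flag_large_vessels(big, sp, d_max = 5)
  expect_false(qc2$pass)
  expect_identical(sum(qc2$components$flagged), 1L)

  # oracle: brute-force inscribed radius of the flagged component
  idx <- which(big, arr.ind = TRUE)
  bg <- which(!big, arr.ind = TRUE)
  sub <- idx[sample.int(nrow(idx), 40), , drop = FALSE]
  brute <- max(apply(sub, 1, function(p)
    sqrt(min(colSums(((t(bg) - p) * sp)^2)))))
  expect_gte(max(qc2$components$max_radius_mm) + 1e-9, brute)
  expect_gt(max(qc2$components$max_radius_mm), qc2$radius_limit_mm)

  empty <- flag_large_vessels(array(FALSE, c(8, 8, 8)), sp)
  expect_true(empty$pass)
})
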
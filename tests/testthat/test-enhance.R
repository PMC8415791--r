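p_small <- vesselness_params(d_min = 1, d_max = 3, n_scales = 3)

test_that("vesselness of a constant image is identically zero", {
  vol <- scalar_volume(array(150, dim = c(24, 24, 24)),
                       spacing = c(0.4, 0.4, 0.4))
  v <- vesselness(vol, p_small)
  expect_true(all(v$data == 0))
})

test_that("grids smaller than the kernel support are rejected", {
  vol <- scalar_volume(array(rnorm(10^3), dim = c(10, 10, 10)))
  expect_error(vesselness(vol, vesselness_params(d_max = 8)), "kernel support")
})

test_that("a bright cylinder outscores an equally bright sphere", {
  cyl <- cylinder_volume(radius = 0.6)
  dims <- dim(cyl$data); sp <- cyl$spacing
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * sp[a])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  d2 <- (g$x - 8.11)^2 + (g$y - 7.93)^2 + (g$z - 8.05)^2
  sph <- scalar_volume(array(100 + 200 * (d2 <= 0.6^2), dim = dims),
                       spacing = sp)
  expect_gt(max(vesselness(cyl, p_small)$data),
            max(vesselness(sph, p_small)$data))
})

test_that("axis-aligned cylinders give equal responses on an isotropic grid", {
  vx <- vesselness(cylinder_volume(axis = 1), p_small)
  vz <- vesselness(cylinder_volume(axis = 3), p_small)
  expect_lt(abs(max(vx$data) - max(vz$data)) / max(vz$data), 0.05)
})

test_that("response is shift-invariant in intensity and monotone in contrast", {
  cyl <- cylinder_volume()
  v0 <- vesselness(cyl, p_small)
  shifted <- scalar_volume(cyl$data + 500, spacing = cyl$spacing)
  expect_equal(vesselness(shifted, p_small)$data, v0$data, tolerance = 1e-10)

  doubled <- scalar_volume(100 + 2 * (cyl$data - 100), spacing = cyl$spacing)
  v2 <- vesselness(doubled, p_small)
  expect_gte(max(v2$data), max(v0$data))
})

test_that("the multiscale maximum dominates every single-scale response", {
  cyl <- cylinder_volume()
  multi <- vesselness(cyl, p_small)
  radii <- exp(seq(log(0.5), log(1.5), length.out = 3))
  for (rv in radii) {
    single <- vesselness(cyl, vesselness_params(d_min = 2 * rv, d_max = 2 * rv,
                                                n_scales = 1))
    expect_true(all(multi$data >= single$data - 1e-12))
  }
})

test_that("vesselness output lies in [0, 1)", {
  ph <- suppressWarnings(lsa_phantom(seed = 21, dims = c(40, 40, 40),
                                     noise_sigma = 12, bias_amplitude = 0.15))
  v <- vesselness(ph$volume, p_small)
  expect_gte(min(v$data), 0)
  expect_lt(max(v$data), 1)
})

test_that("bias correction recovers a known multiplicative field", {
  ph <- suppressWarnings(lsa_phantom(seed = 2, dims = c(64, 64, 64),
                                     noise_sigma = 0, bias_amplitude = 0.3))
  cb <- correct_bias(ph$volume, field_fwhm = 40)
  truth <- ph$truth$bias_field
  expect_lt(rms(cb$field - truth), rms(1 - truth))

  # mean foreground intensity is preserved
  fg <- ph$volume$data > lsavol:::otsu_threshold(ph$volume$data) / 4
  expect_lt(abs(mean(cb$volume$data[fg]) / mean(ph$volume$data[fg]) - 1), 0.01)
})

test_that("bias correction is a near-identity on bias-free input", {
  ph <- suppressWarnings(lsa_phantom(seed = 2, dims = c(48, 48, 48),
                                     noise_sigma = 0, bias_amplitude = 0))
  cb <- correct_bias(ph$volume, field_fwhm = 40)
  expect_lt(rms(cb$volume$data - ph$volume$data) / rms(ph$volume$data), 0.02)
})

test_that("bias correction is approximately idempotent and fixes constants", {
  ph <- suppressWarnings(lsa_phantom(seed = 2, dims = c(64, 64, 64),
                                     noise_sigma = 0, bias_amplitude = 0.2))
  once <- correct_bias(ph$volume, 40)
  twice <- correct_bias(once$volume, 40)
  expect_lt(rms(twice$volume$data - once$volume$data) /
              rms(once$volume$data), 0.01)

  const <- correct_bias(scalar_volume(array(50, dim = c(16, 16, 16))), 40)
  expect_lt(diff(range(const$volume$data)), 1e-8)
})

test_that("vesselness parameter validation enforces the documented ranges", {
  expect_error(vesselness_params(d_min = 0), "d_min")
  expect_error(vesselness_params(d_min = 6, d_max = 5))
  expect_error(vesselness_params(alpha = 0))
  p <- vesselness_params()
  expect_equal(c(p$d_min, p$d_max, p$n_scales, p$alpha, p$beta, p$contrast),
               c(1, 5, 5, 0.10, 0.40, 100))
})
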
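test_that("generated phantoms satisfy the mask-triplet invariants", {
  for (seed in c(1, 17, 99)) {
    s <- generate_phantom(phantom_params(seed = seed, noise_sigma = 8,
                                         bias_field_amplitude = 0.15))
    expect_triplet_invariants(s$truth)
    expect_identical(dim(s$volume$data), dim(s$truth$whole$data))
  }
})

test_that("phantom with no fissures has tissue equal to the whole mask", {
  s <- generate_phantom(phantom_params(n_fissures = 0, noise_sigma = 0))
  expect_identical(sum(s$truth$fissures$data), 0L)
  expect_identical(s$truth$tissue$data, s$truth$whole$data)
})

test_that("phantom generation is voxel-identical for a fixed seed", {
  p <- phantom_params(seed = 5, noise_sigma = 10, bias_field_amplitude = 0.2)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$fissures$data, b$truth$fissures$data)
})

test_that("planar fissure voxel count matches an exhaustive slab-ellipsoid scan", {
  shape <- c(48, 48, 48)
  ax <- c(18, 15, 12)
  s <- generate_phantom(phantom_params(
    grid_shape = shape, ellipsoid_semi_axes = ax, n_fissures = 1,
    fissure_width = 2, warp_amplitude = 0, noise_sigma = 0,
    fissure_normals = matrix(c(1, 0, 0), 1), fissure_offsets = 0))
  # independent oracle: scan every voxel against the analytic predicates
  ctr <- (shape + 1) / 2
  count <- 0L
  for (x in 1:shape[1]) for (y in 1:shape[2]) for (z in 1:shape[3]) {
    inside <- ((x - ctr[1]) / ax[1])^2 + ((y - ctr[2]) / ax[2])^2 +
      ((z - ctr[3]) / ax[3])^2 <= 1
    slab <- abs(x - ctr[1]) < 1
    if (inside && slab) count <- count + 1L
  }
  expect_identical(sum(s$truth$fissures$data), count)
})

test_that("phantom parameter validation rejects impossible geometry", {
  expect_error(phantom_params(fissure_intensity = 200), "tissue_intensity")
  expect_error(phantom_params(ellipsoid_semi_axes = c(30, 15, 12)),
               "fit inside")
  expect_error(phantom_params(fissure_width = 0), "fissure_width")
  expect_error(phantom_params(noise_sigma = -1), "noise_sigma")
})

test_that("bias field is identity at amplitude 0 and bounded otherwise", {
  s <- generate_phantom(phantom_params(seed = 3))
  expect_identical(apply_bias_field(s$volume, 0)$data, s$volume$data)
  out <- apply_bias_field(s$volume, 0.2, seed = 11)
  ratio <- out$data / s$volume$data
  expect_true(all(ratio >= 0.8 - 1e-12 & ratio <= 1.2 + 1e-12))
  out2 <- apply_bias_field(s$volume, 0.2, seed = 11)
  expect_identical(out$data, out2$data)
  expect_error(apply_bias_field(s$volume, -0.1), "amplitude")
})

test_that("additive noise has the requested standard deviation", {
  v <- intensity_volume(array(100, dim = c(64, 64, 64)))
  expect_identical(add_noise(v, 0)$data, v$data)
  out <- add_noise(v, 5, seed = 21)
  expect_lt(abs(sd(out$data - v$data) - 5), 0.5)
  expect_identical(out$data, add_noise(v, 5, seed = 21)$data)
  expect_error(add_noise(v, -2), "sigma")
})
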
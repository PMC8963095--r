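test_that("Otsu threshold matches the exhaustive brute-force maximizer", {
  set.seed(7)
  for (i in 1:5) {
    nlev <- sample(3:64, 1)
    x <- array(sample(sort(runif(nlev, 0, 255)), 20^3, replace = TRUE,
                      prob = runif(nlev)),
               dim = c(20, 20, 20))
    v <- intensity_volume(x)
    expect_equal(otsu_threshold(v), oracle_otsu(x), tolerance = 1e-12)
  }
})

test_that("Otsu separates a well-separated bimodal volume", {
  x <- array(rep(c(10, 200), each = 500), dim = c(10, 10, 10))
  thr <- otsu_threshold(intensity_volume(x))
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  b <- binarize(intensity_volume(x), thr)
  expect_identical(b$data == 1L, x == 200)
  # symmetric swap separates the same way
  x2 <- 210 - x
  thr2 <- otsu_threshold(intensity_volume(x2))
  b2 <- binarize(intensity_volume(x2), thr2)
  expect_identical(b2$data == 1L, x2 == 200)
})

test_that("binarization is strict: voxels must exceed the threshold", {
  x <- array(runif(6^3, 0, 100), dim = c(6, 6, 6))
  v <- intensity_volume(x)
  expect_identical(sum(binarize(v, min(x) - 1)$data), length(x))
  expect_identical(sum(binarize(v, max(x))$data), 0L)
  expect_identical(binarize(v, 50)$data == 1L, x > 50)
})

test_that("mask smoothing preserves balls and shaves one-voxel spikes", {
  # digital ball of radius 10
  co <- as.matrix(expand.grid(1:32, 1:32, 1:32)) - 16.5
  ball <- array(as.integer(rowSums(co^2) <= 100), dim = c(32, 32, 32))
  sm <- smooth_mask(binary_mask(ball), iterations = 3)
  expect_gte(dice(sm, binary_mask(ball)), 0.95)
  # spiky mask: ball plus isolated one-voxel protrusions
  spiky <- ball
  spiky[16, 16, 28] <- 1L
  spiky[28, 16, 16] <- 1L
  out <- smooth_mask(binary_mask(spiky), iterations = 2)
  expect_lt(boundary_count(out$data) / max(1, sum(out$data)),
            boundary_count(spiky) / sum(spiky))
  expect_identical(out$data[16, 16, 28], 0L)
  # zero iterations is the identity; empty mask errors
  expect_identical(smooth_mask(binary_mask(spiky), iterations = 0)$data,
                   spiky)
  expect_error(smooth_mask(binary_mask(array(0L, dim = c(8, 8, 8)))),
               "empty")
})

test_that("fissure derivation keeps only dark voxels inside the cerebellum", {
  block <- array(0L, dim = c(5, 5, 5))
  block[2:4, 2:4, 2:4] <- 1L
  whole <- binary_mask(block)
  # binary image bright everywhere: no fissures
  bright_all <- binary_mask(array(1L, dim = c(5, 5, 5)))
  expect_identical(sum(derive_fissure_mask(bright_all, whole)$data), 0L)
  # center voxel dark -> it is the fissure
  bin <- block
  bin[3, 3, 3] <- 0L
  f <- derive_fissure_mask(binary_mask(bin), whole)
  expect_identical(sum(f$data), 1L)
  expect_identical(f$data[3, 3, 3], 1L)
  # bright voxels outside the whole mask never become fissures
  outside <- array(0L, dim = c(5, 5, 5))
  outside[1, 1, 1] <- 1L
  f2 <- derive_fissure_mask(binary_mask(outside), whole)
  expect_true(all(f2$data[block == 0L] == 0L))
  expect_error(derive_fissure_mask(binary_mask(array(0L, c(4, 4, 4))), whole),
               "grids")
})

test_that("tissue derivation is the set difference whole minus fissures", {
  block <- array(0L, dim = c(5, 5, 5))
  block[2:4, 2:4, 2:4] <- 1L
  whole <- binary_mask(block)
  none <- binary_mask(array(0L, dim = c(5, 5, 5)))
  expect_identical(derive_tissue_mask(whole, none)$data, block)
  expect_identical(sum(derive_tissue_mask(whole, whole)$data), 0L)
  center <- array(0L, dim = c(5, 5, 5))
  center[3, 3, 3] <- 1L
  expect_identical(sum(derive_tissue_mask(whole, binary_mask(center))$data),
                   26L)
  bad <- array(0L, dim = c(5, 5, 5))
  bad[1, 1, 1] <- 1L
  expect_error(derive_tissue_mask(whole, binary_mask(bad)), "subset")
})

test_that("label construction on noiseless phantoms recovers ground truth", {
  for (seed in c(2, 23)) {
    s <- generate_phantom(phantom_params(seed = seed))
    tri <- build_label_triplet(enhance_contrast(s$volume), s$truth$whole,
                               use_snakes = FALSE)
    expect_identical(tri$fissures$data, s$truth$fissures$data)
    expect_identical(tri$tissue$data, s$truth$tissue$data)
    expect_equal(dice(tri$fissures, s$truth$fissures), 1.0)
    expect_triplet_invariants(tri)
  }
  # no fissures -> empty fissure map
  s0 <- generate_phantom(phantom_params(n_fissures = 0))
  tri0 <- build_label_triplet(enhance_contrast(s0$volume), s0$truth$whole,
                              use_snakes = FALSE)
  expect_identical(sum(tri0$fissures$data), 0L)
})

test_that("label construction is deterministic and invariant-preserving with snakes", {
  s <- generate_phantom(phantom_params(seed = 6, noise_sigma = 8))
  e <- enhance_contrast(s$volume)
  a <- build_label_triplet(e, s$truth$whole, snake_iterations = 4)
  b <- build_label_triplet(e, s$truth$whole, snake_iterations = 4)
  expect_identical(a$fissures$data, b$fissures$data)
  expect_triplet_invariants(a)
  qc <- triplet_qc(a)
  expect_identical(qc$whole_voxels, sum(a$whole$data))
  expect_true(qc$fissure_fraction >= 0 && qc$fissure_fraction <= 1)
})
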
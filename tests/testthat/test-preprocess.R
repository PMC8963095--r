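test_that("normalization centers and scales by the population SD", {
  v <- intensity_volume(array(rep(c(0, 2), each = 32), dim = c(4, 4, 4)))
  out <- normalize_intensity(v)
  expect_setequal(unique(as.numeric(out$data)), c(-1, 1))
  # idempotent on an already-normalized volume
  again <- normalize_intensity(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
  # contract: |mean| tiny, SD within 1e-6 of 1
  r <- normalize_intensity(intensity_volume(array(rnorm(16^3, 40, 7),
                                                  dim = c(16, 16, 16))))
  n <- length(r$data)
  expect_lt(abs(mean(r$data)), 1e-6)
  expect_lt(abs(sqrt(mean((r$data - mean(r$data))^2)) - 1), 1e-6)
  expect_error(normalize_intensity(intensity_volume(array(3, dim = c(4, 4, 4)))),
               "constant")
})

test_that("range rescaling maps min/max to the target and is idempotent", {
  v <- intensity_volume(array(runif(8^3, -3, 3), dim = c(8, 8, 8)))
  out <- rescale_range(v)
  expect_equal(min(out$data), 1)
  expect_equal(max(out$data), 255)
  expect_equal(rescale_range(out)$data, out$data, tolerance = 1e-12)
  three <- rescale_range(intensity_volume(array(c(0, 1, 2, 0, 1, 2, 0, 2),
                                                dim = c(2, 2, 2))))
  expect_setequal(unique(as.numeric(three$data)), c(1, 128, 255))
  expect_error(rescale_range(intensity_volume(array(9, dim = c(4, 4, 4)))),
               "constant")
})

test_that("histogram equalization is monotone and flattens bimodal input", {
  set.seed(4)
  # monotone: rank order preserved on a two-value volume
  v <- intensity_volume(array(rep(c(10, 200), 32), dim = c(4, 4, 4)))
  out <- equalize_histogram(v)
  expect_true(all(out$data[v$data == 200] > out$data[v$data == 10][1]))
  # near-identity on an already-uniform histogram
  u <- rescale_range(intensity_volume(array(runif(32^3), dim = c(32, 32, 32))))
  eq <- equalize_histogram(u)
  expect_lt(max(abs(eq$data - u$data)), 6)  # within ~2 bins of identity
  # chi-squared distance to uniform decreases on a bimodal phantom
  ph <- rescale_range(generate_phantom(phantom_params(seed = 8,
                                                      noise_sigma = 10))$volume)
  chi2 <- function(x) {
    h <- tabulate(findInterval(as.numeric(x), seq(1, 255, length.out = 33),
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = 32)
    e <- length(x) / 32
    sum((h - e)^2 / e)
  }
  expect_lt(chi2(equalize_histogram(ph)$data), chi2(ph$data))
})

test_that("contrast enhancement composes the stages deterministically", {
  s <- generate_phantom(phantom_params(seed = 12, noise_sigma = 6))
  a <- enhance_contrast(s$volume)
  expect_gte(min(a$data), 1)
  expect_lte(max(a$data), 255)
  expect_identical(a$data, enhance_contrast(s$volume)$data)
  expect_error(enhance_contrast(intensity_volume(array(0, dim = c(4, 4, 4)))),
               "constant")
})

test_that("cropping produces the dilated, clipped bounding box", {
  m <- array(0L, dim = c(12, 12, 12))
  m[6, 6, 6] <- 1L
  v <- intensity_volume(array(rnorm(12^3), dim = c(12, 12, 12)))
  tight <- crop_to_mask(v, binary_mask(m), margin = 0)
  expect_identical(tight$box$lower, rep(5L, 3))
  expect_identical(tight$box$upper, rep(6L, 3))
  wide <- crop_to_mask(v, binary_mask(m), margin = 2)
  expect_identical(wide$box$lower, rep(3L, 3))
  expect_identical(wide$box$upper, rep(8L, 3))
  # clipped at the grid corner
  m2 <- array(0L, dim = c(12, 12, 12))
  m2[1, 1, 1] <- 1L
  corner <- crop_to_mask(v, binary_mask(m2), margin = 2)
  expect_identical(corner$box$lower, rep(0L, 3))
  expect_identical(corner$box$upper, rep(3L, 3))
  expect_error(crop_to_mask(v, binary_mask(array(0L, dim = c(12, 12, 12)))),
               "empty")
})

test_that("crop/uncrop round trip restores the original voxels in the box", {
  set.seed(9)
  s <- generate_phantom(phantom_params(seed = 31))
  cr <- crop_to_mask(s$volume, s$truth$whole, margin = 3)
  back <- uncrop(cr$volume, cr$box)
  lo <- cr$box$lower + 1
  hi <- cr$box$upper
  expect_identical(back[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
                   s$volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
})

test_that("crop padding to a multiple of 16 stays within the grid", {
  s <- generate_phantom(phantom_params(seed = 13))
  cr <- crop_to_mask(s$volume, s$truth$whole, margin = 2, pad_multiple = 16)
  side <- cr$box$upper - cr$box$lower
  expect_true(all(side %% 16 == 0))
  expect_true(all(cr$box$lower >= 0))
  expect_true(all(cr$box$upper <= dim(s$volume$data)))
  # mask voxels are all inside the box
  idx <- which(s$truth$whole$data == 1L, arr.ind = TRUE)
  expect_true(all(t(idx) - 1 >= cr$box$lower) &&
                all(t(idx) <= cr$box$upper))
})
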
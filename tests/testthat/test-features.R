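# low-contrast dark sphere on a flat slab
dark_sphere_volume <- function(level = 90, grid = c(48L, 48L, 6L)) {
  img <- array(100, dim = grid)
  sph <- rasterize_ellipsoid(c(24, 24, 3), rep(2, 3), grid, c(1, 1, 1))
  img[sph] <- level
  list(img = volume_image(img), sph = sph,
       mask = array(TRUE, dim = grid))
}

test_that("CLAHE output is bounded and enhances low contrast", {
  # a faint dark sphere on a slab whose global range is dominated by an
  # unrelated bright stripe, so global rescaling leaves the sphere faint
  grid <- c(48L, 48L, 4L)
  img <- array(100, dim = grid)
  sph <- rasterize_ellipsoid(c(24, 24, 2), rep(3, 3), grid, c(1, 1, 1))
  img[sph] <- 92
  img[, 45:48, ] <- 400
  vol <- volume_image(img)
  mask <- array(TRUE, dim = grid)
  cl <- clahe_map(vol, mask, clip = 0.01)
  expect_true(all(cl >= 0 & cl <= 1))
  # local contrast (difference of means) strictly larger after equalization
  bgsel <- !sph & img < 200
  raw01 <- (img - min(img)) / diff(range(img))
  contrast_raw <- mean(raw01[bgsel]) - mean(raw01[sph])
  contrast_cl <- mean(cl[bgsel]) - mean(cl[sph])
  expect_gt(contrast_cl, contrast_raw)

  expect_warning(z <- clahe_map(volume_image(array(4, c(16, 16, 2))),
                                array(TRUE, c(16, 16, 2))), "constant")
  expect_true(all(z == 0))
})

test_that("exponential intensity feature is a monotone closed form", {
  img <- volume_image(array(c(0, -1, 1, 2, -2, 0.5, -0.5, 0), c(2, 2, 2)))
  e <- exp_intensity(img, p = 1)
  expect_equal(e[1, 1, 1], 1)
  expect_equal(e[2, 1, 1], exp(-1), tolerance = 1e-12)
  expect_true(all(diff(e[order(img$voxels)]) >= 0))
  big <- volume_image(array(c(100, -100, 0, 0, 0, 0, 0, 0), c(2, 2, 2)))
  expect_warning(eb <- exp_intensity(big), "clipped")
  expect_true(all(is.finite(eb)))
})

test_that("FRST highlights dark discs more than bars and peaks at the center", {
  grid <- c(40L, 40L, 1L)
  mask <- array(TRUE, dim = grid)
  # constant image -> zero
  expect_true(all(frst_map(volume_image(array(1, grid)), mask) == 0))
  # dark disc of radius 3 voxels
  img <- array(100, dim = grid)
  disc <- rasterize_ellipsoid(c(20, 20, 0), c(3, 3, 0.4), grid, c(1, 1, 1))
  img[disc] <- 40
  fd <- frst_map(volume_image(img), mask, radii = c(2L, 3L, 4L))
  pk <- which(fd == max(fd), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk[1:2] - c(21, 21))), 1)
  # equally dark elongated bar responds less at its center
  img2 <- array(100, dim = grid)
  img2[10:30, 19:21, 1] <- 40
  fb <- frst_map(volume_image(img2), mask, radii = c(2L, 3L, 4L))
  expect_gt(fd[21, 21, 1], fb[20, 20, 1])
})

test_that("blobness is a zero-sum high-pass that dips at dark blobs", {
  flat <- volume_image(array(3, c(32, 32, 2)))
  expect_true(all(blobness_map(flat) == 0))
  pp <- dark_sphere_volume()
  bl <- blobness_map(pp$img, sigma = 1.5)
  expect_lt(bl[25, 25, 3], 0)
  expect_lt(abs(sum(bl[, , 1])), 1e-6 * sum(abs(bl[, , 3])) + 1e-9)
})

test_that("LoG vanishes on constants and ramps, extremal at a matched blob", {
  flat <- volume_image(array(3, c(32, 32, 2)))
  expect_lt(max(abs(log_map(flat))), 1e-12)
  ramp <- volume_image(array(rep(seq_len(32), each = 32), c(32, 32, 1)))
  lg <- log_map(ramp, sigma = 1.5)
  interior <- lg[8:25, 8:25, 1]   # away from the replicate-padded border
  expect_lt(max(abs(interior)), 1e-8)
  pp <- dark_sphere_volume(level = 40)
  lr <- pp$img
  lg2 <- log_map(lr, sigma = 1.5)
  center <- which(abs(lg2[, , 3]) == max(abs(lg2[, , 3])), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(center - c(25, 25))), 1)
})

test_that("feature stack is max-normalized, finite and deterministic", {
  ph <- generate_phantom(small_spec(n_cmbs = 3, seed = 41))
  vr <- remove_vessels(ph$image, ph$brain_mask, seed = 42)
  st <- assemble_features(vr$image, ph$brain_mask)
  expect_named(st$features, c("intensity", "exp_intensity", "clahe",
                              "frst_mean", "st_lambda1", "blobness", "log"))
  for (m in st$features) {
    expect_true(all(is.finite(m)))
    expect_true(max(abs(m)) == 1 || all(m == 0))
  }
  st2 <- assemble_features(vr$image, ph$brain_mask)
  expect_identical(st$features, st2$features)
})

test_that("normalized features are invariant to positive intensity scaling", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 8), n_cmbs = 1,
                                      seed = 43))
  a <- assemble_features(ph$image, ph$brain_mask)
  scaled <- volume_image(2.5 * ph$image$voxels, ph$image$voxel_size_mm)
  b <- assemble_features(scaled, ph$brain_mask)
  for (nm in names(a$features))
    expect_equal(a$features[[nm]], b$features[[nm]], tolerance = 1e-8,
                 label = nm)
})

test_that("training-voxel sampling respects counts, mask and seed", {
  ph <- generate_phantom(small_spec(n_cmbs = 3, seed = 44))
  stk <- assemble_features(ph$image, ph$brain_mask)
  tr <- sample_training_voxels(stk, ph$cmb_truth, neg_pos_ratio = 10,
                               seed = 7)
  n_pos <- sum(ph$cmb_truth > 0 & ph$brain_mask)
  expect_equal(nrow(tr$x), 11 * n_pos)
  expect_equal(sum(tr$y == 1), n_pos)
  expect_true(all(ph$brain_mask[tr$voxels]))
  tr2 <- sample_training_voxels(stk, ph$cmb_truth, neg_pos_ratio = 10,
                                seed = 7)
  expect_identical(tr, tr2)
  expect_error(sample_training_voxels(stk, array(0L, dim(ph$cmb_truth))),
               "positive")
})
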
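# a slab phantom with one in-plane dark tube and one dark sphere, used to
# probe the line-vs-blob behaviour of the stage-1 features
tube_sphere_phantom <- function() {
  grid <- c(48L, 48L, 8L)
  vs <- c(1, 1, 1)
  img <- array(100, dim = grid)
  tube <- rasterize_tube(rbind(c(8, 12, 4), c(40, 12, 4)), 1, grid, vs)
  sph <- rasterize_ellipsoid(c(24, 32, 4), rep(2, 3), grid, vs)
  img[tube] <- 20
  img[sph] <- 50
  list(img = volume_image(img, vs), tube = tube, sph = sph,
       mask = array(TRUE, dim = grid))
}

test_that("Frangi vesselness prefers tubes over blobs and ignores offsets", {
  pp <- tube_sphere_phantom()
  fr <- frangi_vesselness(pp$img, pp$mask)
  expect_true(all(fr >= 0))
  # tube centerline beats sphere center
  expect_gt(max(fr[pp$tube]), fr[24, 32, 4])
  # constant image -> zero response
  flat <- volume_image(array(7, c(32, 32, 4)))
  expect_true(all(frangi_vesselness(flat, array(TRUE, c(32, 32, 4))) == 0))
  # adding a constant changes nothing (second-order filter)
  shifted <- volume_image(pp$img$voxels + 250, pp$img$voxel_size_mm)
  expect_equal(frangi_vesselness(shifted, pp$mask), fr, tolerance = 1e-10)
})

test_that("frangi_params and structure tensor validate and behave", {
  expect_error(frangi_params(beta1 = 0), "beta1")
  expect_error(frangi_params(beta2 = -1), "beta2")
  flat <- volume_image(array(3, c(24, 24, 4)))
  st0 <- structure_tensor_features(flat)
  expect_lt(max(abs(st0$lambda1)), 1e-12)
  expect_lt(max(abs(st0$linearity)), 1e-12)

  # ideal straight edge: linearity high on the edge, low at a blob center
  grid <- c(40L, 40L, 2L)
  img <- array(100, dim = grid)
  img[1:20, , ] <- 40
  edge <- structure_tensor_features(volume_image(img))
  expect_gt(max(edge$linearity[19:22, , 1]), 0)
  pp <- tube_sphere_phantom()
  st <- structure_tensor_features(pp$img)
  expect_true(all(st$linearity >= 0))
  expect_lt(st$linearity[24, 32, 4], max(st$linearity[pp$tube]) / 5)
})

test_that("vessel-voxel clustering captures tubes, spares microbleeds", {
  sp <- small_spec(n_cmbs = 3, seed = 21)
  ph <- generate_phantom(sp)
  # vessel/sulci truth: dark mimic voxels that are not labeled microbleeds
  mimic_level <- sp$background_level * (1 - sp$vessel_contrast)
  vtruth <- ph$image$voxels < (mimic_level + 15) & ph$brain_mask &
    ph$cmb_truth == 0
  fr <- frangi_vesselness(ph$image, ph$brain_mask)
  st <- structure_tensor_features(ph$image)
  vm <- classify_vessel_voxels(fr, st, ph$brain_mask, seed = 42)
  expect_true(all(ph$brain_mask[vm]))
  expect_gte(sum(vm & vtruth) / sum(vtruth), 0.8)
  expect_lte(sum(vm & ph$cmb_truth > 0) / sum(ph$cmb_truth > 0), 0.2)
  # determinism
  vm2 <- classify_vessel_voxels(fr, st, ph$brain_mask, seed = 42)
  expect_identical(vm, vm2)
})

test_that("degenerate features give an empty vessel mask with a warning", {
  flat <- volume_image(array(1, c(32, 32, 8)))
  mask <- array(TRUE, c(32, 32, 8))
  fr <- frangi_vesselness(flat, mask)
  st <- structure_tensor_features(flat)
  expect_warning(vm <- classify_vessel_voxels(fr, st, mask), "degenerate")
  expect_false(any(vm))
})

test_that("inpainting follows the nearest-3 rule and never touches unmasked voxels", {
  # empty mask: identity
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 8), seed = 2))
  out <- inpaint(ph$image, array(FALSE, dim(ph$image)))
  expect_identical(out$voxels, ph$image$voxels)

  # masked voxel whose 3 nearest unmasked neighbours are 10, 20, 30 -> 20
  img <- array(50, c(5, 5, 1))
  img[2, 3, 1] <- 10; img[3, 2, 1] <- 20; img[3, 4, 1] <- 30
  vm <- array(FALSE, c(5, 5, 1))
  vm[3, 3, 1] <- TRUE
  vm[4, 3, 1] <- TRUE   # the 4th orthogonal neighbour is itself masked
  got <- inpaint(volume_image(img), vm)
  expect_equal(got$voxels[3, 3, 1], 20)
  # unmasked voxels bit-identical
  expect_identical(got$voxels[!vm], img[!vm])

  # masked voxel surrounded by constant c -> c
  img2 <- array(7, c(5, 5, 1))
  got2 <- inpaint(volume_image(img2), vm)
  expect_equal(got2$voxels[3, 3, 1], 7)

  # fully masked slice is filled from neighbouring slices, with a warning
  img3 <- volume_image(array(rep(c(1, 5, 9), each = 16), c(4, 4, 3)))
  vm3 <- array(FALSE, c(4, 4, 3)); vm3[, , 2] <- TRUE
  expect_warning(got3 <- inpaint(img3, vm3), "entirely masked")
  expect_true(all(got3$voxels[, , 2] == 5))
})

test_that("vessel removal reduces tubular response while microbleeds keep contrast", {
  sp <- small_spec(n_cmbs = 3, seed = 23)
  ph <- generate_phantom(sp)
  vr <- remove_vessels(ph$image, ph$brain_mask, seed = 42)
  fr_before <- sum(frangi_vesselness(ph$image, ph$brain_mask))
  fr_after <- sum(frangi_vesselness(vr$image, ph$brain_mask))
  expect_lt(fr_after, fr_before)
  # every microbleed keeps a clearly hypointense core
  bg <- vr$image$voxels[ph$brain_mask & ph$cmb_truth == 0 &
                          !vr$vessel_mask]
  survived <- vapply(seq_len(ph$placed_cmb_count), function(k)
    min(vr$image$voxels[ph$cmb_truth == k]) < mean(bg) - 3 * sd(bg), TRUE)
  expect_gte(mean(survived), 0.9)
})
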
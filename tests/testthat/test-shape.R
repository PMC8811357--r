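test_that("26-connectivity merges corner neighbours and splits separated voxels", {
  m <- array(FALSE, c(6, 6, 6))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE             # shares only a corner
  comps <- label_components(m)
  expect_length(comps, 1L)

  m2 <- array(FALSE, c(6, 6, 6))
  m2[2, 2, 2] <- TRUE
  m2[2, 2, 4] <- TRUE            # one background voxel between
  expect_length(label_components(m2), 2L)

  expect_length(label_components(array(FALSE, c(4, 4, 4))), 0L)
})

test_that("solidity is exactly 1 for convex lattice shapes", {
  m <- array(FALSE, c(12, 12, 8))
  m[4:9, 4:9, 3:6] <- TRUE       # filled rectangular prism
  cp <- compute_shape_attributes(label_components(m)[[1]], c(1, 1, 1))
  expect_identical(cp$solidity, 1)
  expect_equal(cp$volume_mm3, 144)
})

test_that("rasterized sphere attributes pass every criterion", {
  s <- rasterize_ellipsoid(c(8, 8, 8), rep(2, 3), c(16L, 16L, 16L), c(1, 1, 1))
  cp <- compute_shape_attributes(label_components(s)[[1]], c(1, 1, 1))
  expect_lt(abs(cp$volume_mm3 - 33.51) / 33.51, 0.15)
  expect_lt(cp$ellipticity, 0.2)
  expect_gte(cp$solidity, 0.9)
  expect_lt(abs(cp$diameter_mm - 4), 1)
  f <- filter_candidates(list(cp), shape_criteria())
  expect_true(f$report$passes)
  # larger sphere: ellipticity still near 0 on the analytic axes
  s8 <- rasterize_ellipsoid(c(10, 10, 10), rep(4, 3), c(20L, 20L, 20L),
                            c(1, 1, 1))
  cp8 <- compute_shape_attributes(label_components(s8)[[1]], c(1, 1, 1))
  expect_lte(cp8$ellipticity, 0.05)
})

test_that("elongated tubes fail by ellipticity and diameter", {
  tb <- rasterize_tube(rbind(c(5, 5, 5), c(25, 5, 5)), 1, c(30L, 12L, 10L),
                       c(1, 1, 1))
  cp <- compute_shape_attributes(label_components(tb)[[1]], c(1, 1, 1))
  expect_gte(cp$ellipticity, 0.8)
  expect_gt(cp$diameter_mm, 10)
  f <- filter_candidates(list(cp), shape_criteria())
  expect_false(f$report$passes)
})

test_that("size extremes are rejected", {
  # single anisotropic voxel: 0.8 x 0.8 x 3 mm = 1.92 mm^3 < 5
  m <- array(FALSE, c(8, 8, 4)); m[4, 4, 2] <- TRUE
  f1 <- filter_candidates(label_components(m), shape_criteria(),
                          voxel_size_mm = c(0.8, 0.8, 3))
  expect_false(f1$report$passes)
  expect_false(f1$report$pass_volume)

  # 12 mm sphere: volume and diameter both out of range
  s <- rasterize_ellipsoid(c(10, 10, 10), rep(6, 3), c(20L, 20L, 20L),
                           c(1, 1, 1))
  f2 <- filter_candidates(label_components(s), shape_criteria(),
                          voxel_size_mm = c(1, 1, 1))
  expect_false(f2$report$pass_volume)
  expect_false(f2$report$pass_diameter)
  expect_false(f2$report$passes)
})

test_that("boundary values follow strict/inclusive semantics", {
  mk <- function(vol, ell, sol, diam)
    list(id = 1L, voxels = matrix(c(1, 1, 1), 1), n_vox = 1L,
         centroid_mm = c(0, 0, 0), volume_mm3 = vol, ellipticity = ell,
         solidity = sol, diameter_mm = diam)
  crit <- shape_criteria()
  ok <- function(cp) filter_candidates(list(cp), crit)$report$passes
  base <- mk(50, 0.1, 0.9, 5)
  expect_true(ok(base))
  expect_false(ok(mk(5, 0.1, 0.9, 5)))       # volume exactly 5 rejected
  expect_false(ok(mk(120, 0.1, 0.9, 5)))     # volume exactly 120 rejected
  expect_false(ok(mk(50, 0.2, 0.9, 5)))      # ellipticity exactly 0.2 rejected
  expect_true(ok(mk(50, 0.1, 0.6, 5)))       # solidity exactly 0.6 accepted
  expect_false(ok(mk(50, 0.1, 0.59, 5)))
  expect_false(ok(mk(50, 0.1, 0.9, 2)))      # diameter exactly 2 rejected
  expect_false(ok(mk(50, 0.1, 0.9, 10)))     # diameter exactly 10 rejected
})

test_that("tightening any criterion never grows the surviving set (conjunction)", {
  set.seed(99)
  comps <- lapply(1:60, function(i)
    list(id = i, voxels = matrix(c(1, 1, 1), 1), n_vox = 1L,
         centroid_mm = c(0, 0, 0),
         volume_mm3 = runif(1, 0, 150),
         ellipticity = runif(1),
         solidity = runif(1),
         diameter_mm = runif(1, 0, 14)))
  base_crit <- shape_criteria()
  n0 <- length(filter_candidates(comps, base_crit)$surviving)
  tighter <- list(
    shape_criteria(vol_range_mm3 = c(10, 100)),
    shape_criteria(ellipticity_max = 0.1),
    shape_criteria(solidity_min = 0.8),
    shape_criteria(diameter_range_mm = c(3, 8)))
  for (cr in tighter)
    expect_lte(length(filter_candidates(comps, cr)$surviving), n0)
  # conjunction: survivors = intersection of single-criterion survivors
  rep_ <- filter_candidates(comps, base_crit)$report
  expect_equal(rep_$passes,
               rep_$pass_volume & rep_$pass_ellipticity &
                 rep_$pass_solidity & rep_$pass_diameter)
})
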
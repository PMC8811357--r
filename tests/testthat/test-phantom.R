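test_that("rasterization matches brute-force voxel-center membership", {
  grid <- c(12L, 12L, 12L)
  vs <- c(1, 1, 1)
  m <- rasterize_ellipsoid(c(5, 5, 5), rep(2, 3), grid, vs)
  expect_equal(sum(m), brute_sphere_count(c(5, 5, 5), 2, grid, vs))
  # 2 mm radius sphere at 1 mm voxels: count within 15% of 4/3 pi r^3
  expect_lt(abs(sum(m) - 33.51) / 33.51, 0.15)

  # sub-voxel ellipsoid centered on a voxel center -> exactly that voxel
  tiny <- rasterize_ellipsoid(c(5, 5, 5), rep(0.3, 3), grid, vs)
  expect_equal(sum(tiny), 1L)
  expect_true(tiny[6, 6, 6])

  # entirely outside the grid -> empty, not an error
  expect_equal(sum(rasterize_ellipsoid(c(50, 50, 50), rep(2, 3), grid, vs)), 0L)

  # tube along x: elongated component with Feret diameter >= path length
  tb <- rasterize_tube(rbind(c(3, 6, 6), c(23, 6, 6)), 1, c(28L, 12L, 12L), vs)
  comp <- compute_shape_attributes(label_components(tb)[[1]], vs)
  expect_gte(comp$diameter_mm, 20)
  # zero-length path degenerates to a sphere
  sp <- rasterize_tube(rbind(c(6, 6, 6), c(6, 6, 6)), 2, grid, vs)
  expect_equal(sum(sp), brute_sphere_count(c(6, 6, 6), 2, grid, vs))
  # path outside the grid -> empty
  expect_equal(sum(rasterize_tube(rbind(c(90, 90, 90), c(99, 99, 99)), 1,
                                  grid, vs)), 0L)
})

test_that("degenerate phantom spec gives a constant background", {
  sp <- phantom_spec(grid_shape = c(32, 32, 8), n_cmbs = 0, n_vessels = 0,
                     noise_sd = 0, sulci_density = 0, seed = 9)
  ph <- generate_phantom(sp)
  expect_false(ph$has_cmb)
  expect_equal(ph$placed_cmb_count, 0L)
  v <- ph$image$voxels[ph$brain_mask]
  expect_true(all(v == sp$background_level))
  expect_true(all(ph$image$voxels[!ph$brain_mask] == 0))
})

test_that("phantom truth labels, contrast direction and geometry", {
  sp <- small_spec(n_cmbs = 5, seed = 31)
  ph <- generate_phantom(sp)
  expect_equal(ph$placed_cmb_count, 5L)
  expect_true(ph$has_cmb)
  labs <- sort(unique(ph$cmb_truth[ph$cmb_truth > 0]))
  expect_equal(labs, 1:5)
  # truth only inside brain
  expect_true(all(ph$brain_mask[ph$cmb_truth > 0]))
  # every CMB voxel darker than background level
  expect_true(mean(ph$image$voxels[ph$cmb_truth > 0]) <
                mean(ph$image$voxels[ph$brain_mask & ph$cmb_truth == 0]))
  # per-component Feret diameter within the spec'd range +- a voxel diagonal
  diag_mm <- sqrt(sum(sp$voxel_size_mm^2))
  for (k in 1:5) {
    cp <- list(id = k, voxels = which(ph$cmb_truth == k, arr.ind = TRUE))
    cp <- compute_shape_attributes(cp, sp$voxel_size_mm)
    expect_gte(cp$diameter_mm, sp$cmb_diameter_range_mm[1] - diag_mm)
    expect_lte(cp$diameter_mm, sp$cmb_diameter_range_mm[2] + diag_mm)
  }
})

test_that("phantom generation is seed-deterministic", {
  sp <- phantom_spec(grid_shape = c(32, 32, 8), n_cmbs = 2, seed = 77)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$cmb_truth, b$cmb_truth)
  expect_identical(a$brain_mask, b$brain_mask)
})

test_that("cohort prevalence, determinism and manifest consistency", {
  sp <- phantom_spec(grid_shape = c(32, 32, 8), seed = 1)
  co <- generate_cohort(40, 0.5, sp, seed = 11)
  man <- attr(co, "manifest")
  expect_equal(sum(man$has_cmb), 20L)
  expect_equal(sum(vapply(co, `[[`, TRUE, "has_cmb")), 20L)
  expect_true(all(man$n_cmbs[man$has_cmb] >= 1))
  # per-subject consistency between manifest and generated truth
  expect_equal(man$n_cmbs, unname(vapply(co, `[[`, 1L, "placed_cmb_count")))

  co0 <- generate_cohort(6, 0, sp, seed = 3)
  expect_false(any(vapply(co0, `[[`, TRUE, "has_cmb")))

  co2 <- generate_cohort(5, 0.4, sp, seed = 11)
  co3 <- generate_cohort(5, 0.4, sp, seed = 11)
  expect_identical(lapply(co2, `[[`, "image"), lapply(co3, `[[`, "image"))
})

test_that("phantom cohort writes NIfTI volumes plus manifest and spec", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(2, 0.5, phantom_spec(grid_shape = c(32, 32, 8)),
                        seed = 4)
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  expect_true(all(file.exists(man$image_path)))
  r <- read_volume(man$image_path[1])
  expect_identical(r$voxels, co[[1]]$image$voxels)
  tr <- read_volume(man$truth_path[1])
  expect_identical(round(tr$voxels), round(co[[1]]$cmb_truth + 0))
})
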
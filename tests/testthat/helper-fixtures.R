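# Shared fixtures. Heavy objects (trained models, cohorts) are built once per
# test run and memoized here; every generator call is seeded so the fixtures
# are identical across runs.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# desk-scale phantom geometry used by most pipeline tests
small_spec <- function(...) {
  phantom_spec(grid_shape = c(64L, 64L, 16L), ...)
}

small_config <- function(seed = 5L, ...) {
  pipeline_config(th_ncmb = 1L, seed = seed, ...)
}

# 8 positive training subjects and a fitted model
small_model <- function() {
  cached("small_model", {
    train <- generate_cohort(8, 1, small_spec(), seed = 101)
    cmb_fit(train, small_config())
  })
}

small_test_cohort <- function() {
  cached("small_test_cohort", generate_cohort(10, 0.5, small_spec(), seed = 202))
}

# predictions of the small model on the small cohort
small_predictions <- function() {
  cached("small_predictions",
         run_predict(small_model(), small_test_cohort()))
}

# brute-force voxel-center rasterization oracle for spheres
brute_sphere_count <- function(center, radius, grid, vs) {
  n <- 0L
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2]))
    for (k in seq_len(grid[3])) {
      p <- c((i - 1) * vs[1], (j - 1) * vs[2], (k - 1) * vs[3])
      if (sum((p - center)^2) <= radius^2) n <- n + 1L
    }
  n
}
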
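# build a synthetic feature stack directly from a matrix of 7-vectors
stack_from_matrix <- function(x, cfg = feature_config()) {
  n <- nrow(x)
  d <- c(n, 1L, 1L)
  feats <- lapply(seq_len(ncol(x)), function(j) array(x[, j], dim = d))
  names(feats) <- c("intensity", "exp_intensity", "clahe", "frst_mean",
                    "st_lambda1", "blobness", "log")
  structure(list(features = feats, mask = array(TRUE, dim = d),
                 voxel_size_mm = c(1, 1, 1), cfg = cfg),
            class = "voxel_feature_stack")
}

test_that("voxel classifier separates separable classes and calibrates in [0,1]", {
  set.seed(13)
  n <- 300
  x <- matrix(runif(n * 7), ncol = 7,
              dimnames = list(NULL, c("intensity", "exp_intensity", "clahe",
                                      "frst_mean", "st_lambda1", "blobness",
                                      "log")))
  y <- as.integer(x[, 1] + x[, 4] > 1.2)
  x[y == 1, 1] <- x[y == 1, 1] + 2      # make the classes cleanly separable
  model <- train_voxel_classifier(list(x = x, y = y), seed = 3)
  p <- predict_probability(model, stack_from_matrix(x))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(as.integer(p[seq_len(n)] > 0.5), y)
  # deterministic given the model
  p2 <- predict_probability(model, stack_from_matrix(x))
  expect_identical(p, p2)
  # retraining with the same seed gives an identical model
  model2 <- train_voxel_classifier(list(x = x, y = y), seed = 3)
  expect_identical(predict_probability(model2, stack_from_matrix(x)), p)
  expect_error(train_voxel_classifier(list(x = x, y = rep(1L, n))), "classes")
})

test_that("probability thresholding is monotone with the stated edge cases", {
  set.seed(14)
  p <- array(runif(4 * 4 * 2), c(4, 4, 2))
  mask <- array(TRUE, c(4, 4, 2))
  expect_equal(sum(threshold_candidates(p, 1, mask)), 0L)
  expect_equal(sum(threshold_candidates(p, 0, mask)), sum(p > 0))
  counts <- vapply(seq(0, 1, 0.1), function(th)
    sum(threshold_candidates(p, th, mask)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("stack/model feature mismatch is an error", {
  set.seed(15)
  x <- matrix(runif(100 * 7), ncol = 7,
              dimnames = list(NULL, c("intensity", "exp_intensity", "clahe",
                                      "frst_mean", "st_lambda1", "blobness",
                                      "log")))
  y <- rep(0:1, 50)
  x[y == 1, 2] <- x[y == 1, 2] + 3
  model <- train_voxel_classifier(list(x = x, y = y), seed = 1)
  bad <- stack_from_matrix(x)
  names(bad$features)[3] <- "something_else"
  expect_error(predict_probability(model, bad), "match")
})

test_that("probability-threshold sweep yields monotone FROC columns", {
  model <- small_model()
  cohort <- small_test_cohort()[1:4]
  fc <- sweep_th_prob(model, cohort, grid = seq(0.1, 0.9, by = 0.2))
  pts <- fc$points[order(fc$points$threshold), ]
  expect_equal(nrow(pts), 5L)
  expect_true(all(diff(pts$tpr) <= 1e-12))
  # FP cluster counts shrink with the threshold up to component splitting,
  # which can turn one overlapping cluster into two (at most a fraction of
  # a false positive per subject on sparse candidate masks)
  expect_true(all(diff(pts$fpavg) <= 0.5))
  expect_true(all(pts$tpr >= 0 & pts$tpr <= 1, na.rm = TRUE))
})

test_that("phantom-trained model ranks microbleed voxels above background", {
  model <- small_model()
  ph <- small_test_cohort()[[4]]      # a CMB-positive subject
  expect_gt(ph$placed_cmb_count, 0)
  vr <- remove_vessels(ph$image, ph$brain_mask, seed = 42)
  stk <- assemble_features(vr$image, ph$brain_mask)
  p <- predict_probability(model, stk)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p[!ph$brain_mask] == 0))
  expect_gt(median(p[ph$cmb_truth > 0]),
            median(p[ph$brain_mask & ph$cmb_truth == 0]))
})

test_that("held-out voxel-level discrimination is near-perfect on phantoms", {
  model <- small_model()
  cohort <- small_test_cohort()
  pos_p <- c(); neg_p <- c()
  for (sub in cohort[c(4, 6)]) {
    vr <- remove_vessels(sub$image, sub$brain_mask, seed = 42)
    stk <- assemble_features(vr$image, sub$brain_mask)
    p <- predict_probability(model, stk)
    pos_p <- c(pos_p, p[sub$cmb_truth > 0])
    set.seed(1)
    bg <- which(sub$brain_mask & sub$cmb_truth == 0)
    neg_p <- c(neg_p, p[sample(bg, 2000)])
  }
  # ROC AUC by rank statistic
  r <- rank(c(pos_p, neg_p))
  auc <- (sum(r[seq_along(pos_p)]) - length(pos_p) * (length(pos_p) + 1) / 2) /
    (length(pos_p) * length(neg_p))
  expect_gte(auc, 0.95)
})
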
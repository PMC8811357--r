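#' Pipeline configuration
#'
#' Nested configuration for the full preselection pipeline. Every random
#' operation (clustering restarts, voxel sampling, calibration split) derives
#' its seed from the single `seed` here, making end-to-end runs bit
#' reproducible. Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param modality `"SWI"` or `"GRE"` (sets the subject-threshold default).
#' @param vessel_removal list: `beta1`, `beta2`, `scales_vox`, `sigma_grad`,
#'   `sigma_window`, and `on` (`"raw"` or `"standardized"`), the image the
#'   stage-1 features are computed on.
#' @param features a [feature_config].
#' @param shape a [shape_criteria].
#' @param th_ncmb subject count threshold (NULL = modality default).
#' @param neg_pos_ratio negatives sampled per positive training voxel.
#' @param max_train_rows stratified cap on total training rows.
#' @param clahe_on `"vessel_removed"` (default) or `"original"` image.
#' @param seed global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(modality = c("SWI", "GRE"),
                            vessel_removal = list(beta1 = 0.9, beta2 = 20,
                                                  scales_vox = c(1, 2, 3),
                                                  sigma_grad = 1,
                                                  sigma_window = 1.5,
                                                  on = "raw"),
                            features = feature_config(),
                            shape = shape_criteria(),
                            th_ncmb = NULL,
                            neg_pos_ratio = 10,
                            max_train_rows = 6000L,
                            clahe_on = c("vessel_removed", "original"),
                            seed = 1L) {
  modality <- match.arg(modality)
  clahe_on <- match.arg(clahe_on)
  structure(list(modality = modality,
                 vessel_removal = vessel_removal,
                 features = features,
                 shape = shape,
                 th_ncmb = th_ncmb,
                 neg_pos_ratio = neg_pos_ratio,
                 max_train_rows = as.integer(max_train_rows),
                 clahe_on = clahe_on,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config].
#' @param path YAML file path.
#' @return `read_config` returns the reconstructed [pipeline_config];
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), identity, how = "list")
  plain$features <- unclass(config$features)
  plain$shape <- unclass(config$shape)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    modality = y$modality,
    vessel_removal = lapply(y$vessel_removal, unlist),
    features = do.call(feature_config, lapply(y$features, unlist)),
    shape = do.call(shape_criteria, lapply(y$shape, unlist)),
    th_ncmb = y$th_ncmb,
    neg_pos_ratio = y$neg_pos_ratio,
    max_train_rows = y$max_train_rows,
    clahe_on = y$clahe_on,
    seed = y$seed)
}

# subject input normalization: accepts phantom_subject, volume_image, array,
# or a NIfTI path; returns list(image, mask, truth?)
.as_subject <- function(subject, mask = NULL) {
  if (inherits(subject, "phantom_subject"))
    return(list(image = subject$image, mask = subject$brain_mask,
                truth = subject$cmb_truth))
  if (is.character(subject)) subject <- read_volume(subject)
  img <- as_volume(subject)
  if (is.character(mask)) mask <- read_volume(mask)$voxels > 0.5
  list(image = img, mask = mask, truth = NULL)
}

# stages: reorient -> mask -> standardize -> vessel removal -> feature stack
# Stage-1 features default to raw intensities: the Frangi beta2 = 20 noise
# cutoff is calibrated for native intensity units, where object responses
# saturate the contrast term and the filter becomes shape-driven.
pipeline_stages <- function(image, mask = NULL, config = pipeline_config(),
                            seed = config$seed) {
  img <- reorient_canonical(as_volume(image))
  mask <- compute_brain_mask(img, mask)
  std <- standardize_intensity(img, mask)
  vr_cfg <- config$vessel_removal
  stage1_input <- if (identical(vr_cfg$on, "standardized")) std else img
  vr <- remove_vessels(stage1_input, mask,
                       frangi_params(vr_cfg$beta1, vr_cfg$beta2,
                                     vr_cfg$scales_vox),
                       sigma_grad = vr_cfg$sigma_grad,
                       sigma_window = vr_cfg$sigma_window,
                       seed = derive_seed(seed, 1L))
  clahe_src <- if (config$clahe_on == "original") std else NULL
  stack <- assemble_features(vr$image, mask, config$features,
                             clahe_source = clahe_src)
  list(image = img, mask = mask, std = std, vessel_removed = vr$image,
       vessel_mask = vr$vessel_mask, stack = stack)
}

#' Train the voxel-level candidate classifier
#'
#' Fits a radial-basis support-vector machine on normalized 7-feature voxel
#' vectors, with Platt sigmoid probability calibration fitted on a held-out
#' calibration split (deterministic for a given seed). Both classes must be
#' present.
#'
#' @param training a list with elements `x` (n x 7 matrix) and `y` (0/1), or
#'   a list of such lists from several subjects.
#' @param cfg the [feature_config] the features were built with.
#' @param seed seed for the fit/calibration split.
#' @param max_rows stratified cap on training rows.
#' @return Object of class `cmb_model`.
#' @export
train_voxel_classifier <- function(training, cfg = feature_config(),
                                   seed = 1L, max_rows = 6000L) {
  if (!is.null(training$x)) training <- list(training)
  x <- do.call(rbind, lapply(training, `[[`, "x"))
  y <- unlist(lapply(training, `[[`, "y"))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (nrow(x) > max_rows) {
    keep <- with_seed(derive_seed(seed, 2L), {
      f <- max_rows / nrow(x)
      unlist(lapply(split(seq_along(y), y), function(ix)
        sample(ix, max(2L, floor(f * length(ix))))))
    })
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  # deterministic stratified 80/20 fit/calibration split
  cal <- with_seed(derive_seed(seed, 3L),
                   unlist(lapply(split(seq_along(y), y), function(ix)
                     sample(ix, max(1L, floor(0.2 * length(ix)))))))
  cal <- sort(cal)
  fit <- setdiff(seq_along(y), cal)
  if (length(unique(y[fit])) < 2L || length(unique(y[cal])) < 2L)
    stop("both classes required in fit and calibration splits")
  svm_fit <- e1071::svm(x[fit, , drop = FALSE], factor(y[fit], levels = c(0, 1)),
                        kernel = "radial", scale = TRUE, probability = FALSE)
  dv_cal <- attr(predict(svm_fit, x[cal, , drop = FALSE],
                         decision.values = TRUE), "decision.values")[, 1]
  platt <- suppressWarnings(
    glm(y[cal] ~ dv_cal, family = binomial()))
  structure(list(svm = svm_fit,
                 platt = unname(stats::coef(platt)),
                 feature_config = cfg,
                 feature_names = colnames(x),
                 n_pos = sum(y == 1), n_neg = sum(y == 0),
                 seed = seed),
            class = "cmb_model")
}

#' Fit the CMB preselection model on a training cohort
#'
#' The main fitting entry point. Runs the vessel-removal and feature stages
#' on every training subject that has voxel-level truth, samples training
#' voxels (all positives plus `neg_pos_ratio` negatives per positive), and
#' trains the calibrated voxel classifier. The returned model carries the
#' full pipeline configuration, so [predict.cmb_model()] can run the whole
#' pipeline on new subjects.
#'
#' @param cohort list of `phantom_subject`s, or a manifest data.frame with
#'   columns `image_path`, `mask_path`, `truth_path` (and `subject_id`).
#' @param config a [pipeline_config].
#' @param seed overrides `config$seed`.
#' @return Object of class `cmb_model`.
#' @export
cmb_fit <- function(cohort, config = pipeline_config(), seed = config$seed) {
  if (is.data.frame(cohort)) {
    if (!all(c("image_path", "truth_path") %in% names(cohort)))
      stop("manifest must name image_path and truth_path columns")
    cohort <- lapply(seq_len(nrow(cohort)), function(i) {
      img <- read_volume(cohort$image_path[i])
      msk <- if ("mask_path" %in% names(cohort) && nzchar(cohort$mask_path[i]))
        read_volume(cohort$mask_path[i])$voxels > 0.5 else NULL
      tru <- round(read_volume(cohort$truth_path[i])$voxels)
      structure(list(image = img, brain_mask = msk, cmb_truth = tru,
                     has_cmb = any(tru > 0), placed_cmb_count = NA_integer_,
                     spec = NULL), class = "phantom_subject")
    })
  }
  samples <- list()
  n_used <- 0L
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    truth <- sub$cmb_truth
    if (is.null(truth) || !any(truth > 0)) next
    st <- pipeline_stages(sub$image, sub$brain_mask, config,
                          seed = derive_seed(seed, 10L + i))
    samples[[length(samples) + 1L]] <-
      sample_training_voxels(st$stack, truth, config$neg_pos_ratio,
                             seed = derive_seed(seed, 100L + i))
    n_used <- n_used + 1L
  }
  if (length(samples) == 0L)
    stop("no training subject has positive truth voxels")
  model <- train_voxel_classifier(samples, config$features, seed = seed,
                                  max_rows = config$max_train_rows)
  model$config <- config
  model$n_subjects <- n_used
  model
}

#' @export
print.cmb_model <- function(x, ...) {
  cat("CMB voxel-candidate model (radial-basis SVM, Platt-calibrated)\n")
  cat(sprintf("  training voxels: %d positive, %d negative%s\n",
              x$n_pos, x$n_neg,
              if (!is.null(x$n_subjects))
                sprintf(" from %d subject(s)", x$n_subjects) else ""))
  cat(sprintf("  support vectors: %d; th_prob = %.2f\n",
              nrow(x$svm$SV), x$feature_config$th_prob))
  invisible(x)
}

#' @export
summary.cmb_model <- function(object, ...) {
  print(object)
  cat(sprintf("  Platt calibration: p = plogis(%.3f + %.3f * decision)\n",
              object$platt[1], object$platt[2]))
  if (!is.null(object$config)) {
    cat(sprintf("  modality %s, subject threshold %s\n",
                object$config$modality,
                ifelse(is.null(object$config$th_ncmb), "modality default",
                       object$config$th_ncmb)))
  }
  invisible(object)
}

#' Voxel-wise CMB probability map
#'
#' Applies the calibrated classifier to a feature stack, producing the
#' per-voxel probability of being a microbleed voxel; voxels outside the
#' brain mask get probability 0.
#'
#' @param model a [cmb_model][cmb_fit].
#' @param stack a [assemble_features()] stack built with a compatible
#'   [feature_config].
#' @return Numeric 3-D array of probabilities in [0, 1].
#' @export
predict_probability <- function(model, stack) {
  stopifnot(inherits(model, "cmb_model"),
            inherits(stack, "voxel_feature_stack"))
  if (!identical(names(stack$features), model$feature_names))
    stop("feature stack does not match the features the model was trained on")
  x <- stack_matrix(stack)
  dv <- attr(predict(model$svm, x, decision.values = TRUE),
             "decision.values")[, 1]
  p <- plogis(model$platt[1] + model$platt[2] * dv)
  out <- array(0, dim = dim(stack$mask))
  out[stack$mask] <- pmin(pmax(p, 0), 1)
  out
}

#' Threshold a probability map into the initial candidate mask
#'
#' @param p_cmb probability array from [predict_probability()].
#' @param th_prob global probability threshold (strict `>`).
#' @param mask optional brain mask to intersect with.
#' @return Logical candidate mask.
#' @export
threshold_candidates <- function(p_cmb, th_prob = 0.8, mask = NULL) {
  out <- p_cmb > th_prob
  if (!is.null(mask)) out <- out & mask
  out
}

#' Run the full pipeline on one subject
#'
#' Executes reorientation, brain masking, standardization, vessel/sulci
#' removal, feature extraction, probability prediction, thresholding,
#' component labeling, shape filtering and the subject decision.
#'
#' @param object a fitted [cmb_model][cmb_fit].
#' @param subject a `phantom_subject`, [volume_image], 3-D array or NIfTI
#'   path.
#' @param mask optional brain mask (array or NIfTI path).
#' @param th_prob,th_ncmb optional overrides of the model configuration.
#' @param subject_id identifier for reports.
#' @param return_maps keep the probability map, vessel mask and candidate
#'   label arrays in the result (memory-heavy).
#' @param ... unused.
#' @return Object of class `cmb_prediction`: the [subject_decision] fields
#'   plus `candidates` (per-component QC report), `surviving_labels`
#'   (labeled array of surviving components) and optionally the stage maps.
#' @export
predict.cmb_model <- function(object, subject, mask = NULL, th_prob = NULL,
                              th_ncmb = NULL, subject_id = NA_character_,
                              return_maps = FALSE, ...) {
  config <- object$config
  if (is.null(config)) config <- pipeline_config(features = object$feature_config)
  sub <- .as_subject(subject, mask)
  st <- pipeline_stages(sub$image, sub$mask, config, seed = config$seed)
  p_cmb <- predict_probability(object, st$stack)
  if (is.null(th_prob)) th_prob <- object$feature_config$th_prob
  cand <- threshold_candidates(p_cmb, th_prob, st$mask)
  comps <- label_components(cand)
  filt <- filter_candidates(comps, config$shape,
                            voxel_size_mm = st$stack$voxel_size_mm)
  th <- if (!is.null(th_ncmb)) subject_threshold(th_ncmb, config$modality)
  else subject_threshold(config$th_ncmb, config$modality)
  dec <- decide_subject(filt, th, subject_id = subject_id)
  out <- c(unclass(dec),
           list(candidates = filt$report,
                surviving_labels = components_to_labels(filt$surviving,
                                                        dim(st$mask)),
                th_prob = th_prob))
  if (return_maps) {
    out$p_cmb <- p_cmb
    out$vessel_mask <- st$vessel_mask
    out$candidate_mask <- cand
  }
  class(out) <- "cmb_prediction"
  out
}

#' @export
print.cmb_prediction <- function(x, ...) {
  cat(sprintf("subject %s: %d initial candidate(s), %d surviving, threshold %d -> %s\n",
              x$subject_id, nrow(x$candidates), x$candidate_count, x$th_ncmb,
              if (x$is_cmb_subject) "CMB subject" else "non-CMB subject"))
  invisible(x)
}

#' Sweep the probability threshold and measure cluster-wise FROC points
#'
#' For each threshold in the grid, thresholds the cohort's probability maps,
#' labels 26-connected clusters and computes cluster-wise TPR and FPavg
#' against the truth. Probability maps are computed once per subject. This is
#' the sweep used to select `th_prob` as the highest-TPR point at an
#' acceptable FPavg.
#'
#' @param model a fitted [cmb_model][cmb_fit].
#' @param cohort list of `phantom_subject`s (with `cmb_truth`).
#' @param grid probability thresholds (default 0 to 1 in steps of 0.1).
#' @return A [froc_curve()] object whose points carry `threshold`, `tpr`,
#'   `fpavg`.
#' @export
sweep_th_prob <- function(model, cohort, grid = seq(0, 1, by = 0.1)) {
  config <- model$config
  if (is.null(config)) config <- pipeline_config(features = model$feature_config)
  pmaps <- lapply(cohort, function(sub) {
    st <- pipeline_stages(sub$image, sub$brain_mask, config,
                          seed = config$seed)
    list(p = predict_probability(model, st$stack), mask = st$mask,
         truth = sub$cmb_truth)
  })
  rows <- lapply(grid, function(th) {
    det <- lapply(pmaps, function(pm) {
      m <- threshold_candidates(pm$p, th, pm$mask)
      attr(label_components(m), "labels")
    })
    cm <- cluster_metrics(det, lapply(pmaps, `[[`, "truth"))
    data.frame(threshold = th, tpr = cm$cluster_tpr, fpavg = cm$fpavg)
  })
  froc_curve(do.call(rbind, rows))
}
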
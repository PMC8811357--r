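#' Subject-level candidate-count threshold
#'
#' A subject is called CMB-positive when its surviving candidate count
#' strictly exceeds `th_ncmb`. Defaults are per modality: 35 for SWI, 30 for
#' T2*-GRE (SWI enhances mimics as well as microbleeds, so a higher count
#' threshold is needed). The threshold is intentionally set above plausible
#' true CMB counts to absorb residual false positives on clinical data; for
#' clean synthetic cohorts a much lower value is appropriate.
#'
#' @param th_ncmb nonnegative integer threshold; if `NULL`, the modality
#'   default is used.
#' @param modality `"SWI"` or `"GRE"`.
#' @return An object of class `subject_threshold`.
#' @export
subject_threshold <- function(th_ncmb = NULL, modality = c("SWI", "GRE")) {
  modality <- match.arg(modality)
  defaults <- c(SWI = 35L, GRE = 30L)
  if (is.null(th_ncmb)) th_ncmb <- defaults[[modality]]
  th_ncmb <- as.integer(th_ncmb)
  if (is.na(th_ncmb) || th_ncmb < 0) stop("'th_ncmb' must be >= 0")
  structure(list(th_ncmb = th_ncmb, modality = modality),
            class = "subject_threshold")
}

#' Subject-level CMB decision
#'
#' Converts a surviving candidate count into the binary subject call:
#' CMB-positive iff `count > th_ncmb` (strict; a count equal to the threshold
#' is a non-CMB call).
#'
#' @param candidates surviving components (a list), a `filter_candidates()`
#'   result, or a plain count.
#' @param th a [subject_threshold] (or integer threshold).
#' @param subject_id optional identifier carried into the result.
#' @return Object of class `subject_decision`: list with `subject_id`,
#'   `candidate_count`, `th_ncmb`, `is_cmb_subject`.
#' @export
decide_subject <- function(candidates, th = subject_threshold(),
                           subject_id = NA_character_) {
  if (is.numeric(th)) th <- subject_threshold(th)
  count <- if (is.numeric(candidates)) {
    as.integer(candidates)
  } else if (is.list(candidates) && !is.null(candidates$surviving)) {
    length(candidates$surviving)
  } else {
    length(candidates)
  }
  structure(list(subject_id = subject_id, candidate_count = count,
                 th_ncmb = th$th_ncmb,
                 is_cmb_subject = count > th$th_ncmb),
            class = "subject_decision")
}

#' @export
print.subject_decision <- function(x, ...) {
  cat(sprintf("subject %s: %d surviving candidate(s), threshold %d -> %s\n",
              x$subject_id, x$candidate_count, x$th_ncmb,
              if (x$is_cmb_subject) "CMB subject" else "non-CMB subject"))
  invisible(x)
}

#' Intensity-percentile baseline candidate mask
#'
#' Baseline replacement for the classifier stage: after the same
#' preprocessing and vessel removal as the main pipeline, in-brain voxels
#' with intensity strictly below the within-mask 5th-percentile value become
#' initial candidates. Downstream shape filtering and subject decision reuse
#' the main modules unchanged.
#'
#' @param img a [volume_image] (vessel-removed for the controlled comparison).
#' @param mask logical brain mask.
#' @param percentile lower percentile (default 5), computed within the mask
#'   with linear interpolation.
#' @return Logical candidate mask (subset of `mask`).
#' @export
baseline_candidate_mask <- function(img, mask, percentile = 5) {
  img <- as_volume(img)
  if (!all(dim(mask) == dim(img$voxels))) stop("mask shape mismatch")
  mask <- array(as.logical(mask), dim = dim(mask))
  thr <- quantile(img$voxels[mask], percentile / 100, names = FALSE)
  mask & img$voxels < thr
}

#' Sweep the subject-count threshold and build ROC points
#'
#' Evaluates the subject decision rule over a grid of count thresholds
#' (default 10 to 80 in steps of 5) and reports subject-level TPR and FPR at
#' each, plus the knee point operationalized as the threshold maximizing the
#' Youden index (TPR - FPR).
#'
#' @param counts integer vector of surviving candidate counts per subject.
#' @param labels logical vector of true subject labels.
#' @param grid integer thresholds to evaluate.
#' @return Object of class `cmb_roc_sweep`: data.frame of
#'   (threshold, tpr, fpr, youden) with the knee threshold as attribute
#'   `knee`.
#' @export
sweep_th_ncmb <- function(counts, labels, grid = seq(10L, 80L, by = 5L)) {
  labels <- as.logical(labels)
  rows <- lapply(grid, function(th) {
    dec <- counts > th
    m <- subject_metrics(dec, labels)
    data.frame(threshold = th, tpr = m$tpr, fpr = 1 - m$specificity)
  })
  tab <- do.call(rbind, rows)
  tab$youden <- tab$tpr - tab$fpr
  knee <- if (all(is.na(tab$youden))) NA_integer_ else
    tab$threshold[which.max(tab$youden)]
  structure(tab, knee = knee, class = c("cmb_roc_sweep", "data.frame"))
}

#' @export
plot.cmb_roc_sweep <- function(x, ...) {
  plot(roc_curve(x), ...)
}
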
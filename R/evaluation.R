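#' Subject-level detection metrics
#'
#' Computes subject-level true positive rate, specificity and accuracy from
#' binary predictions and truth labels:
#' `TPR = S_TP / (S_TP + S_FN)`, `specificity = S_TN / (S_TN + S_FP)`,
#' `accuracy = (S_TP + S_TN) / S_N`. A metric with a zero denominator is
#' reported as `NA` (undefined) and flagged, never coerced to 0 or 1.
#'
#' @param predicted logical vector of CMB-subject calls.
#' @param truth logical vector of true subject labels, same length/ids.
#' @return List with `tpr`, `specificity`, `accuracy`, the confusion counts,
#'   and `undefined` (names of undefined metrics).
#' @export
subject_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have the same length")
  s_tp <- sum(predicted & truth)
  s_fp <- sum(predicted & !truth)
  s_tn <- sum(!predicted & !truth)
  s_fn <- sum(!predicted & truth)
  n <- length(truth)
  undefined <- character(0)
  tpr <- if (s_tp + s_fn > 0) s_tp / (s_tp + s_fn) else {
    undefined <- c(undefined, "tpr"); NA_real_
  }
  spec <- if (s_tn + s_fp > 0) s_tn / (s_tn + s_fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  acc <- if (n > 0) (s_tp + s_tn) / n else {
    undefined <- c(undefined, "accuracy"); NA_real_
  }
  list(tpr = tpr, specificity = spec, accuracy = acc,
       s_tp = s_tp, s_fp = s_fp, s_tn = s_tn, s_fn = s_fn,
       n_subjects = n, undefined = undefined)
}

#' Cluster-wise detection metrics
#'
#' Matches detected components against truth components by the
#' at-least-one-voxel overlap rule: a truth cluster counts as a true positive
#' if any detected cluster overlaps it by one or more voxels; detected
#' clusters with no overlap with any truth cluster are false positives. One
#' detection covering two truth clusters yields two TPs and no FP.
#' `cluster TPR = TP / (TP + FN)`; `FPavg` = total FPs over the cohort
#' divided by the number of subjects.
#'
#' @param detected list of integer-labeled detection arrays (one per subject),
#'   or a single array.
#' @param truth list of integer-labeled truth arrays (aligned), or an array.
#' @param n_subjects number of subjects (defaults to `length(detected)`).
#' @return List with `cluster_tpr`, `fpavg`, the raw counts
#'   (`tp_clus`, `fn_clus`, `fp_clus_total`) and `undefined`.
#' @export
cluster_metrics <- function(detected, truth, n_subjects = NULL) {
  if (is.array(detected)) detected <- list(detected)
  if (is.array(truth)) truth <- list(truth)
  if (length(detected) != length(truth))
    stop("'detected' and 'truth' must pair up per subject")
  if (is.null(n_subjects)) n_subjects <- length(detected)
  tp <- fn <- fp <- 0L
  for (i in seq_along(detected)) {
    det <- detected[[i]]
    tru <- truth[[i]]
    if (!all(dim(det) == dim(tru))) stop("subject ", i, ": shape mismatch")
    truth_ids <- unique(tru[tru > 0L])
    det_ids <- unique(det[det > 0L])
    both <- det > 0L & tru > 0L
    hit_truth <- unique(tru[both])
    hit_det <- unique(det[both])
    tp <- tp + length(hit_truth)
    fn <- fn + length(truth_ids) - length(hit_truth)
    fp <- fp + length(det_ids) - length(hit_det)
  }
  undefined <- character(0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- "cluster_tpr"; NA_real_
  }
  list(cluster_tpr = tpr, fpavg = fp / n_subjects,
       tp_clus = tp, fn_clus = fn, fp_clus_total = fp,
       n_subjects = n_subjects, undefined = undefined)
}

#' Subject-level ROC curve and AUC
#'
#' Sorts operating points by false positive rate, anchors the curve at
#' (0, 0) and (1, 1), and integrates by the trapezoid rule. With fewer than
#' two distinct points the AUC is undefined (`NA`).
#'
#' @param points data.frame with columns `fpr` and `tpr` (and optionally
#'   `threshold`).
#' @return Object of class `cmb_roc`: list with the sorted `points`, `auc`
#'   and `undefined` flag.
#' @export
roc_curve <- function(points) {
  stopifnot(all(c("fpr", "tpr") %in% names(points)))
  pts <- points[is.finite(points$fpr) & is.finite(points$tpr), , drop = FALSE]
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  distinct <- nrow(unique(pts[, c("fpr", "tpr")]))
  if (distinct < 2L) {
    return(structure(list(points = pts, auc = NA_real_, undefined = TRUE),
                     class = "cmb_roc"))
  }
  x <- c(0, pts$fpr, 1)
  y <- c(0, pts$tpr, 1)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  structure(list(points = pts, auc = min(max(auc, 0), 1), undefined = FALSE),
            class = "cmb_roc")
}

#' @export
print.cmb_roc <- function(x, ...) {
  cat(sprintf("subject-level ROC: %d point(s), AUC = %s\n", nrow(x$points),
              ifelse(x$undefined, "undefined", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' @export
plot.cmb_roc <- function(x, ...) {
  plot(c(0, x$points$fpr, 1), c(0, x$points$tpr, 1), type = "b",
       xlab = "subject-level FPR", ylab = "subject-level TPR",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cluster-wise FROC curve
#'
#' Sorts operating points by average false positives per subject; no area is
#' computed (the x axis is unbounded).
#'
#' @param points data.frame with columns `fpavg` and `tpr`.
#' @return Object of class `cmb_froc` holding the sorted points.
#' @export
froc_curve <- function(points) {
  stopifnot(all(c("fpavg", "tpr") %in% names(points)))
  pts <- points[order(points$fpavg, points$tpr), , drop = FALSE]
  structure(list(points = pts), class = "cmb_froc")
}

#' @export
print.cmb_froc <- function(x, ...) {
  cat(sprintf("FROC: %d point(s), FPavg range [%s, %s]\n", nrow(x$points),
              signif(min(x$points$fpavg), 3), signif(max(x$points$fpavg), 3)))
  invisible(x)
}

#' @export
plot.cmb_froc <- function(x, ...) {
  plot(x$points$fpavg, x$points$tpr, type = "b",
       xlab = "FPavg (false positives / subject)", ylab = "cluster-wise TPR",
       ylim = c(0, 1), ...)
  invisible(x)
}
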
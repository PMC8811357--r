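#' Train the pipeline from a cohort manifest
#'
#' Orchestration wrapper around [cmb_fit()]: accepts an in-memory cohort or a
#' manifest CSV naming image/mask/truth NIfTI paths, fits the model, and
#' optionally serializes it (with its configuration and a provenance record)
#' to `model_path`.
#'
#' @param cohort list of `phantom_subject`s, a manifest data.frame, or the
#'   path of a manifest CSV.
#' @param config a [pipeline_config].
#' @param model_path optional output path for the serialized model (`.rds`).
#' @return The fitted [cmb_model][cmb_fit], invisibly if written to disk.
#' @export
run_train <- function(cohort, config = pipeline_config(), model_path = NULL) {
  if (is.character(cohort)) cohort <- read.csv(cohort, stringsAsFactors = FALSE)
  model <- cmb_fit(cohort, config)
  model$provenance <- list(
    fitted = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("cmbselect")),
    seed = config$seed)
  if (!is.null(model_path)) {
    saveRDS(model, model_path)
    return(invisible(model))
  }
  model
}

#' Predict subject status for one or more subjects
#'
#' Runs the full pipeline per subject and collects per-subject decisions and
#' candidate reports. Optionally writes the decision table and per-subject
#' candidate reports as CSV.
#'
#' @param model a fitted [cmb_model][cmb_fit] or path to a serialized model.
#' @param subjects one subject (see [predict.cmb_model()]) or a list of them.
#' @param masks optional list of masks matching `subjects`.
#' @param out_dir optional directory for `decisions.csv` and
#'   `candidates_<id>.csv` reports.
#' @param ... passed to [predict.cmb_model()].
#' @return List with `decisions` (data.frame) and `predictions` (list of
#'   `cmb_prediction`s).
#' @export
run_predict <- function(model, subjects, masks = NULL, out_dir = NULL, ...) {
  if (is.character(model)) model <- readRDS(model)
  one <- inherits(subjects, c("phantom_subject", "volume_image")) ||
    (is.array(subjects) && length(dim(subjects)) == 3L) ||
    is.character(subjects) && length(subjects) == 1L
  if (one) subjects <- list(subjects)
  ids <- names(subjects)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_along(subjects))
  preds <- lapply(seq_along(subjects), function(i)
    predict(model, subjects[[i]],
            mask = if (is.null(masks)) NULL else masks[[i]],
            subject_id = ids[i], ...))
  decisions <- do.call(rbind, lapply(preds, function(p)
    data.frame(subject_id = p$subject_id,
               candidate_count = p$candidate_count,
               th_ncmb = p$th_ncmb,
               is_cmb_subject = p$is_cmb_subject)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(decisions, file.path(out_dir, "decisions.csv"),
              row.names = FALSE)
    jsonlite::write_json(decisions, file.path(out_dir, "decisions.json"),
                         auto_unbox = TRUE, digits = NA)
    for (p in preds)
      write.csv(p$candidates,
                file.path(out_dir, sprintf("candidates_%s.csv", p$subject_id)),
                row.names = FALSE)
  }
  list(decisions = decisions, predictions = preds)
}

#' Evaluate subject-level predictions against truth labels
#'
#' Joins decisions to truth labels by subject id and computes the
#' subject-level metrics; an id mismatch is an error listing the offenders.
#'
#' @param decisions data.frame with `subject_id` and `is_cmb_subject` (as
#'   produced by [run_predict()]).
#' @param labels data.frame with `subject_id` and `has_cmb`.
#' @return The [subject_metrics()] list.
#' @export
run_evaluate <- function(decisions, labels) {
  missing_ids <- setdiff(decisions$subject_id, labels$subject_id)
  extra_ids <- setdiff(labels$subject_id, decisions$subject_id)
  if (length(missing_ids) || length(extra_ids))
    stop("subject id mismatch; unmatched: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  m <- match(decisions$subject_id, labels$subject_id)
  subject_metrics(decisions$is_cmb_subject, labels$has_cmb[m])
}

#' Sweep the subject threshold over a cohort of predictions
#'
#' Convenience wrapper: takes candidate counts and labels (or the outputs of
#' [run_predict()] plus a label table) and produces the ROC sweep table and
#' curve.
#'
#' @param decisions data.frame with `subject_id` and `candidate_count`.
#' @param labels data.frame with `subject_id` and `has_cmb`.
#' @param grid thresholds (default 10..80 by 5).
#' @return List with `sweep` (the [sweep_th_ncmb()] table) and `roc` (the
#'   [roc_curve()] object).
#' @export
run_sweep <- function(decisions, labels, grid = seq(10L, 80L, by = 5L)) {
  m <- match(decisions$subject_id, labels$subject_id)
  if (any(is.na(m)))
    stop("subject id mismatch; unmatched: ",
         paste(decisions$subject_id[is.na(m)], collapse = ", "))
  sw <- sweep_th_ncmb(decisions$candidate_count, labels$has_cmb[m], grid)
  list(sweep = sw, roc = roc_curve(sw))
}

#' Cross-validation fold assignment
#'
#' Deterministically assigns ids to `k` folds (shuffled once with `seed`);
#' `k = length(ids)` gives leave-one-out. Every id lands in exactly one test
#' fold and fold sizes differ by at most one.
#'
#' @param ids subject identifiers.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return List of `k` character/integer vectors (the test ids per fold).
#' @export
make_folds <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (k < 2L || k > n) stop("'k' must be between 2 and length(ids)")
  perm <- with_seed(seed, sample(n))
  unname(split(ids[perm], rep_len(seq_len(k), n)))
}
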
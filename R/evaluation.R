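#' Voxelwise confusion counts
#'
#' Exact TP/FP/FN/TN counts of a predicted binary label volume against a
#' ground-truth mask, restricted to an evaluation mask (by default all
#' voxels). A TP is a correctly identified lesional voxel; an FP a
#' non-lesional voxel called lesional; an FN a missed lesional voxel; a TN a
#' correctly rejected non-lesional voxel.
#'
#' @param pred 0/1 3D array or [fcd_volume].
#' @param truth 0/1 3D array or [fcd_volume] on the same grid.
#' @param mask optional logical array of voxels to evaluate.
#' @param level `"voxel"` or `"subject"` (annotation only).
#' @return An object of class `puv_confusion`: list with integer `tp`, `fp`,
#'   `fn`, `tn` and the `level`.
#' @export
confusion_counts <- function(pred, truth, mask = NULL, level = "voxel") {
  p <- if (inherits(pred, "fcd_volume")) pred$data else pred
  t <- if (inherits(truth, "fcd_volume")) truth$data else truth
  if (!identical(dim(p), dim(t))) stop("prediction/truth grid mismatch")
  if (is.null(mask)) mask <- TRUE else {
    if (!identical(dim(mask), dim(p))) stop("mask grid mismatch")
  }
  p <- (p != 0)[mask]; t <- (t != 0)[mask]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t), level = level),
            class = "puv_confusion")
}

#' @export
print.puv_confusion <- function(x, ...) {
  cat(sprintf("<puv_confusion> (%s) TP %d  FP %d  FN %d  TN %d\n",
              x$level, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Detection metrics from confusion counts
#'
#' `TPR = TP/(TP+FN)` (sensitivity; equals recall), `FPR = FP/(FP+TN)`,
#' `precision = TP/(TP+FP)` and the F-score
#' `2 * precision * recall / (precision + recall)`. Conventions for empty
#' denominators: precision is 0 when no positive calls were made; the F-score
#' is 0 when precision + recall is 0; TPR is `NA` when the truth has no
#' positives.
#'
#' @param counts a `puv_confusion` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return An object of class `puv_metrics`: list with `tpr`, `fpr`,
#'   `precision`, `recall`, `f_score` and the counts.
#' @export
detection_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  tpr <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  fpr <- if (fp + tn == 0) NA_real_ else fp / (fp + tn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (is.na(tpr)) 0 else tpr
  f_score <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tpr = tpr, fpr = fpr, precision = precision, recall = recall,
                 f_score = f_score, counts = counts),
            class = "puv_metrics")
}

#' @export
print.puv_metrics <- function(x, ...) {
  cat(sprintf("<puv_metrics> TPR %.4f  FPR %.4f  precision %.4f  F %.4f\n",
              x$tpr, x$fpr, x$precision, x$f_score))
  invisible(x)
}

#' Subject-level metrics from patient/control calls
#'
#' Patient is the positive class. Unknown subject ids in `truth_flags` raise
#' an error.
#'
#' @param calls list of `puv_call`s (or a logical vector named by subject id).
#' @param truth_flags named logical vector: subject id -> is actually patient.
#' @return A `puv_metrics` with subject-level counts.
#' @export
subject_metrics <- function(calls, truth_flags) {
  if (is.list(calls)) {
    pred <- vapply(calls, function(cl) cl$is_patient_pred, logical(1))
    names(pred) <- vapply(calls, function(cl) cl$subject_id, character(1))
  } else pred <- calls
  if (is.null(names(pred)) || !all(names(pred) %in% names(truth_flags)))
    stop("unknown subject id in calls")
  truth <- truth_flags[names(pred)]
  counts <- structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                           fn = sum(!pred & truth), tn = sum(!pred & !truth),
                           level = "subject"),
                      class = "puv_confusion")
  detection_metrics(counts)
}
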
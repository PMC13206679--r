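# Task-standard evaluation metrics: classification (accuracy, sensitivity,
# specificity, AUROC, F1) and segmentation (IoU, precision, recall, F1).

#' Binary classification metrics from confusion counts
#'
#' Undefined ratios follow the usual convention: a 0/0 denominator yields
#' 1.0 (vacuously perfect), a 0-numerator over a positive denominator 0.0.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts; their total must
#'   be at least 1.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   each in `[0, 1]`.
#' @examples
#' classification_metrics(tp = 8, fp = 5, tn = 5, fn = 2)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    sulba_stop("confusion counts must be non-negative integers",
               "invalid_counts_error")
  }
  total <- sum(counts)
  if (total < 1) {
    sulba_stop("at least one observation is required", "invalid_counts_error")
  }
  list(accuracy = (tp + tn) / total,
       sensitivity = safe_ratio(tp, tp + fn),
       specificity = safe_ratio(tn, tn + fp),
       f1 = safe_ratio(2 * tp, 2 * tp + fp + fn))
}

safe_ratio <- function(num, den) {
  if (den == 0) 1.0 else num / den
}

#' Area under the ROC curve
#'
#' Computed exactly as the Mann–Whitney statistic: the fraction of
#' (positive, negative) score pairs in which the positive outscores the
#' negative, ties counted one half. Invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    sulba_stop("scores and labels must have equal length",
               "invalid_predictions_error")
  }
  if (!all(labels %in% c(0, 1))) {
    sulba_stop("labels must be binary", "invalid_predictions_error")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    sulba_stop("both classes must be present for AUROC",
               "undefined_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged one-vs-rest AUROC
#'
#' For multiclass problems each class is scored against the rest and the
#' per-class AUROCs are averaged unweighted. Classes absent from `labels`
#' are skipped.
#'
#' @param score_matrix Numeric matrix, one column of scores per class;
#'   column names (or indices) identify the classes.
#' @param labels Vector of true class labels matching the columns.
#' @return Macro AUROC in `[0, 1]`.
#' @export
auroc_macro <- function(score_matrix, labels) {
  score_matrix <- as.matrix(score_matrix)
  classes <- colnames(score_matrix)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(score_matrix)))
  labels <- as.character(labels)
  present <- classes[classes %in% labels]
  if (length(present) == 0L || all(labels == labels[1])) {
    sulba_stop("need at least two classes present", "undefined_metric_error")
  }
  per <- vapply(present, function(cl) {
    y <- as.integer(labels == cl)
    if (all(y == 1L) || all(y == 0L)) return(NA_real_)
    auroc(score_matrix[, match(cl, classes)], y)
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

#' Macro-averaged one-vs-rest classification metrics
#'
#' Accuracy is plain multiclass accuracy; sensitivity, specificity and F1
#' are computed one-vs-rest per class and averaged unweighted across the
#' classes present in the truth.
#'
#' @param predicted Vector of predicted class labels.
#' @param truth Vector of true class labels, same length.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`, `f1`.
#' @export
classification_metrics_macro <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    sulba_stop("predicted and truth must be equal-length, non-empty",
               "invalid_predictions_error")
  }
  classes <- sort(unique(truth))
  per <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    classification_metrics(tp, fp, tn, fn)
  })
  list(accuracy = mean(predicted == truth),
       sensitivity = mean(vapply(per, `[[`, numeric(1), "sensitivity")),
       specificity = mean(vapply(per, `[[`, numeric(1), "specificity")),
       f1 = mean(vapply(per, `[[`, numeric(1), "f1")))
}

#' Binary segmentation overlap metrics
#'
#' With intersection `I` and union `U` of the foreground sets:
#' `iou = I/U`, `precision = I/|pred|`, `recall = I/|truth|`,
#' `f1 = 2I/(|pred| + |truth|)` (the Dice coefficient). Empty-mask 0/0
#' cases return 1.0.
#'
#' @param predicted Binary (0/1 or logical) spatial grid.
#' @param truth Binary spatial grid of identical shape.
#' @return Named list with `iou`, `precision`, `recall`, `f1` in `[0, 1]`.
#' @export
segmentation_metrics <- function(predicted, truth) {
  p <- extract_binary(predicted)
  t_ <- extract_binary(truth)
  if (length(p) != length(t_)) {
    sulba_stop("predicted and truth masks differ in shape",
               "shape_mismatch_error")
  }
  I <- sum(p & t_)
  U <- sum(p | t_)
  list(iou = safe_ratio(I, U),
       precision = safe_ratio(I, sum(p)),
       recall = safe_ratio(I, sum(t_)),
       f1 = safe_ratio(2 * I, sum(p) + sum(t_)))
}

extract_binary <- function(m) {
  if (inherits(m, "data_tensor")) m <- m$values
  v <- c(m)
  if (!all(v %in% c(0, 1, TRUE, FALSE))) {
    sulba_stop("masks must be binary", "invalid_mask_error")
  }
  as.logical(v)
}
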
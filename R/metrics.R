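#' @title Imbalance-aware forecast evaluation metrics
#' @description
#' Skewed self-report distributions let a majority-class predictor look
#' deceptively good under plain accuracy or mean absolute error. The metrics
#' here give every class equal weight: macro-averaged MAE for ordinal
#' predictions, balanced accuracy for binary ones, and a scale-normalized
#' balanced error that puts both tasks on a common 0-1 scale.
#' @name metrics
NULL

check_paired <- function(truth, pred) {
  if (length(truth) == 0L) stop("empty label vector")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
}

#' Mean absolute error
#' @param truth,pred Equal-length numeric/integer label vectors.
#' @return Numeric scalar.
#' @export
mae <- function(truth, pred) {
  check_paired(truth, pred)
  mean(abs(as.numeric(pred) - as.numeric(truth)))
}

#' Plain accuracy
#' @inheritParams mae
#' @return Fraction of exact matches.
#' @export
accuracy <- function(truth, pred) {
  check_paired(truth, pred)
  mean(truth == pred)
}

#' Per-class mean absolute error
#'
#' MAE computed separately within each true class present in `truth`.
#'
#' @inheritParams mae
#' @return Named numeric vector, one entry per class present in `truth`.
#' @export
per_class_mae <- function(truth, pred) {
  check_paired(truth, pred)
  err <- abs(as.numeric(pred) - as.numeric(truth))
  vapply(split(err, truth), mean, numeric(1))
}

#' Macro-averaged mean absolute error (MAMAE)
#'
#' Computes the MAE per true class, then averages the per-class values with
#' equal weight, so rare classes count as much as the majority class. Classes
#' absent from `truth` are excluded from the average (avoiding 0/0, as in
#' usual macro-metric conventions).
#'
#' @inheritParams mae
#' @return Numeric scalar.
#' @export
#' @examples
#' mamae(c(0, 0, 3), c(0, 1, 1))  # mean(0.5, 2) = 1.25
mamae <- function(truth, pred) {
  mean(per_class_mae(truth, pred))
}

#' Balanced accuracy (BAcc)
#'
#' The arithmetic mean of sensitivity (true positive rate) and specificity
#' (true negative rate). Requires both classes present in `truth`; the
#' positive class is 1.
#'
#' @param truth,pred Equal-length binary vectors in `{0,1}`.
#' @return Numeric scalar in `[0,1]`.
#' @export
bacc <- function(truth, pred) {
  check_paired(truth, pred)
  if (length(unique(truth)) < 2L)
    stop("bacc undefined: a class is absent from truth")
  tpr <- mean(pred[truth == 1] == 1)
  tnr <- mean(pred[truth == 0] == 0)
  (tpr + tnr) / 2
}

#' Scale-normalized balanced error
#'
#' Maps ordinal and binary performance onto a common `[0,1]` scale where 0 is
#' perfect and 1 is maximally wrong. For a binary task this is `1 - BAcc`.
#' For an ordinal task each per-class MAE is divided by the largest absolute
#' error achievable for that true class, `max(c - min, max - c)` on the label
#' scale, and the normalized values are averaged over classes present in the
#' truth with equal weight.
#'
#' @inheritParams mae
#' @param task `"ordinal"` or `"binary"`.
#' @param label_range Inclusive ordinal label range, default `c(0, 3)`.
#' @return Numeric scalar in `[0,1]`.
#' @export
scale_normalized_balanced_error <- function(truth, pred,
                                            task = c("ordinal", "binary"),
                                            label_range = c(0, 3)) {
  task <- match.arg(task)
  if (task == "binary") return(1 - bacc(truth, pred))
  pc <- per_class_mae(truth, pred)
  cls <- as.numeric(names(pc))
  worst <- pmax(cls - label_range[1], label_range[2] - cls)
  if (any(worst == 0))
    stop("degenerate single-point label scale: worst-case error is 0")
  mean(pc / worst)
}

#' Full metric report for one prediction set
#'
#' @inheritParams scale_normalized_balanced_error
#' @return A list with `mae`, `acc`, `n_per_class`, and, per task, `mamae`,
#'   `per_class_mae`, `nbe` (ordinal) or `bacc`, `per_class_recall`, `nbe`
#'   (binary).
#' @export
metric_report <- function(truth, pred, task = c("ordinal", "binary"),
                          label_range = c(0, 3)) {
  task <- match.arg(task)
  rep <- list(task = task,
              mae = mae(truth, pred),
              acc = accuracy(truth, pred),
              n_per_class = table(truth))
  if (task == "ordinal") {
    rep$per_class_mae <- per_class_mae(truth, pred)
    rep$mamae <- mean(rep$per_class_mae)
    rep$nbe <- scale_normalized_balanced_error(truth, pred, "ordinal", label_range)
  } else {
    rep$bacc <- bacc(truth, pred)
    rep$per_class_recall <- vapply(split(pred == truth, truth), mean, numeric(1))
    rep$nbe <- 1 - rep$bacc
  }
  rep
}

#' Confusion matrix in true-class columns
#'
#' Counts of predictions (rows) against true classes (columns) over the full
#' admissible label set, so raw values for any metric can be recovered.
#'
#' @inheritParams mae
#' @param levels Admissible label values, default `0:3`.
#' @return Integer matrix, predictions in rows, truth in columns.
#' @export
confusion_counts <- function(truth, pred, levels = 0:3) {
  check_paired(truth, pred)
  table(predicted = factor(pred, levels = levels),
        true = factor(truth, levels = levels))
}
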
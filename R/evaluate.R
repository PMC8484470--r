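## Segmentation metrics (pixel precision / sensitivity / DSC) and
## classification metrics (per-class one-vs-rest precision / sensitivity /
## F1, overall accuracy, confusion matrix).

#' Pixel-level segmentation metrics
#'
#' \code{precision = TP/(TP+FP)}, \code{sensitivity = TP/(TP+FN)},
#' \code{DSC = 2 TP / ((TP+FP) + (TP+FN))}. Empty-mask conventions: a
#' metric is 1 when both masks are empty (perfect agreement on nothing)
#' and 0 when only its denominator is empty.
#'
#' @param pred,truth logical matrices of one shape.
#' @return named numeric: precision, sensitivity, dsc, and the raw
#'   TP/FP/FN/TN counts.
#' @export
segmentationMetrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("invalid input: masks differ in shape", call. = FALSE)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  ratio <- function(num, den) {
    if (den == 0) (if (tp + fp + fn == 0) 1 else 0) else num / den
  }
  c(precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    dsc = ratio(2 * tp, (tp + fp) + (tp + fn)),
    TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Multi-class classification report
#'
#' One-vs-rest counts per class give precision, sensitivity and
#' \code{F1 = 2 P S / (P + S)} (0 when P + S = 0); accuracy is the trace
#' of the confusion matrix over the sample count.
#'
#' @param pred,truth label vectors of equal length.
#' @param classes the admissible labels; any label outside this set is an
#'   error.
#' @return list with \code{confusion} (truth in rows, prediction in
#'   columns), \code{perClass} (data.frame: precision, sensitivity, f1,
#'   support), and \code{accuracy}.
#' @export
classificationReport <- function(pred, truth, classes = sort(unique(truth))) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("invalid input: label vectors differ in length", call. = FALSE)
  bad <- setdiff(unique(c(pred, truth)), classes)
  if (length(bad))
    stop("invalid input: unseen label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  per <- t(vapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    s <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + s == 0) 0 else 2 * p * s / (p + s)
    c(precision = p, sensitivity = s, f1 = f1, support = tp + fn)
  }, numeric(4)))
  list(confusion = unclass(cm),
       perClass = as.data.frame(per),
       accuracy = sum(diag(cm)) / length(truth))
}

#' Write a classification report as JSON
#'
#' @param report from [classificationReport()].
#' @param path output file.
#' @export
writeClassReport <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              perClass = cbind(class = rownames(report$perClass),
                               report$perClass),
              confusion = as.data.frame.matrix(report$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
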
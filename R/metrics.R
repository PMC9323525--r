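#' Classification performance metrics
#'
#' Sensitivity is the proportion of positive-class samples correctly
#' identified, TP / (TP + FN); specificity the proportion of negative-class
#' samples correctly identified, TN / (TN + FP); the misclassification error
#' the proportion of all samples classified incorrectly,
#' (FP + FN) / (TP + TN + FP + FN).
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return a fraction in [0, 1].
#' @name classificationMetrics
NULL

#' @rdname classificationMetrics
#' @export
sensitivity <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  if (cm@TP + cm@FN < 1L) stop("no positive cases: sensitivity undefined")
  cm@TP / (cm@TP + cm@FN)
}

#' @rdname classificationMetrics
#' @export
specificity <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  if (cm@TN + cm@FP < 1L) stop("no negative cases: specificity undefined")
  cm@TN / (cm@TN + cm@FP)
}

#' @rdname classificationMetrics
#' @export
misclassificationError <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  total <- cm@TP + cm@TN + cm@FP + cm@FN
  if (total < 1L) stop("empty confusion matrix")
  (cm@FP + cm@FN) / total
}
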
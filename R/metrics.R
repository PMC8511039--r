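#' Patchwise accuracy
#'
#' Fraction of patches assigned their correct tissue class.  When `slide` is
#' supplied, per-slide accuracies are computed first and averaged unweighted
#' across slides.
#'
#' @param pred,truth Integer class vectors of equal length.
#' @param slide Optional slide identifier per patch for grouped averaging.
#' @return Proportion in `[0, 1]`.
#' @export
patchwise_accuracy <- function(pred, truth, slide = NULL) {
  if (length(pred) == 0) stop("no patches to score")
  if (length(pred) != length(truth)) stop("prediction and truth lengths differ")
  if (is.null(slide)) return(mean(pred == truth))
  mean(tapply(pred == truth, slide, mean))
}

#' Pixelwise accuracy of a label map
#'
#' Fraction of evaluated pixels whose label matches the ground truth.
#' Background pixels (truth 0) are excluded from the denominator by default,
#' since background sits outside the four-class problem.
#'
#' @param map_pred,map_true Integer label matrices of identical dimensions.
#' @param ignore_background Exclude pixels whose true label is 0.
#' @return Proportion in `[0, 1]`.
#' @export
pixelwise_accuracy <- function(map_pred, map_true, ignore_background = TRUE) {
  if (!identical(dim(map_pred), dim(map_true))) {
    stop("label map dimensions differ")
  }
  keep <- if (ignore_background) map_true != 0L else rep(TRUE, length(map_true))
  if (!any(keep)) stop("no evaluable pixels (all background)")
  mean(map_pred[keep] == map_true[keep])
}

#' Confusion matrix over the four tissue classes
#'
#' Rows are true classes, columns predicted; background is excluded (only
#' positions where both labels are in 1..4 are counted, and the number of
#' discarded positions is reported as an attribute).
#'
#' @param truth,pred Integer label vectors or matrices.
#' @return 4 x 4 count matrix with attribute `n_excluded`.
#' @export
confusion_matrix <- function(truth, pred) {
  t <- as.vector(truth); p <- as.vector(pred)
  if (length(t) != length(p)) stop("truth and prediction lengths differ")
  keep <- t %in% 1:4 & p %in% 1:4
  cm <- table(factor(t[keep], levels = 1:4), factor(p[keep], levels = 1:4))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(true = 1:4, pred = 1:4))
  attr(cm, "n_excluded") <- sum(!keep)
  cm
}

#' Per-class accuracy, sensitivity and specificity
#'
#' One-vs-rest metrics from a confusion matrix: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, accuracy `(TP+TN)/total`.  A class with no true
#' instances has undefined (NA) sensitivity, which macro averages skip.
#'
#' @param cm K x K confusion matrix (rows true, columns predicted).
#' @return List with `per_class` (data frame) and `macro` (named vector of
#'   the averages across classes).
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  res <- lapply(seq_len(K), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    data.frame(
      class = k,
      accuracy = (tp + tn) / total,
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    )
  })
  per_class <- do.call(rbind, res)
  macro <- c(accuracy = mean(per_class$accuracy, na.rm = TRUE),
             sensitivity = mean(per_class$sensitivity, na.rm = TRUE),
             specificity = mean(per_class$specificity, na.rm = TRUE))
  list(per_class = per_class, macro = macro)
}
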
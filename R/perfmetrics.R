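#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples of true class `i` predicted as
#' class `j`.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_order Class labels in reporting order (default P1-P4).
#' @return K x K integer matrix with dimnames `(true, predicted)`.
#' @export
confusion <- function(y_true, y_pred, class_order = patty_categories()) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` lengths differ", call. = FALSE)
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown))
    stop(sprintf("labels outside class order: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  f <- function(x) factor(x, levels = class_order)
  cm <- table(true = f(y_true), predicted = f(y_pred))
  matrix(as.integer(cm), nrow = length(class_order),
         dimnames = list(true = class_order, predicted = class_order))
}

#' One-vs-rest counts for a class
#'
#' Reduces a multiclass confusion matrix to the TP/TN/FP/FN counts of one
#' class against the rest.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param class_k Class label or index.
#' @return Named integer vector `c(TP, FN, FP, TN)`; the four counts sum to
#'   the total sample count.
#' @export
ovr_counts <- function(cm, class_k) {
  k <- if (is.character(class_k)) match(class_k, rownames(cm)) else class_k
  if (is.na(k) || k < 1 || k > nrow(cm))
    stop("`class_k` not in the class order", call. = FALSE)
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Per-class performance measures from one-vs-rest counts
#'
#' The seven standard measures, all in percent:
#' classification accuracy `(TP+TN)/total`, false positive error `FP/total`,
#' false negative error `FN/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and misclassification
#' `(FP+FN)/total`. Two identities hold exactly: accuracy + FP error +
#' FN error = 100 and accuracy + misclassification = 100. Ratios with an
#' empty denominator are reported as `NA`, never as 0 or 100. Values are
#' carried at full precision; rounding to one decimal is a serialization
#' concern only.
#'
#' @param counts Output of [ovr_counts()].
#' @return Named numeric vector of the seven measures (class
#'   `class_metrics`).
#' @export
class_metrics <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  fp <- counts[["FP"]]; tn <- counts[["TN"]]
  total <- tp + fn + fp + tn
  if (total <= 0) stop("empty confusion counts", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- c(
    classification_accuracy = 100 * (tp + tn) / total,
    fp_error = 100 * fp / total,
    fn_error = 100 * fn / total,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    misclassification = 100 * (fp + fn) / total
  )
  class(out) <- c("class_metrics", class(out))
  out
}

#' Unweighted mean of performance-measure sets
#'
#' Field-wise arithmetic mean across a list of [class_metrics()] vectors;
#' used both to average the four classes into an overall row and to average
#' the SNV and SNV+detrend runs per class. Averaging is done at full
#' precision.
#'
#' @param metrics_list Nonempty list of `class_metrics`.
#' @return A `class_metrics` vector of means.
#' @export
macro_mean <- function(metrics_list) {
  if (!length(metrics_list)) stop("empty metrics list", call. = FALSE)
  m <- do.call(rbind, lapply(metrics_list, unclass))
  out <- colMeans(m)
  class(out) <- c("class_metrics", class(out))
  out
}

#' Regulatory acceptance flag
#'
#' The screening convention for this application domain: a model is an
#' acceptable classifier when its accuracy is at least 90%; the bound is
#' inclusive.
#'
#' @param overall_accuracy Accuracy in percent, in `[0, 100]`.
#' @return `"acceptable"` or `"rejected"`.
#' @export
regulation_flag <- function(overall_accuracy) {
  stopifnot(all(overall_accuracy >= 0 & overall_accuracy <= 100))
  ifelse(overall_accuracy >= 90, "acceptable", "rejected")
}

#' Per-class performance table for a validation run
#'
#' Computes the one-vs-rest measures of every class from true/predicted
#' labels, in the conventional column order.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_order Class order.
#' @return data.frame, one row per class plus columns of the seven measures.
#' @export
performance_table <- function(y_true, y_pred,
                              class_order = patty_categories()) {
  cm <- confusion(y_true, y_pred, class_order)
  rows <- lapply(class_order, function(cl)
    as.data.frame(t(unclass(class_metrics(ovr_counts(cm, cl))))))
  out <- do.call(rbind, rows)
  cbind(class = class_order, out)
}
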
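#' Confusion matrix from truth and predicted labels
#'
#' @param truth Vector of true class labels.
#' @param predicted Vector of predicted class labels, same length.
#' @return An object of class `confusion_matrix`: list with `classes`,
#'   `counts` (square matrix, truth rows x predicted columns) and
#'   `n_total`.
#' @examples
#' confusion(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length", call. = FALSE)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  counts <- unclass(matrix(as.integer(counts), nrow = length(classes),
                           dimnames = list(truth = classes,
                                           predicted = classes)))
  structure(list(classes = classes, counts = counts,
                 n_total = length(truth)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d records, %d classes):\n",
              x$n_total, length(x$classes)))
  print(x$counts)
  invisible(x)
}

#' Per-class evaluation metrics (one-vs-rest)
#'
#' Computes the one-vs-rest confusion cells for one class and the derived
#' metrics. Two per-class "accuracy" notions are reported:
#' `threat_score`, the threat score (critical success index)
#' `TP / (TP + FP + FN)` which ignores true negatives, and
#' `accuracy_standard`, `(TP + TN) / n`. The threat score is the quantity
#' that per-class accuracy columns in frame-classifier evaluation tables
#' typically correspond to; the standard definition is kept alongside
#' because the two differ substantially for prevalent classes. NPV is computed through the
#' prevalence identity
#' `spec * (1 - prev) / (spec * (1 - prev) + (1 - recall) * prev)`,
#' algebraically equal to `TN / (TN + FN)` on integer counts. Ratios with
#' zero denominators are returned as `NaN` and flagged in `undefined`.
#'
#' @param m A `confusion_matrix`.
#' @param cls A class label present in `m$classes`.
#' @return An object of class `class_metrics`: list with `tp`, `fp`, `fn`,
#'   `tn`, `threat_score`, `accuracy_standard`, `precision`, `recall`,
#'   `specificity`, `npv`, `prevalence`, `balanced_accuracy`, `f1`,
#'   `undefined` (character vector of metrics with zero denominators).
#' @examples
#' m <- confusion(rep(c("krill", "water"), c(26, 74)),
#'                rep(c("krill", "water", "krill", "water"),
#'                    c(16, 10, 5, 69)))
#' class_metrics(m, "krill")
#' @export
class_metrics <- function(m, cls) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!(cls %in% m$classes)) stop("unknown class: ", cls, call. = FALSE)
  i <- match(cls, m$classes)
  tp <- m$counts[i, i]
  fp <- sum(m$counts[-i, i])
  fn <- sum(m$counts[i, -i])
  tn <- m$n_total - tp - fp - fn
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NaN) }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  specificity <- ratio(tn, tn + fp, "specificity")
  prevalence <- ratio(tp + fn, m$n_total, "prevalence")
  threat_score <- ratio(tp, tp + fp + fn, "threat_score")
  accuracy_standard <- ratio(tp + tn, m$n_total, "accuracy_standard")
  npv_den <- specificity * (1 - prevalence) + (1 - recall) * prevalence
  npv <- if (!is.finite(npv_den) || npv_den == 0) {
    undefined <- c(undefined, "npv"); NaN
  } else specificity * (1 - prevalence) / npv_den
  f1_den <- precision + recall
  f1 <- if (!is.finite(f1_den) || f1_den == 0) {
    undefined <- c(undefined, "f1"); NaN
  } else 2 * precision * recall / f1_den
  structure(list(
    class = cls, tp = tp, fp = fp, fn = fn, tn = tn,
    threat_score = threat_score,
    accuracy_standard = accuracy_standard,
    precision = precision, recall = recall, specificity = specificity,
    npv = npv, prevalence = prevalence,
    balanced_accuracy = (recall + specificity) / 2,
    f1 = f1, undefined = undefined),
    class = "class_metrics")
}

#' Per-class metrics from printed rates
#'
#' Reconstructs the per-class metrics implied by published recall,
#' precision, specificity and prevalence at a given evaluation size,
#' without access to the underlying counts: implied (real-valued) cells
#' are `TP = recall * prevalence * n`, `FP = TP * (1 - precision) /
#' precision`, `FN = prevalence * n - TP`, `TN = n - TP - FP - FN`.
#' Useful for checking the internal consistency of reported metric tables.
#'
#' @param recall,precision,specificity,prevalence Printed rates in `[0, 1]`.
#' @param n Evaluation set size.
#' @return A list with the implied cells and derived `f1`, `npv`,
#'   `balanced_accuracy`, `threat_score`.
#' @examples
#' class_metrics_from_rates(recall = 0.63, precision = 0.83,
#'                          specificity = 0.95, prevalence = 0.26, n = 1000)
#' @export
class_metrics_from_rates <- function(recall, precision, specificity,
                                     prevalence, n = 1000) {
  stopifnot(recall >= 0, recall <= 1, precision > 0, precision <= 1,
            specificity >= 0, specificity <= 1,
            prevalence > 0, prevalence < 1, n > 0)
  tp <- recall * prevalence * n
  fn <- prevalence * n - tp
  fp <- tp * (1 - precision) / precision
  tn <- n - tp - fn - fp
  npv_den <- specificity * (1 - prevalence) + (1 - recall) * prevalence
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       f1 = 2 * precision * recall / (precision + recall),
       npv = specificity * (1 - prevalence) / npv_den,
       balanced_accuracy = (recall + specificity) / 2,
       threat_score = tp / (tp + fp + fn))
}

#' Overall accuracy of a confusion matrix
#'
#' @param m A `confusion_matrix`.
#' @return Proportion of records on the diagonal (trace / n).
#' @export
overall_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$n_total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(m$counts)) / m$n_total
}

#' Full classification report
#'
#' One row per class in published evaluation-table layout, plus overall
#' accuracy as an attribute.
#'
#' @param truth,predicted Label vectors (see [confusion()]).
#' @return A data frame with one row per class and columns
#'   `class, accuracy, recall, specificity, precision, npv, prevalence,
#'   balanced_accuracy, f1` (where `accuracy` is the threat score), with
#'   attribute `overall_accuracy`.
#' @export
classification_report <- function(truth, predicted) {
  m <- confusion(truth, predicted)
  rows <- lapply(m$classes, function(cls) {
    cm <- class_metrics(m, cls)
    data.frame(class = cls, accuracy = cm$threat_score,
               recall = cm$recall, specificity = cm$specificity,
               precision = cm$precision, npv = cm$npv,
               prevalence = cm$prevalence,
               balanced_accuracy = cm$balanced_accuracy, f1 = cm$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_accuracy") <- overall_accuracy(m)
  out
}
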
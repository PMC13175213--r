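# Multiclass evaluation: confusion matrices, per-class precision / recall /
# F1, macro-averaged F1 (arithmetic mean of class-wise F1), overall
# accuracy, the four-to-two class collapse, and multi-trial mean/SD
# summaries. Zero-denominator cases (a class never predicted and/or never
# present) are defined as 0, a conservative convention.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted as
#' class `j`.
#'
#' @param y_true,y_pred Integer class indices in `1..k`.
#' @param k Number of classes.
#' @param labels Optional class labels for dimnames (length `k`).
#' @return A `col6_confusion` integer matrix with true classes in rows.
#' @export
confusion_matrix <- function(y_true, y_pred, k = 4L, labels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (any(c(y_true, y_pred) < 1) || any(c(y_true, y_pred) > k)) {
    stop("class indices out of range 1..", k, call. = FALSE)
  }
  cm <- matrix(0L, k, k)
  for (t in seq_along(y_true)) {
    cm[y_true[t], y_pred[t]] <- cm[y_true[t], y_pred[t]] + 1L
  }
  if (!is.null(labels)) dimnames(cm) <- list(true = labels, pred = labels)
  structure(cm, class = c("col6_confusion", "matrix", "array"))
}

#' Per-class precision, recall and F1
#'
#' For class c: precision = TP / (TP + FP), recall = TP / (TP + FN), and F1
#' is their harmonic mean. Any zero denominator yields 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with columns `class`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm) {
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  cls <- if (!is.null(dimnames(cm))) rownames(cm) else as.character(1:k)
  tibble::tibble(class = cls, precision = unname(precision),
                 recall = unname(recall), f1 = unname(f1))
}

#' Macro-averaged F1
#'
#' Arithmetic mean of the class-wise F1 scores.
#'
#' @param per_class_f1 Numeric vector of per-class F1 values.
#' @return A single number in [0, 1].
#' @export
macro_f1 <- function(per_class_f1) {
  if (length(per_class_f1) == 0) {
    stop("macro_f1 of an empty vector is undefined", call. = FALSE)
  }
  mean(per_class_f1)
}

#' Overall accuracy
#'
#' Fraction of samples whose predicted class equals the true class.
#'
#' @param y_true,y_pred Equal-length class index vectors.
#' @return A single number in [0, 1].
#' @export
accuracy_score <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("accuracy of zero samples is undefined",
                                call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  mean(y_true == y_pred)
}

#' Collapse the four-class labels to binary
#'
#' Control maps to the negative class (0); the three pathogenic-mechanism
#' classes (glycine substitution, pseudoexon insertion, exon skipping) pool
#' into the positive class (1).
#'
#' @param y Integer class indices in 1..4.
#' @return Integer vector of 0 (control) / 1 (pathogenic).
#' @export
binarize_labels <- function(y) {
  if (any(y < 1 | y > 4)) stop("class indices out of range 1..4",
                               call. = FALSE)
  as.integer(y != 1L)
}

#' Full evaluation report
#'
#' Confusion matrix plus per-class precision/recall/F1, macro-F1 and
#' accuracy for one model's predictions on one test set.
#'
#' @param y_true,y_pred Integer class indices in 1..k.
#' @param k Number of classes.
#' @param labels Optional class labels.
#' @return A `col6_report` object.
#' @export
evaluation_report <- function(y_true, y_pred, k = 4L,
                              labels = class_labels()[seq_len(k)]) {
  cm <- confusion_matrix(y_true, y_pred, k = k, labels = labels)
  pc <- precision_recall_f1(cm)
  structure(list(confusion = cm, per_class = pc,
                 macro_f1 = macro_f1(pc$f1),
                 accuracy = accuracy_score(y_true, y_pred),
                 n = length(y_true)),
            class = "col6_report")
}

#' @export
print.col6_report <- function(x, ...) {
  cat("<col6_report> n = ", x$n, ", macro-F1 = ", round(x$macro_f1, 3),
      ", accuracy = ", round(x$accuracy, 3), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.col6_report <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.col6_report <- function(x, ...) {
  tibble::tibble(macro_f1 = x$macro_f1, accuracy = x$accuracy, n = x$n)
}

#' Mean and SD over repeated trials
#'
#' Summarizes macro-F1 and accuracy over a list of evaluation reports with
#' the arithmetic mean and the sample (n - 1) standard deviation.
#'
#' @param reports List of [evaluation_report()] objects.
#' @return One-row tibble: `n_trials`, `mean_f1`, `std_f1`,
#'   `mean_accuracy`, `std_accuracy`.
#' @export
summarize_trials <- function(reports) {
  if (length(reports) < 2) {
    stop("need at least 2 reports for a mean/SD summary", call. = FALSE)
  }
  f1 <- vapply(reports, `[[`, numeric(1), "macro_f1")
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  tibble::tibble(n_trials = length(reports),
                 mean_f1 = mean(f1), std_f1 = stats::sd(f1),
                 mean_accuracy = mean(acc), std_accuracy = stats::sd(acc))
}
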
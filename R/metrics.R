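#' Multi-class confusion matrix
#'
#' `counts[i, j]` is the number of samples with true stage `i` predicted as
#' stage `j`.
#'
#' @param y_true,y_pred integer stage vectors (values in `1..n_classes`),
#'   equal length >= 1.
#' @param n_classes number of classes (default 8).
#' @return an `n_classes x n_classes` integer matrix of class
#'   `pd_confusion`.
#' @export
confusion <- function(y_true, y_pred, n_classes = 8L) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred differ in length (%d vs %d)",
          length(y_true), length(y_pred))
  if (length(y_true) == 0L) stopf("need at least one sample")
  if (!all(y_true %in% seq_len(n_classes)) || !all(y_pred %in% seq_len(n_classes)))
    stopf("stages must be integers in 1..%d", n_classes)
  cm <- table(factor(y_true, levels = seq_len(n_classes)),
              factor(y_pred, levels = seq_len(n_classes)))
  structure(matrix(as.integer(cm), n_classes, n_classes,
                   dimnames = list(true = seq_len(n_classes),
                                   pred = seq_len(n_classes))),
            class = c("pd_confusion", "matrix"))
}

#' Overall accuracy from a confusion matrix
#'
#' The multi-class generalization of the binary (TP+TN)/(all) form:
#' `trace(cm) / n`.
#'
#' @param cm a confusion matrix.
#' @return accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) stopf("empty confusion matrix")
  sum(diag(cm)) / n
}

#' Per-class precision, recall and F1 with macro/micro averages
#'
#' `precision_i = TP_i / (TP_i + FP_i)`, `recall_i = TP_i / (TP_i + FN_i)`,
#' `F1_i` their harmonic mean. Classes with zero denominator score 0 (with a
#' warning); classes that are never true and never predicted are excluded
#' from the macro mean (and flagged in `macro_excluded`).
#'
#' @param cm a confusion matrix.
#' @return a list with `precision`, `recall`, `f1` (per-class vectors),
#'   `macro_f1`, `micro_f1`, and `macro_excluded` (logical per class).
#' @export
f1_scores <- function(cm) {
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  safe_div <- function(a, b, what) {
    out <- ifelse(b > 0, a / b, 0)
    if (any(b == 0 & (rowSums(cm) + colSums(cm)) > 0))
      warning(sprintf("zero denominator in %s for class(es) %s; scored 0", what,
                      paste(which(b == 0 & (rowSums(cm) + colSums(cm)) > 0),
                            collapse = ",")), call. = FALSE)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  absent <- (rowSums(cm) + colSums(cm)) == 0
  list(precision = precision, recall = recall, f1 = f1,
       macro_f1 = mean(f1[!absent]),
       micro_f1 = sum(tp) / sum(cm),
       macro_excluded = absent)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p0 - pe) / (1 - pe)` with `p0` the overall
#' accuracy and `pe = sum_k row_k * col_k / n^2` the marginal-product chance
#' agreement (the multi-class form; the binary TP/TN expression is its N=2
#' special case).
#'
#' @param cm a confusion matrix.
#' @return kappa in `[-1, 1]`.
#' @export
kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stopf("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) stopf("kappa undefined: chance agreement is 1")
  (p0 - pe) / (1 - pe)
}

#' Ordinal mean absolute error
#'
#' Mean absolute difference between predicted and true stage indices on the
#' ordinal 1..8 scale; distant-stage confusions are penalized more than
#' adjacent ones.
#'
#' @param y_true,y_pred integer stage vectors.
#' @return MAE >= 0.
#' @export
ordinal_mae <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred differ in length")
  mean(abs(as.numeric(y_pred) - as.numeric(y_true)))
}

#' Full metric report
#'
#' Bundles the confusion matrix with overall accuracy, per-class
#' precision/recall/F1, macro and micro F1, Cohen's kappa and ordinal MAE.
#'
#' @param y_true,y_pred integer stage vectors.
#' @param n_classes number of classes (default 8).
#' @return an object of class `pd_metric_report`.
#' @export
metric_report <- function(y_true, y_pred, n_classes = 8L) {
  cm <- confusion(y_true, y_pred, n_classes)
  f <- suppressWarnings(f1_scores(cm))
  structure(list(OA = overall_accuracy(cm), precision = f$precision,
                 recall = f$recall, f1 = f$f1, macro_f1 = f$macro_f1,
                 micro_f1 = f$micro_f1, kappa = kappa(cm),
                 MAE = ordinal_mae(y_true, y_pred), matrix = cm,
                 n = length(y_true)),
            class = "pd_metric_report")
}

#' @export
print.pd_metric_report <- function(x, ...) {
  cat(sprintf("OA %.4f | macro F1 %.4f | kappa %.4f | MAE %.4f (n = %d)\n",
              x$OA, x$macro_f1, x$kappa, x$MAE, x$n))
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' @param report a `pd_metric_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  obj <- list(OA = report$OA, precision = report$precision,
              recall = report$recall, f1 = report$f1,
              macro_f1 = report$macro_f1, micro_f1 = report$micro_f1,
              kappa = report$kappa, MAE = report$MAE, n = report$n,
              confusion = unclass(report$matrix))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a confusion matrix as CSV with stage-name headers
#'
#' @param cm a confusion matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm))
  df <- as.data.frame(m)
  names(df) <- stage_names()[seq_len(ncol(m))]
  df <- cbind(stage = stage_names()[seq_len(nrow(m))], df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
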
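# Multi-class evaluation: confusion matrix, accuracy, precision, recall,
# F1 and average confidence score, with macro or support-weighted averaging.

#' Confusion matrix over a fixed vocabulary
#'
#' @param true_labels,predicted_labels Character vectors of equal length;
#'   every label must belong to `classes`.
#' @param classes Ordered class vocabulary (K >= 2 distinct names).
#' @return K x K integer matrix, rows = true class, columns = predicted
#'   class, in vocabulary order.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, classes) {
  classes <- as.character(classes)
  if (length(classes) < 2L || anyDuplicated(classes)) {
    stopf("`classes` must hold >= 2 distinct names")
  }
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors differ in length (%d vs %d)",
          length(true_labels), length(predicted_labels))
  }
  bad_t <- which(!true_labels %in% classes)
  if (length(bad_t) > 0L) {
    stopf("unknown true label '%s' at sample %d", true_labels[bad_t[1L]], bad_t[1L])
  }
  bad_p <- which(!predicted_labels %in% classes)
  if (length(bad_p) > 0L) {
    stopf("unknown predicted label '%s' at sample %d",
          predicted_labels[bad_p[1L]], bad_p[1L])
  }
  cm <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class one-vs-rest counts from a confusion matrix
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return `data.frame` with columns `class`, `TP`, `FP`, `FN`, `TN`,
#'   `support`; each row satisfies TP + FP + FN + TN = N.
#' @export
class_counts <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  data.frame(class = rownames(cm), TP = as.integer(tp), FP = as.integer(fp),
             FN = as.integer(fn), TN = as.integer(tn),
             support = as.integer(rowSums(cm)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall accuracy
#'
#' The ratio of correctly classified samples to the total,
#' `sum(diag(cm)) / sum(cm)`.
#'
#' @param cm A confusion matrix.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  n <- sum(cm)
  if (n < 1) stopf("confusion matrix is empty")
  sum(diag(cm)) / n
}

avg_per_class <- function(values, support, mode) {
  if (mode == "macro") mean(values) else sum(values * support) / sum(support)
}

per_class_safe <- function(num, den) {
  # zero-denominator classes contribute 0 (flagged upstream), not NaN
  ifelse(den > 0, num / den, 0)
}

#' Aggregate precision
#'
#' Per class, TP / (TP + FP); aggregated as the unweighted mean (`macro`)
#' or the support-weighted mean (`weighted`). Classes predicted for no
#' sample have an undefined ratio and contribute 0.
#'
#' @param cm A confusion matrix.
#' @param mode `"macro"` (default) or `"weighted"`.
#' @return Aggregate precision in \[0, 1\].
#' @export
precision <- function(cm, mode = c("macro", "weighted")) {
  mode <- match.arg(mode)
  cc <- class_counts(cm)
  avg_per_class(per_class_safe(cc$TP, cc$TP + cc$FP), cc$support, mode)
}

#' Aggregate recall
#'
#' Per class, TP / (TP + FN); aggregation as in [precision()]. Classes with
#' no true samples contribute 0.
#'
#' @inheritParams precision
#' @return Aggregate recall in \[0, 1\].
#' @export
recall <- function(cm, mode = c("macro", "weighted")) {
  mode <- match.arg(mode)
  cc <- class_counts(cm)
  avg_per_class(per_class_safe(cc$TP, cc$TP + cc$FN), cc$support, mode)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2 P R / (P + R)`; defined as 0
#' when `P + R == 0`.
#'
#' @param p,r Precision and recall, each >= 0.
#' @return F1 in \[0, 1\] for inputs in \[0, 1\].
#' @examples
#' f1(0.8, 0.6)
#' @export
f1 <- function(p, r) {
  if (any(c(p, r) < 0)) stopf("precision and recall must be non-negative")
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Average confidence score
#'
#' The mean probability a classifier assigns to its predicted class, over
#' all samples.
#'
#' @param confidences Numeric vector of per-sample confidences in (0, 1\].
#' @return Mean confidence.
#' @export
acs <- function(confidences) {
  if (length(confidences) < 1L) stopf("need at least one confidence")
  if (any(!is.finite(confidences)) || any(confidences <= 0) ||
      any(confidences > 1)) {
    stopf("confidences must lie in (0, 1]")
  }
  mean(confidences)
}

#' Full metric report for a scored prediction set
#'
#' Assembles accuracy, aggregate precision and recall, the F1 score (the
#' harmonic mean of the aggregate precision and recall), and the average
#' confidence score, together with a per-class one-vs-rest table and the
#' confusion matrix. Metrics are kept at full precision; percentage
#' formatting (2 decimals) happens only in `print()`.
#'
#' @param true_labels Character vector of true labels.
#' @param predicted_labels Character vector of predicted labels.
#' @param confidences Optional per-sample confidences for the ACS; when
#'   omitted the report's `ACS` is `NA`.
#' @param classes Ordered vocabulary; defaults to the sorted union of the
#'   labels.
#' @param mode Aggregation of per-class precision/recall: `"macro"`
#'   (default) or `"weighted"`.
#' @return An object of class `metric_report`: list with `metrics` (named
#'   vector A, P, R, FS, ACS), `per_class`, `confusion_matrix`, `mode`, and
#'   `zero_denominator` (classes whose precision or recall ratio was
#'   undefined and contributed 0).
#' @export
metric_report <- function(true_labels, predicted_labels, confidences = NULL,
                          classes = NULL, mode = c("macro", "weighted")) {
  mode <- match.arg(mode)
  if (is.null(true_labels) || length(true_labels) == 0L) {
    stopf("true labels are required for a metric report")
  }
  if (is.null(classes)) classes <- sort(unique(c(true_labels, predicted_labels)))
  cm <- confusion_matrix(true_labels, predicted_labels, classes)
  cc <- class_counts(cm)
  pc_p <- per_class_safe(cc$TP, cc$TP + cc$FP)
  pc_r <- per_class_safe(cc$TP, cc$TP + cc$FN)
  pc_f <- mapply(f1, pc_p, pc_r)
  per_class <- data.frame(cc, precision = pc_p, recall = pc_r, f1 = pc_f,
                          stringsAsFactors = FALSE)
  p <- avg_per_class(pc_p, cc$support, mode)
  r <- avg_per_class(pc_r, cc$support, mode)
  metrics <- c(A = accuracy(cm), P = p, R = r, FS = f1(p, r),
               ACS = if (is.null(confidences)) NA_real_ else acs(confidences))
  zero <- cc$class[(cc$TP + cc$FP) == 0 | (cc$TP + cc$FN) == 0]
  structure(list(metrics = metrics, per_class = per_class,
                 confusion_matrix = cm, mode = mode,
                 zero_denominator = zero),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (%s averaging, N = %d)\n",
              x$mode, sum(x$confusion_matrix)))
  m <- x$metrics
  for (nm in names(m)) {
    cat(sprintf("  %-3s %s\n", nm,
                if (is.na(m[[nm]])) "NA" else sprintf("%.2f%%", 100 * m[[nm]])))
  }
  if (length(x$zero_denominator) > 0L) {
    cat("  zero-denominator classes:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metric report as JSON
#'
#' Schema: `metrics` (A, P, R, FS, ACS as fractions), `per_class`,
#' `confusion_matrix`, `mode`, `zero_denominator`.
#'
#' @param report A [metric_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  doc <- list(
    metrics = as.list(report$metrics),
    mode = report$mode,
    per_class = report$per_class,
    confusion_matrix = list(
      classes = rownames(report$confusion_matrix),
      counts = unname(apply(report$confusion_matrix, 1L, as.list))
    ),
    zero_denominator = report$zero_denominator
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
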
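# Confusion-matrix metrics and ROC/AUC.
#
# The positive class throughout is good-quality sleep. Metrics with a zero
# denominator are reported as NA (undefined), never as 0.

normalize_binary <- function(x) {
  if (is.character(x)) {
    if (!all(x %in% c("good", "poor"))) stop("labels must be 'good'/'poor' or 0/1")
    return(as.integer(x == "good"))
  }
  if (is.logical(x)) return(as.integer(x))
  if (!all(x %in% c(0, 1))) stop("labels must be 'good'/'poor' or 0/1")
  as.integer(x)
}

#' Tabulate a confusion matrix
#'
#' @param labels True labels: `"good"`/`"poor"`, logical, or 0/1 (1 = good,
#'   the positive class).
#' @param predictions Predicted labels, same encodings.
#' @return Object of class `confusion_matrix`: a list with integer `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  y <- normalize_binary(labels)
  p <- normalize_binary(predictions)
  if (length(y) != length(p)) stop("labels and predictions differ in length")
  if (length(y) < 1L) stop("need at least one instance")
  structure(list(tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
                 tn = sum(y == 0 & p == 0), fn = sum(y == 1 & p == 0)),
            class = "confusion_matrix")
}

#' Confusion matrix from explicit cell counts
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cells < 0) || sum(cells) < 1) stop("cell counts must be non-negative and sum to >= 1")
  out <- lapply(cells, as.integer)
  structure(out, class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the proportion of correct predictions of either class;
#' precision is tp/(tp+fp); recall (sensitivity) is tp/(tp+fn); specificity
#' is tn/(tn+fp); F1 is the harmonic mean of precision and recall. Any
#' metric whose denominator is zero is `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `metrics_report`: a list with `accuracy`,
#'   `precision`, `recall_sensitivity`, `specificity`, `f1` and the matrix.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  recall <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(
    accuracy = ratio(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn),
    precision = precision,
    recall_sensitivity = recall,
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    f1 = f1,
    confusion = cm), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cm <- x$confusion
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", cm$tp, cm$fp, cm$tn, cm$fn))
  for (nm in c("accuracy", "precision", "recall_sensitivity", "specificity", "f1", "auc")) {
    if (!is.null(x[[nm]])) cat(sprintf("%-18s %s\n", nm, format(round(x[[nm]], digits), nsmall = digits)))
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct confidence value as a decision threshold to trace
#' the ROC curve from (0,0) to (1,1) and integrates it by the trapezoidal
#' rule. With ties grouped at one threshold, the trapezoidal area equals the
#' rank-statistic definition of AUC — the probability that a randomly chosen
#' positive scores above a randomly chosen negative, ties counted one half.
#'
#' @param labels True labels (1/"good" = positive); both classes required.
#' @param confidences Numeric scores in `[0, 1]` (any real scores work; only
#'   their order matters).
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(labels, confidences) {
  y <- normalize_binary(labels)
  stopifnot(length(y) == length(confidences))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present to compute a ROC curve")
  ord <- order(confidences, decreasing = TRUE)
  y <- y[ord]; s <- confidences[ord]
  # group ties: one ROC vertex per distinct score
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                    threshold = c(Inf, s[last_of_group]))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full metrics report from labels and confidences
#'
#' Thresholds confidences at `threshold` for the confusion-matrix metrics and
#' adds the threshold-free ROC/AUC.
#'
#' @param labels True labels (1/"good" = positive).
#' @param confidences Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold for the hard label (default 0.5).
#' @return A `metrics_report` with `auc` and `roc` fields added.
#' @export
evaluate_predictions <- function(labels, confidences, threshold = 0.5) {
  cm <- confusion(labels, as.integer(confidences >= threshold))
  rep <- metrics_from_confusion(cm)
  ra <- roc_auc(labels, confidences)
  rep$auc <- ra$auc
  rep$roc <- ra$roc
  rep
}

#' Reconstruct the confusion matrix implied by printed sensitivity/specificity
#'
#' Published evaluations often report only rounded metrics. Over a test set
#' of known class sizes, the integer cell counts are nevertheless uniquely
#' recoverable: tp is the unique integer in `0..n_pos` whose ratio rounds to
#' the printed sensitivity, and tn likewise from specificity. Errors if no
#' cell count or more than one is consistent at the given tolerance.
#'
#' @param sensitivity,specificity Printed (rounded) values.
#' @param n_pos,n_neg Numbers of positive and negative test instances.
#' @param tol Matching tolerance (default `5e-4`, i.e. agreement at 4
#'   decimal places; printed 3-decimal values still match uniquely).
#' @return A `confusion_matrix`.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg,
                                  tol = 5e-4) {
  pick <- function(target, n, what) {
    k <- which(abs(seq(0L, n) / n - target) <= tol) - 1L
    if (length(k) == 0L) stop("no ", what, " count over ", n, " matches ", target)
    if (length(k) > 1L) stop("ambiguous ", what, " count for ", target, " over ", n)
    k
  }
  tp <- pick(sensitivity, n_pos, "true-positive")
  tn <- pick(specificity, n_neg, "true-negative")
  confusion_matrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Write a metrics report and ROC curve to disk
#'
#' @param report A `metrics_report` (from [evaluate_predictions()]).
#' @param json_path Path for the JSON metrics report.
#' @param roc_csv_path Optional path for a `fpr,tpr,threshold` CSV.
#' @return `json_path`, invisibly.
#' @export
write_metrics_report <- function(report, json_path, roc_csv_path = NULL) {
  out <- list(
    confusion = report$confusion[c("tp", "fp", "tn", "fn")],
    accuracy = report$accuracy, precision = report$precision,
    recall_sensitivity = report$recall_sensitivity,
    specificity = report$specificity, f1 = report$f1, auc = report$auc)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(roc_csv_path) && !is.null(report$roc)) {
    utils::write.csv(report$roc[c("fpr", "tpr", "threshold")], roc_csv_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}
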
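normalize_labels <- function(labels) {
  lab <- tolower(as.character(labels))
  lab[lab == "p"] <- "pathogenic"
  lab[lab == "b"] <- "benign"
  if (any(!lab %in% c("pathogenic", "benign")))
    stop("labels must be pathogenic/benign (or P/B)")
  lab
}

#' Confusion counts at a probability threshold
#'
#' A variant is predicted pathogenic when its probability is strictly
#' greater than `threshold`; counts are tallied against the labels
#' (pathogenic = positive class).
#'
#' @param probabilities numeric vector in `[0, 1]`
#' @param labels vector of `pathogenic`/`benign` (or `P`/`B`)
#' @param threshold cutoff in `[0, 1]`
#' @return named integer vector (class `confusion_counts`) with elements
#'   `tp`, `tn`, `fp`, `fn`
#' @export
confusion_at_threshold <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels differ in length")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  lab <- normalize_labels(labels)
  pred_path <- probabilities > threshold
  structure(c(tp = sum(pred_path & lab == "pathogenic"),
              tn = sum(!pred_path & lab == "benign"),
              fp = sum(pred_path & lab == "benign"),
              fn = sum(!pred_path & lab == "pathogenic")),
            class = "confusion_counts")
}

#' Accuracy metrics from confusion counts
#'
#' Standard definitions: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), balanced accuracy = (sensitivity + specificity)/2, accuracy
#' = (TP+TN)/n. A metric whose class is empty is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts a `confusion_counts` vector, or `tp` given with `tn`,
#'   `fp`, `fn`
#' @param tn,fp,fn individual counts when `counts` is the `tp` scalar
#' @return list of class `construct_metrics` with `counts`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `accuracy` and `auc` (`NA` unless
#'   filled by the caller, e.g. [construct_cv()])
#' @examples
#' metrics_from_counts(76, 162, 15, 17)   # BA 0.866, accuracy 0.881
#' @export
metrics_from_counts <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.null(tn)) counts <- c(tp = counts, tn = tn, fp = fp, fn = fn)
  counts <- as.integer(counts[c("tp", "tn", "fp", "fn")])
  names(counts) <- c("tp", "tn", "fp", "fn")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  pos <- counts["tp"] + counts["fn"]; neg <- counts["tn"] + counts["fp"]
  sens <- if (pos > 0) unname(counts["tp"] / pos) else NA_real_
  spec <- if (neg > 0) unname(counts["tn"] / neg) else NA_real_
  structure(list(counts = counts, sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2,
                 accuracy = unname((counts["tp"] + counts["tn"]) / sum(counts)),
                 auc = NA_real_),
            class = "construct_metrics")
}

#' @export
print.construct_metrics <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$counts["tp"], x$counts["tn"],
              x$counts["fp"], x$counts["fn"]))
  cat(sprintf("sensitivity %.3f  specificity %.3f  BA %.3f  accuracy %.3f",
              x$sensitivity, x$specificity, x$balanced_accuracy, x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random pathogenic
#' variant scores above a random benign one, with ties counted half.
#'
#' @inheritParams confusion_at_threshold
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(probabilities, labels) {
  lab <- normalize_labels(labels)
  n1 <- sum(lab == "pathogenic"); n0 <- sum(lab == "benign")
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(probabilities)  # midranks handle ties as half-wins
  (sum(r[lab == "pathogenic"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-conditional score distribution summaries
#'
#' Tukey box-plot statistics of predicted probabilities per class:
#' five-number summary (quartiles by the linear-interpolation convention,
#' `quantile` type 7), inner and outer fences at 1.5 and 3 IQR, and the
#' values flagged as mild (strictly beyond the inner fence, within the
#' outer) or extreme (strictly beyond the outer fence) outliers. This is
#' the summary used to read off a reporting threshold separating the bulk
#' of pathogenic from the bulk of benign predictions.
#'
#' @inheritParams confusion_at_threshold
#' @return list of class `score_distribution`, one element per class, each
#'   with `n`, `min`, `q1`, `median`, `q3`, `max`, `iqr`, fence positions,
#'   `mild_outliers` and `extreme_outliers`
#' @export
class_score_distribution <- function(probabilities, labels) {
  lab <- normalize_labels(labels)
  out <- lapply(split(probabilities, lab), function(v) {
    q <- unname(stats::quantile(v, c(.25, .5, .75), type = 7))
    iqr <- q[3] - q[1]
    inner <- c(q[1] - 1.5 * iqr, q[3] + 1.5 * iqr)
    outer <- c(q[1] - 3 * iqr, q[3] + 3 * iqr)
    beyond_inner <- v < inner[1] | v > inner[2]
    beyond_outer <- v < outer[1] | v > outer[2]
    list(n = length(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3],
         max = max(v), iqr = iqr,
         lower_inner_fence = inner[1], upper_inner_fence = inner[2],
         lower_outer_fence = outer[1], upper_outer_fence = outer[2],
         mild_outliers = sort(v[beyond_inner & !beyond_outer]),
         extreme_outliers = sort(v[beyond_outer]))
  })
  structure(out, class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  for (cls in names(x)) {
    s <- x[[cls]]
    cat(sprintf("%s (n = %d): min %.3f  Q1 %.3f  median %.3f  Q3 %.3f  max %.3f\n",
                cls, s$n, s$min, s$q1, s$median, s$q3, s$max))
    cat(sprintf("  outliers: %d mild, %d extreme\n",
                length(s$mild_outliers), length(s$extreme_outliers)))
  }
  invisible(x)
}

#' Threshold sweep report
#'
#' For each candidate threshold, tabulates the confusion counts, the number
#' of variants predicted pathogenic, and the false-positive share among
#' them (`100 * FP / (TP + FP)`, in percent; `NA` when nothing is
#' predicted pathogenic). Used to choose a high-confidence reporting
#' threshold, e.g. a cutoff at which false positives are a small share of
#' the positive calls.
#'
#' @inheritParams confusion_at_threshold
#' @param thresholds numeric vector of cutoffs in `[0, 1]`
#' @return data frame of class `threshold_sweep` with columns `threshold`,
#'   `tp`, `tn`, `fp`, `fn`, `n_predicted_positive`, `fp_share_pct`
#' @export
threshold_report <- function(probabilities, labels, thresholds) {
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must be in [0, 1]")
  rows <- lapply(thresholds, function(t) {
    cc <- confusion_at_threshold(probabilities, labels, t)
    npos <- unname(cc["tp"] + cc["fp"])
    data.frame(threshold = t, tp = cc[["tp"]], tn = cc[["tn"]],
               fp = cc[["fp"]], fn = cc[["fn"]],
               n_predicted_positive = npos,
               fp_share_pct = if (npos > 0) 100 * cc[["fp"]] / npos
               else NA_real_)
  })
  structure(do.call(rbind, rows),
            class = c("threshold_sweep", "data.frame"))
}
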
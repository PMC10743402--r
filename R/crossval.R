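#' Position-ordered fold assignment
#'
#' Assigns cross-validation folds by the rule used to validate ConStruct:
#' variants are sorted by their position in the otoferlin sequence and fold
#' labels `1..k` are assigned cyclically along that order, so every fold
#' samples the whole protein and fold sizes differ by at most one. Ties at
#' the same position are broken by (`ref_aa`, `alt_aa`) lexicographic
#' order, making the assignment deterministic and independent of input row
#' order.
#'
#' @param records variant data frame with `position`, `ref_aa`, `alt_aa`
#' @param k number of folds (default 5)
#' @return integer vector of fold labels aligned with the rows of `records`
#' @examples
#' v <- data.frame(position = 10 * (10:1), ref_aa = "A", alt_aa = "V")
#' assign_position_folds(v)   # cyclic along position order
#' @export
assign_position_folds <- function(records, k = 5L) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0L) stop("no records")
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of records (", n, ")")
  o <- order(records$position, records$ref_aa, records$alt_aa)
  folds <- integer(n)
  folds[o] <- rep_len(seq_len(k), n)
  folds
}

#' Position-ordered k-fold cross-validation of ConStruct
#'
#' Runs the full ConStruct validation loop: folds are assigned with
#' [assign_position_folds()], a model is fitted on each training split and
#' used to predict its held-out fold, so every variant receives exactly one
#' out-of-fold probability from a model that never saw it. Confusion counts
#' and accuracy metrics are computed per fold and pooled over the
#' concatenated out-of-fold predictions (pooled counts sum to `n`); AUC is
#' likewise pooled.
#'
#' @inheritParams construct_fit
#' @param k number of folds (default 5)
#' @param threshold probability cutoff for confusion counts (default 0.5,
#'   strict `>`)
#' @return object of class `construct_cv`: list with `probabilities`
#'   (out-of-fold, aligned with `data` rows), `labels`, `folds`, `pooled`
#'   (a [metrics_from_counts()] report with AUC), `per_fold` (list of
#'   per-fold reports), `threshold` and `hyperparameters`
#' @examples
#' cfg <- simulation_config(n_pathogenic = 25, n_benign = 40, seed = 3)
#' cv <- construct_cv(simulate_training_set(cfg), ntree = 100)
#' cv
#' @export
construct_cv <- function(data, map = otoferlin_annotation(),
                         matrix = blosum80(), k = 5L, ntree = 500,
                         mtry = NULL, nodesize = 1, seed = 17,
                         threshold = 0.5) {
  data <- as.data.frame(data)
  if (!"label" %in% names(data) ||
      !all(data$label %in% c("pathogenic", "benign")))
    stop("cross-validation needs records labelled pathogenic/benign only")
  folds <- assign_position_folds(data, k)
  features <- encode_features(data, map, matrix)
  labels <- data$label
  probs <- rep(NA_real_, nrow(data))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- construct_fit(features[!test, , drop = FALSE],
                         labels = labels[!test], ntree = ntree, mtry = mtry,
                         nodesize = nodesize, seed = seed + f - 1L)
    probs[test] <- predict(fit, features[test, , drop = FALSE])
    rep_f <- metrics_from_counts(
      confusion_at_threshold(probs[test], labels[test], threshold))
    rep_f$auc <- tryCatch(roc_auc(probs[test], labels[test]),
                          error = function(e) NA_real_)
    per_fold[[f]] <- rep_f
  }
  pooled <- metrics_from_counts(
    confusion_at_threshold(probs, labels, threshold))
  pooled$auc <- roc_auc(probs, labels)
  structure(list(probabilities = probs, labels = labels, folds = folds,
                 pooled = pooled, per_fold = per_fold,
                 threshold = threshold,
                 hyperparameters = list(ntree = ntree, mtry = mtry,
                                        nodesize = nodesize, seed = seed,
                                        k = k)),
            class = "construct_cv")
}

#' @export
print.construct_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("ConStruct %d-fold cross-validation (position-ordered), n = %d\n",
              x$hyperparameters$k, length(x$labels)))
  cat(sprintf("  pooled: TP %d  TN %d  FP %d  FN %d  (threshold %.2f)\n",
              p$counts["tp"], p$counts["tn"], p$counts["fp"], p$counts["fn"],
              x$threshold))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  BA %.3f  accuracy %.3f  AUC %.3f\n",
              p$sensitivity, p$specificity, p$balanced_accuracy, p$accuracy,
              p$auc))
  invisible(x)
}

#' @export
summary.construct_cv <- function(object, ...) {
  print(object)
  ba <- vapply(object$per_fold, `[[`, 0, "balanced_accuracy")
  cat("  per-fold BA:", paste(sprintf("%.3f", ba), collapse = "  "), "\n")
  invisible(object)
}

#' Box plot of out-of-fold score distributions by class
#'
#' Draws the class-conditional distribution of out-of-fold probabilities
#' (Tukey box plots), the display used to calibrate a reporting threshold
#' from the separation between pathogenic and benign scores.
#'
#' @param x a [construct_cv()] object
#' @param ... passed to [graphics::boxplot()]
#' @export
plot.construct_cv <- function(x, ...) {
  graphics::boxplot(x$probabilities ~ factor(x$labels,
                                             c("benign", "pathogenic")),
                    xlab = "class", ylab = "predicted probability",
                    main = "Out-of-fold score distribution", ...)
  invisible(x)
}
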
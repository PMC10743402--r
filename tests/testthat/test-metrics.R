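test_that("confusion counts follow the strict-threshold rule", {
  cc <- confusion_at_threshold(c(0.9, 0.1), c("P", "B"), 0.5)
  expect_equal(unclass(cc), c(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  # at threshold 1.0 nothing is called pathogenic
  cc1 <- confusion_at_threshold(c(1, 1, 0.2), c("P", "B", "B"), 1)
  expect_equal(unname(cc1["tp"] + cc1["fp"]), 0L)
  expect_error(confusion_at_threshold(c(0.5), c("P", "B")), "length")
})

test_that("confusion counts equal a naive per-case loop", {
  set.seed(21)
  prob <- runif(50)
  lab <- sample(c("pathogenic", "benign"), 50, TRUE)
  for (t in c(0, 0.3, 0.5, 0.85, 1)) {
    tp <- tn <- fp <- fn <- 0L
    for (i in 1:50) {
      pred <- prob[i] > t
      if (pred && lab[i] == "pathogenic") tp <- tp + 1L
      else if (!pred && lab[i] == "benign") tn <- tn + 1L
      else if (pred) fp <- fp + 1L else fn <- fn + 1L
    }
    expect_equal(unclass(confusion_at_threshold(prob, lab, t)),
                 c(tp = tp, tn = tn, fp = fp, fn = fn))
  }
})

test_that("metric identities hold and empty classes are undefined", {
  m <- metrics_from_counts(10, 10, 0, 0)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$accuracy, 1)
  m2 <- metrics_from_counts(0, 5, 3, 0)  # no positives at all
  expect_true(is.na(m2$sensitivity))
  expect_true(is.na(m2$balanced_accuracy))
  expect_equal(m2$specificity, 5 / 8)
  # balanced accuracy is invariant to swapping the two per-class rates
  a <- metrics_from_counts(76, 162, 15, 17)
  b <- metrics_from_counts(162, 76, 17, 15)
  expect_equal(a$balanced_accuracy, b$balanced_accuracy)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("AUC matches the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("P", "P", "B", "B")), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c("P", "B"), 5)), 0.5)
  expect_error(roc_auc(runif(5), rep("P", 5)), "both classes")
  set.seed(30)
  prob <- round(runif(30), 1)  # rounding forces ties
  lab <- sample(c("pathogenic", "benign"), 30, TRUE, prob = c(0.4, 0.6))
  pos <- prob[lab == "pathogenic"]; neg <- prob[lab == "benign"]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  expect_equal(roc_auc(prob, lab), wins / (length(pos) * length(neg)))
  # flipping scores and labels leaves AUC unchanged
  expect_equal(roc_auc(1 - prob, ifelse(lab == "pathogenic", "benign",
                                        "pathogenic")),
               roc_auc(prob, lab))
})

test_that("score distributions use strict Tukey fences", {
  d <- class_score_distribution(c(rep(0.5, 4), rep(0.9, 3)),
                                c(rep("B", 4), rep("P", 3)))
  expect_equal(d$benign$iqr, 0)
  expect_equal(length(d$benign$mild_outliers), 0L)
  expect_equal(length(d$benign$extreme_outliers), 0L)
  # a value at exactly Q3 + 1.5 IQR is not an outlier (strict fences):
  # for c(2,2,2,4,4,7)/10 the quartiles are 0.2 and 0.4, so the upper
  # inner fence falls exactly on the maximum value 0.7
  d2 <- class_score_distribution(c(2, 2, 2, 4, 4, 7) / 10, rep("P", 6))
  expect_equal(d2$pathogenic$upper_inner_fence, 0.7)
  expect_equal(length(d2$pathogenic$mild_outliers), 0L)
  # an injected point beyond 3 IQR is flagged extreme
  vals <- c(0.40, 0.42, 0.44, 0.46, 0.48, 0.95)
  d3 <- class_score_distribution(vals, rep("B", 6))
  expect_true(0.95 %in% d3$benign$extreme_outliers)
})

test_that("threshold sweeps are monotone and report FP share", {
  set.seed(33)
  prob <- runif(80)
  lab <- sample(c("pathogenic", "benign"), 80, TRUE)
  sweep <- threshold_report(prob, lab, seq(0, 1, by = 0.05))
  expect_true(all(diff(sweep$tp) <= 0))
  expect_true(all(diff(sweep$fp) <= 0))
  expect_true(all(diff(sweep$n_predicted_positive) <= 0))
  above <- threshold_report(prob, lab, 1)
  expect_equal(above$n_predicted_positive, 0L)
  expect_true(is.na(above$fp_share_pct))
  one <- threshold_report(c(0.9, 0.9, 0.9, 0.9), c("P", "P", "P", "B"), 0.5)
  expect_equal(one$fp_share_pct, 25)
})
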
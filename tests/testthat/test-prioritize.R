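test_that("local rank scores follow the rank/N convention with mean ties", {
  expect_equal(rank_scores_from_raw(c(0.1, 0.5, 0.9)), c(1, 2, 3) / 3)
  expect_equal(rank_scores_from_raw(c(1, 2, 3, 3)), c(1, 2, 3.5, 3.5) / 4)
  expect_equal(rank_scores_from_raw(0.42), 1)
  # orientation: low raw score means damaging for some methods
  expect_equal(rank_scores_from_raw(c(0.01, 0.5, 0.99),
                                    "lower_is_pathogenic"),
               c(3, 2, 1) / 3)
  # missing values pass through; all-missing is an error
  expect_equal(rank_scores_from_raw(c(0.2, NA, 0.8)),
               c(0.5, NA, 1))
  expect_error(rank_scores_from_raw(c(NA, NA)), "all scores")
})

test_that("mean rank score averages non-missing methods", {
  expect_equal(mean_rank_score(data.frame(a = 0.9, b = 1))$mean_rank_score,
               0.95)
  m <- mean_rank_score(data.frame(a = 0.6, b = NA, c = 0.9))
  expect_equal(m$mean_rank_score, 0.75)
  expect_equal(m$n_methods, 2)
  expect_error(mean_rank_score(data.frame(a = NA_real_, b = NA_real_)),
               "no non-missing")
  # mean lies within the range of its inputs
  set.seed(8)
  rs <- matrix(runif(50), 10)
  mm <- mean_rank_score(rs)$mean_rank_score
  expect_true(all(mm >= apply(rs, 1, min) & mm <= apply(rs, 1, max)))
})

test_that("consensus selection applies both criteria conservatively", {
  vus <- data.frame(position = c(10, 20, 30, 40), ref_aa = "A",
                    alt_aa = "V")
  calls <- data.frame(m1 = c("P", "P", "B", "P"),
                      m2 = c("P", "P", "P", NA))
  ranks <- data.frame(m1 = c(0.9, 0.8, 0.7, 0.6),
                      m2 = c(0.95, 0.85, 0.75, 0.65))
  crit <- consensus_criteria(0.85, c("m1", "m2"))
  sel <- consensus_select(vus, c(0.9, 0.5, 0.95, 0.99), calls, ranks, crit)
  # only variant 1 passes: 2 fails the probability, 3 has a B call,
  # 4 has a missing call (blocks under require_all)
  expect_equal(sel$selected[order(sel$position)], c(TRUE, FALSE, FALSE,
                                                    FALSE))
  # strict threshold: probability exactly at 1.0 can never pass t = 1.0
  crit1 <- consensus_criteria(1, c("m1", "m2"))
  sel1 <- consensus_select(vus, rep(1, 4), calls, ranks, crit1)
  expect_false(any(sel1$selected))
  expect_error(consensus_select(vus, c(0.9, NA, 0.9, 0.9), calls, ranks,
                                crit), "missing ConStruct")
})

test_that("raising the threshold never adds selected variants", {
  set.seed(13)
  n <- 60
  vus <- data.frame(position = sample(1979, n), ref_aa = "A", alt_aa = "V")
  calls <- data.frame(m1 = sample(c("P", "B"), n, TRUE, c(0.7, 0.3)))
  ranks <- data.frame(m1 = runif(n))
  prob <- runif(n)
  prev_set <- NULL
  for (t in c(0.2, 0.5, 0.8, 0.95)) {
    sel <- consensus_select(vus, prob, calls, ranks,
                            consensus_criteria(t, "m1"))
    key <- paste(sel$position, sel$ref_aa, sel$alt_aa)
    sel_set <- key[sel$selected]
    if (!is.null(prev_set)) expect_true(all(sel_set %in% prev_set))
    prev_set <- sel_set
  }
})

test_that("output is a rank-ordered permutation with fixed tie-breaks", {
  vus <- data.frame(position = c(30, 10, 20, 5), ref_aa = c("A", "C", "A",
                                                            "G"),
                    alt_aa = "V")
  ranks <- data.frame(m1 = c(0.5, 0.9, 0.5, 0.2))
  calls <- data.frame(m1 = rep("P", 4))
  sel <- consensus_select(vus, rep(0.9, 4), calls, ranks,
                          consensus_criteria(0.85, "m1"))
  expect_equal(sort(sel$position), sort(vus$position))  # permutation
  # descending mean rank; the 0.5 tie resolves by ascending position
  expect_equal(sel$position, c(10, 20, 30, 5))
})
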
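test_that("generated tables honour the configured composition", {
  cfg <- simulation_config(n_pathogenic = 12, n_benign = 18, n_vus = 40,
                           n_planted = 4, seed = 19)
  tr <- simulate_training_set(cfg)
  expect_equal(nrow(tr), 30L)
  expect_equal(sum(tr$label == "pathogenic"), 12L)
  expect_false(any(duplicated(tr$position)))
  expect_true(all(tr$ref_aa != tr$alt_aa))
  vus <- simulate_vus_set(cfg)
  expect_equal(nrow(vus$variants), 40L)
  expect_equal(sum(vus$planted), 4L)
  expect_false(any(duplicated(vus$variants$position)))
  # an all-benign request trains nothing
  allb <- simulate_training_set(simulation_config(n_pathogenic = 0,
                                                  n_benign = 20, seed = 1))
  expect_true(all(allb$label == "benign"))
  expect_error(construct_fit(allb), "both classes")
})

test_that("generation is byte-identical per seed", {
  cfg <- simulation_config(n_pathogenic = 10, n_benign = 15, n_vus = 30,
                           n_planted = 3, seed = 23)
  t1 <- simulate_training_set(cfg); t2 <- simulate_training_set(cfg)
  expect_identical(t1, t2)
  v1 <- simulate_vus_set(cfg); v2 <- simulate_vus_set(cfg)
  expect_identical(v1, v2)
  p1 <- tempfile(); p2 <- tempfile()
  write_variant_table(t1, p1); write_variant_table(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed moves the draw
  t3 <- simulate_training_set(simulation_config(n_pathogenic = 10,
                                                n_benign = 15, seed = 24))
  expect_false(identical(t1$position, t3$position))
})

test_that("class-conditional tendencies are realized", {
  for (s in 1:20) {
    tr <- simulate_training_set(simulation_config(n_pathogenic = 40,
                                                  n_benign = 60, seed = s))
    p <- tr$label == "pathogenic"
    expect_gt(mean(tr$phylop100[p]), mean(tr$phylop100[!p]))
  }
  # one larger draw: domain enrichment and BLOSUM separation
  tr <- simulate_training_set(simulation_config(seed = 3))
  p <- tr$label == "pathogenic"
  dom <- domain_of(tr$position, default_map)
  expect_gt(mean(dom[p] %in% 2:7), mean(dom[!p] %in% 2:7))
  bs <- blosum_score(tr$ref_aa, tr$alt_aa, default_matrix)
  expect_lt(mean(bs[p]), mean(bs[!p]))
  expect_gt(mean(tr$exon_number[p]), mean(tr$exon_number[!p]))
})

test_that("generator output round-trips through the table readers", {
  cfg <- simulation_config(n_pathogenic = 8, n_benign = 12, seed = 31)
  tr <- simulate_training_set(cfg)
  p <- tempfile(fileext = ".tsv")
  write_variant_table(tr, p)
  expect_equal(read_variant_table(p), tr, ignore_attr = TRUE)
})

test_that("fully missing methods never contribute to the mean rank score", {
  cfg <- simulation_config(n_vus = 25, n_planted = 2, seed = 5,
                           method_missingness = 1)
  vus <- simulate_vus_set(cfg)
  rank_cols <- grep("_rankscore$", names(vus$scores), value = TRUE)
  expect_true(all(is.na(as.matrix(vus$scores[rank_cols]))))
  # with one observed method alongside, the mean equals that method alone
  ranks <- data.frame(dead = NA_real_, live = c(0.4, 0.9))
  expect_equal(mean_rank_score(ranks)$mean_rank_score, c(0.4, 0.9))
})

test_that("impossible constraints are rejected", {
  bare <- toy_annotation()  # single domain coded 1; nothing in 2-7
  cfg <- simulation_config(n_pathogenic = 3, n_benign = 3, seed = 2)
  expect_error(simulate_training_set(cfg, map = bare),
               "no enriched domains")
  big <- simulation_config(n_pathogenic = 15, n_benign = 10, seed = 2)
  expect_error(simulate_training_set(big, map = toy_annotation(
    domains = data.frame(start = 3, end = 7, code = 2))),
    "more variants")
})
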
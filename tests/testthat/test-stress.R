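test_that("counts-per-million normalization is exact and scale invariant", {
  expect_equal(normalize_counts(100, 1e6), 100)
  expect_equal(normalize_counts(c(0, 0), 2e6), c(0, 0))
  expect_equal(normalize_counts(200, 2e6), normalize_counts(100, 1e6))
  m <- matrix(1:6, 2)
  expect_equal(normalize_counts(m, c(1e6, 1e6, 2e6))[, 3],
               c(5, 6) / 2)
  expect_error(normalize_counts(1, 0), "positive")
})

test_that("the exact conditional DE test reproduces forced values", {
  # observation at the null mode
  r <- de_test(c(10, 10), c(10, 10))
  expect_equal(r$log2FC, 0)
  expect_equal(r$p, 1.0)
  # hand-derived fold change with pseudocount, p by enumeration
  r2 <- de_test(40, 10)
  expect_equal(r2$log2FC, log2(40.5 / 10.5), tolerance = 1e-12)
  expect_equal(r2$p, oracle_exact_p(40, 50, 0.5), tolerance = 1e-12)
  # unequal library sizes shift the conditional null
  r3 <- de_test(40, 10, lib_treat = 2, lib_ctrl = 1)
  expect_equal(r3$p, oracle_exact_p(40, 50, 2 / 3), tolerance = 1e-12)
  expect_equal(r3$log2FC, log2((40.5 / 2) / (10.5 / 1)), tolerance = 1e-12)
  # both arms empty: skipped
  expect_true(is.na(de_test(c(0, 0), c(0, 0))$p))
  expect_error(de_test(numeric(0), 5), "replicate")
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.007), 0.007)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(51)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold-change-ratio partitioning follows the threshold", {
  r <- response_partition(c(A = 4, B = 1, D = 1))
  expect_true(r$partitioned)
  expect_equal(unname(r$ratios["AB"]), 4)
  expect_false(response_partition(c(A = 1.5, B = 1.5, D = 1.5))$partitioned)
  r3 <- response_partition(c(A = 2.0, B = 1.5, D = 1.1))
  expect_false(r3$partitioned)
  expect_equal(unname(r3$ratios), c(2 / 1.5, 2 / 1.1, 1.5 / 1.1),
               tolerance = 1e-12)
})

test_that("relabeling subgenomes inverts ratios, keeps the flag", {
  set.seed(52)
  for (i in 1:50) {
    fc <- setNames(2^runif(3, -3, 3), c("A", "B", "D"))
    a <- response_partition(fc)
    swapped <- fc[c("B", "A", "D")]
    names(swapped) <- c("A", "B", "D")
    b <- response_partition(swapped)
    expect_equal(unname(b$ratios["AB"]), unname(1 / a$ratios["AB"]))
    expect_equal(a$partitioned, b$partitioned)
  }
})

test_that("category assignment matches the scheme examples and oracle", {
  lfc1 <- matrix(c(2, 0, 0), 3, dimnames = list(c("A", "B", "D"), NULL))
  expect_equal(categorize_triplet(lfc1, TRUE, 4), "up-A")
  lfc2 <- matrix(c(0, -2, -2), 3, dimnames = list(c("A", "B", "D"), NULL))
  expect_equal(categorize_triplet(lfc2, TRUE, 4), "down-BD")
  expect_equal(categorize_triplet(lfc1, FALSE, 4), "NONE")
  # a flagged condition without a dominant subset stays uncategorized
  lfc3 <- matrix(c(0.6, -0.6, 0), 3, dimnames = list(c("A", "B", "D"), NULL))
  expect_equal(categorize_triplet(lfc3, TRUE, 2.3), "NONE")
  set.seed(53)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    lfc <- matrix(runif(3 * k, -4, 4), 3,
                  dimnames = list(c("A", "B", "D"), NULL))
    flagged <- runif(k) < 0.6
    mr <- 2^abs(runif(k, 0, 3))
    expect_equal(categorize_triplet(lfc, flagged, mr),
                 oracle_categorize(lfc, flagged, mr))
  }
})

test_that("response profiles gate DE and flag planted partitioning", {
  cfg <- sim_config(n_triplets = 40, depth_mean = 300,
                    frac_partitioned = 0.5, partition_ratio = 4,
                    response_mix = c(none = 1, all = 0, ds_hd = 0,
                                     hs_hd = 0),
                    rng_seed = 54)
  sim <- simulate_triplets(cfg)
  cs <- simulate_counts(sim, cfg)
  long <- cs$counts[, .(triplet_id, subgenome, sample, condition, count)]
  pr <- response_profiles(long, control = "CK")
  m <- merge(pr$triplets, cs$truth, by = "triplet_id")
  expect_gte(m[partitioned == TRUE, mean(partitioned_any)], 0.85)
  expect_gte(m[partitioned == FALSE, mean(!partitioned_any)], 0.9)
  # with a flat background, only divergent homeologs can be DE
  g <- merge(pr$genes, cs$truth, by = "triplet_id")
  expect_true(all(g[de == TRUE, subgenome == divergent_subgenome]))
  # adjusted p never smaller than raw p
  expect_true(all(pr$genes[!is.na(p), padj >= p - 1e-12]))
  # every planted divergent homeolog is categorized in the up direction
  expect_true(all(m[partitioned == TRUE & category != "NONE",
                    startsWith(category, "up")]))
})

test_that("stratified partitioning summary reports printed-style percents", {
  bal <- data.frame(triplet_id = sprintf("t%03d", 1:30),
                    label = rep(c("ECT", "UCT", "UNTESTED"), each = 10))
  part <- data.frame(triplet_id = sprintf("t%03d", 1:30),
                     partitioned_any = rep(c(TRUE, FALSE), 15))
  sm <- summarize_partitioning(bal, part)
  expect_equal(sm$stratum, c("ECT", "UCT", "overall"))
  expect_equal(sm$n, c(10, 10, 20))
  expect_equal(sm$percent, c(50, 50, 50))
  empty <- summarize_partitioning(bal[0, ], part[0, ])
  expect_equal(nrow(empty), 0L)
})
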
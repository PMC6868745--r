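test_that("reo_counts counts strict within-sample orderings", {
  m <- toy_em(rbind(a = c(5, 3, 1, 2, 4),
                    b = c(1, 2, 5, 3, 4)),
              labels = c("SCC", "SCC", "ADC", "ADC", "ADC"),
              genes = c("a", "b"))
  expect_equal(reo_counts(m, "a", "b"),
               c(n_scc_pattern = 2, n_scc = 2, n_adc_pattern = 0, n_adc = 3))
  # the tie in sample 5 satisfies neither orientation
  expect_equal(unname(reo_counts(m, "b", "a")["n_adc_pattern"]), 2)
  expect_error(reo_counts(m, "a", "zz"), "zz")
})

test_that("fisher_one_sided equals the hand-enumerated tail and identities", {
  expect_equal(fisher_one_sided(2, 2, 0, 2), 1 / 6)  # C(4,2) enumeration
  expect_equal(fisher_one_sided(2, 2, 0, 2), enum_fisher_greater(2, 2, 0, 2))
  expect_gte(fisher_one_sided(5, 10, 5, 10), 0.5)    # null direction
  # tail identity: P(>=x) + P(<=x) = 1 + P(x)
  k <- 4; n1 <- 7; n2 <- 5; x <- 3
  expect_equal(fisher_one_sided(x, n1, k - x, n2) +
                 stats::phyper(x, k, n1 + n2 - k, n1),
               1 + stats::dhyper(x, k, n1 + n2 - k, n1))
  expect_error(fisher_one_sided(1, 0, 1, 2), "non-empty")
})

test_that("pair orientation, accuracy and FDR behave on a planted matrix", {
  set.seed(7)
  n <- 10  # per class
  labels <- rep(c("ADC", "SCC"), each = n)
  vals <- matrix(rnorm(10 * 2 * n), 10, 2 * n)
  # plant a perfectly separating pair in genes 1 (SCC-high) and 2 (ADC-high)
  vals[1, labels == "SCC"] <- 9; vals[1, labels == "ADC"] <- 1
  vals[2, labels == "SCC"] <- 1; vals[2, labels == "ADC"] <- 9
  m <- toy_em(vals, labels)
  res <- screen_pairs(m, m$gene_ids, fdr_alpha = 0.05, keep_all = TRUE)
  expect_equal(nrow(res), choose(10, 2))
  top <- res[which.min(res$p), ]
  expect_identical(c(top$scc_high, top$scc_low), c("g01", "g02"))
  expect_equal(top$apparent_accuracy, 1)
  expect_equal(top$p, enum_fisher_greater(n, n, 0, n))
  # independent check of every p against stats::fisher.test (greater)
  p_ref <- mapply(function(xs, xa) stats::fisher.test(
    matrix(c(xs, n - xs, xa, n - xa), 2), alternative = "greater")$p.value,
    res$n_scc_pattern, res$n_adc_pattern)
  expect_equal(res$p, unname(p_ref), tolerance = 1e-10)
  # orientation invariant: SCC pattern frequency >= ADC pattern frequency
  expect_true(all(res$n_scc_pattern / n >= res$n_adc_pattern / n))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("enumerated pair count is n(n-1)/2", {
  for (n in c(2, 5, 17)) {
    expect_equal(nrow(enumerate_pairs(sprintf("x%03d", 1:n))), choose(n, 2))
  }
  expect_error(enumerate_pairs("only"), "at least 2")
})

test_that("pair_apparent_accuracy matches the C/M bookkeeping", {
  m <- make_rule_cohort(45, 27, err_adc = 3, err_scc = 1)
  rep <- pair_apparent_accuracy(m, "KRT5", "AGR2")
  expect_equal(rep$C, 68)
  expect_equal(rep$M, 72)
  expect_equal(percent(rep$C, rep$M), 94.44)
  expect_equal(length(rep$reclassified_to_SCC), 3)
  expect_equal(length(rep$reclassified_to_ADC), 1)
  # perfect agreement
  perf <- pair_apparent_accuracy(make_rule_cohort(5, 5), "KRT5", "AGR2")
  expect_equal(perf$accuracy, 1)
  # unlabeled samples are excluded from the report
  m$labels[1] <- "UNKNOWN"
  expect_equal(pair_apparent_accuracy(m, "KRT5", "AGR2")$M, 71)
})

test_that("rank_diff_stat matches direct nested-geometric-mean evaluation", {
  # 5-gene toy with hand-assigned values, 3 samples per class
  vals <- rbind(c(1, 2, 3, 10, 11, 12),
                c(5, 6, 7,  1,  2,  3),
                c(2, 1, 9,  5,  6,  7),
                c(9, 8, 1,  7,  8,  9),
                c(7, 9, 5,  3,  1,  5))
  m <- toy_em(vals, rep(c("ADC", "SCC"), each = 3))
  R <- apply(vals, 2, rank)
  d <- pmax(abs(R[1, ] - R[2, ]), 1)
  oracle <- sqrt(exp(mean(log(d[1:3]))) * exp(mean(log(d[4:6]))))
  expect_equal(rank_diff_stat(m, "g01", "g02"), oracle)
  # one sample per class with |rank diff| 4 (ADC) and 9 (SCC) -> sqrt(36) = 6
  v2 <- cbind(1:10,
              c(20, 2, 3, 4, 1, 5, 6, 7, 8, 9))
  m2 <- toy_em(v2, c("ADC", "SCC"))
  expect_equal(rank_diff_stat(m2, "g01", "g05"), 6)
  # constant case: same |rank diff| r everywhere gives r
  m3 <- toy_em(cbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(1, 2, 3)),
               c("ADC", "ADC", "SCC", "SCC"))
  expect_equal(rank_diff_stat(m3, "g01", "g03"), 2)
})

test_that("screen statistics are invariant under per-sample monotone maps", {
  set.seed(11)
  m <- toy_em(matrix(rnorm(8 * 12), 8, 12),
              rep(c("ADC", "SCC"), each = 6))
  base <- screen_pairs(m, m$gene_ids, keep_all = TRUE)
  for (i in c(1, 13, 27)) {
    tm <- apply_monotone_per_sample(m, seed_offset = i)
    tr <- screen_pairs(tm, tm$gene_ids, keep_all = TRUE)
    expect_equal(tr, base)
  }
})
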
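test_that("proliferation score is a per-sample mean and linear", {
  vals <- rbind(p1 = c(2, 4), p2 = c(4, 8), other = c(100, 200))
  m <- toy_em(vals, c("ADC", "SCC"), genes = rownames(vals))
  expect_equal(unname(proliferation_score(m, c("p1", "p2"))), c(3, 6))
  # constant panel -> the constant
  mc <- toy_em(matrix(7, 3, 2), c("ADC", "SCC"))
  expect_equal(unname(proliferation_score(mc, c("g01", "g02", "g03"))),
               c(7, 7))
  # linearity over matrices of matching shape
  m2 <- toy_em(vals * 2, c("ADC", "SCC"), genes = rownames(vals))
  msum <- toy_em(vals + vals * 2, c("ADC", "SCC"), genes = rownames(vals))
  expect_equal(proliferation_score(msum, c("p1", "p2")),
               proliferation_score(m, c("p1", "p2")) +
                 proliferation_score(m2, c("p1", "p2")))
  expect_error(proliferation_score(m, character(0)), "empty")
  expect_error(proliferation_score(m, c("p1", "nope")), "nope")
  expect_warning(sc <- proliferation_score(m, c("p1", "nope"),
                                           allow_missing = TRUE), "missing")
  expect_equal(unname(sc), c(2, 4))
})

test_that("group score difference reproduces a hand-enumerated rank-sum p", {
  vals <- rbind(p1 = c(9, 8, 7, 6, 1, 2, 3, 4),
                p2 = c(9.2, 8.4, 7.6, 6.8, 1.2, 2.4, 3.6, 4.8))
  m <- toy_em(vals, rep(c("SCC", "ADC"), each = 4), genes = rownames(vals))
  sc <- proliferation_score(m, c("p1", "p2"))
  p_pkg <- stats::wilcox.test(sc[1:4], sc[5:8])$p.value
  expect_equal(p_pkg, perm_ranksum_p(sc[1:4], sc[5:8]))  # 2/70
  expect_equal(p_pkg, 2 / choose(8, 4))
})

test_that("staining index partitions 1..16 into low/medium/high", {
  expect_identical(as.character(ihc_category(1, 1)$category), "low")
  expect_equal(ihc_category(1, 1)$index, 1)
  expect_identical(as.character(ihc_category(2, 3)$category), "medium")
  expect_equal(ihc_category(2, 3)$index, 6)
  expect_identical(as.character(ihc_category(4, 4)$category), "high")
  expect_equal(ihc_category(4, 4)$index, 16)
  grid <- expand.grid(intensity = 1:4, extent = 1:4)
  all16 <- ihc_category(grid$intensity, grid$extent)
  expect_setequal(all16$index, c(1, 2, 3, 4, 6, 8, 9, 12, 16))
  expect_true(all((all16$index < 5) == (all16$category == "low")))
  expect_true(all((all16$index >= 5 & all16$index <= 10) ==
                    (all16$category == "medium")))
  expect_true(all((all16$index >= 11) == (all16$category == "high")))
  expect_error(ihc_category(0, 1), "1..4")
  expect_error(ihc_category(2, 5), "1..4")
})

test_that("crosstab percentages round half-up to the printed style", {
  ct <- ihc_crosstab(63, 96, 43, 80)
  expect_equal(ct$pct_a, 65.63)  # 65.625 rounds up, not to even
  expect_equal(ct$pct_b, 53.75)
  expect_equal(percent(8, 176), 4.55)
  expect_equal(percent(25, 176), 14.20)
  expect_equal(ct$p_two_sided,
               stats::fisher.test(matrix(c(43, 80 - 43, 63, 96 - 63), 2))$p.value,
               tolerance = 1e-9)
  expect_equal(ct$p_one_sided,
               stats::fisher.test(matrix(c(43, 80 - 43, 63, 96 - 63), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_error(ihc_crosstab(1, 0, 1, 2), "positive")
})

test_that("marker contrasts report direction and exact rank-based p", {
  vals <- rbind(KRT5 = c(9, 8, 7, 1, 2, 3),
                TP63 = c(5, 5, 5, 5, 5, 5),
                NAPSA = c(1, 2, 3, 9, 8, 7),
                TTF1 = c(2, 1, 3, 8, 9, 7),
                CD56 = c(1, 1, 1, 1, 1, 1),
                SYP = c(1, 1, 1, 1, 1, 1),
                CHGA = c(1, 1, 1, 1, 1, 1))
  m <- toy_em(vals, rep(c("SCC", "ADC"), each = 3), genes = rownames(vals),
              samples = sprintf("s%d", 1:6))
  res <- marker_contrast(m, group_a = c("s1", "s2", "s3"),
                         group_b = c("s4", "s5", "s6"))
  krt5 <- res[res$gene_id == "KRT5", ]
  expect_identical(krt5$direction, "UP")
  expect_equal(krt5$p, perm_ranksum_p(vals["KRT5", 1:3], vals["KRT5", 4:6]))
  expect_equal(krt5$p, 2 / choose(6, 3))  # brute-force 3-vs-3 enumeration
  # identical groups: nothing significant, directions TIE
  same <- marker_contrast(m, c("s1", "s2"), c("s4", "s5"),
                          markers = c("CD56", "SYP"))
  expect_true(all(same$p == 1))
  expect_true(all(same$direction == "TIE"))
  # antisymmetry under group swap
  swp <- marker_contrast(m, c("s4", "s5", "s6"), c("s1", "s2", "s3"))
  expect_identical(swp$direction[swp$gene_id == "KRT5"], "DOWN")
  expect_error(marker_contrast(m, c("s1", "s2"), c("s2", "s3")), "overlap")
})
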
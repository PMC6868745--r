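test_that("call_directions recovers a planted shift at the enumerated exact p", {
  # one separated gene among constant null genes; 5 tumor vs 5 normal
  tum_vals <- rbind(g1 = c(10, 11, 12, 13, 14),
                    g2 = rep(5, 5), g3 = rep(2, 5), g4 = rep(7, 5),
                    g5 = rep(1, 5), g6 = rep(3, 5))
  nrm_vals <- rbind(g1 = c(1, 2, 3, 4, 5),
                    g2 = rep(5, 5), g3 = rep(2, 5), g4 = rep(7, 5),
                    g5 = rep(1, 5), g6 = rep(3, 5))
  tum <- toy_em(tum_vals, rep("ADC", 5), genes = rownames(tum_vals))
  nrm <- toy_em(nrm_vals, rep("NORMAL", 5), genes = rownames(nrm_vals))
  calls <- call_directions(tum, nrm, "ADC")

  p_oracle <- perm_ranksum_p(tum_vals["g1", ], nrm_vals["g1", ])
  expect_equal(p_oracle, 2 / choose(10, 5))  # frozen enumeration value
  g1 <- calls[calls$gene_id == "g1", ]
  expect_equal(g1$p, p_oracle)
  expect_identical(g1$direction, "UP")
  expect_true(g1$significant)  # BH-adjusted 6 * 2/252 < 0.05
  expect_false(any(calls$significant[calls$gene_id != "g1"]))

  # antisymmetry: swapping groups flips the direction, p unchanged
  rev <- call_directions(nrm, tum, "ADC")
  expect_identical(rev$direction[rev$gene_id == "g1"], "DOWN")
  expect_equal(rev$p, calls$p)
})

test_that("identically distributed groups yield no significant calls", {
  vals <- matrix(rep(c(3, 3, 5, 5), each = 4), 4, 4, byrow = TRUE)
  a <- toy_em(vals, rep("ADC", 4))
  b <- toy_em(vals, rep("NORMAL", 4), samples = sprintf("n%02d", 1:4))
  calls <- call_directions(a, b, "ADC")
  expect_false(any(calls$significant))
  expect_true(all(calls$direction == "TIE"))
  expect_error(call_directions(em_subset(a, samples = 1), b, "ADC"),
               ">= 2 samples")
})

test_that("find_subtype_opposite keeps exactly opposite-and-significant genes", {
  mk <- function(dir, sig) data.frame(
    gene_id = sprintf("g%d", seq_along(dir)), subtype = "ADC",
    direction = dir, p = 0.001, fdr = ifelse(sig, 0.01, 0.5),
    significant = sig, stringsAsFactors = FALSE)
  adc <- mk(c("UP", "UP", "UP", "DOWN", "TIE"),
            c(TRUE, TRUE, FALSE, TRUE, FALSE))
  scc <- mk(c("DOWN", "UP", "DOWN", "UP", "UP"),
            c(TRUE, TRUE, TRUE, TRUE, TRUE))
  opp <- find_subtype_opposite(adc, scc)
  # g1 opposite+sig kept; g2 same direction; g3 not sig in ADC; g4 kept; g5 TIE
  expect_identical(opp$gene_id, c("g1", "g4"))
  expect_identical(opp$dir_adc, c("UP", "DOWN"))
  expect_identical(opp$dir_scc, c("DOWN", "UP"))
})

test_that("integration excludes direction conflicts and is order-invariant", {
  # 6-gene toy, expectations enumerated by hand:
  #  a: in A only, consistent in B            -> kept
  #  b: in A only, ADC direction flips in B   -> excluded
  #  c: in both sets, same directions         -> kept
  #  d: in both sets, stored directions clash -> excluded
  #  e: in B only, TIE in A                   -> excluded
  #  f: in B only, not measured in A          -> kept
  setA <- make_opposite_set(c("a", "b", "c", "d"),
                            c("UP", "UP", "UP", "UP"),
                            c("DOWN", "DOWN", "DOWN", "DOWN"), "A")
  setB <- make_opposite_set(c("c", "d", "e", "f"),
                            c("UP", "DOWN", "UP", "DOWN"),
                            c("DOWN", "UP", "DOWN", "UP"), "B")
  dirs <- list(
    A = list(ADC = make_direction_table(c("a", "b", "c", "d", "e"),
                                        c("UP", "UP", "UP", "UP", "TIE")),
             SCC = make_direction_table(c("a", "b", "c", "d", "e"),
                                        c("DOWN", "DOWN", "DOWN", "DOWN", "DOWN"))),
    B = list(ADC = make_direction_table(c("a", "b", "c", "d", "e", "f"),
                                        c("UP", "DOWN", "UP", "DOWN", "UP", "DOWN")),
             SCC = make_direction_table(c("a", "b", "c", "d", "e", "f"),
                                        c("DOWN", "DOWN", "DOWN", "UP", "DOWN", "UP"))))
  out <- integrate_opposite_sets(list(setA, setB), dirs)
  expect_identical(out$gene_id, c("a", "c", "f"))
  expect_setequal(attr(out, "excluded"), c("b", "d", "e"))

  swapped <- integrate_opposite_sets(list(setB, setA), dirs)
  expect_identical(swapped$gene_id, out$gene_id)

  # idempotence: two identical, fully consistent sets
  twin <- integrate_opposite_sets(
    list(setA, setA),
    list(A = list(ADC = make_direction_table(setA$gene_id, setA$dir_adc),
                  SCC = make_direction_table(setA$gene_id, setA$dir_scc))))
  expect_identical(twin$gene_id, sort(setA$gene_id))
  expect_lte(nrow(out), length(union(setA$gene_id, setB$gene_id)))
})
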
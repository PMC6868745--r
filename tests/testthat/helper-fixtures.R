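# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths: brute-force enumeration only.

toy_em <- function(values, labels, genes = NULL, samples = NULL, id = "toy") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, genes, samples, labels, id)
}

# Cohort over the two built-in signature genes: every sample has the
# label-concordant KRT5/AGR2 ordering except the first `err_adc` ADC samples
# (KRT5 > AGR2) and first `err_scc` SCC samples (KRT5 < AGR2).
make_rule_cohort <- function(n_adc, n_scc, err_adc = 0, err_scc = 0,
                             id = "cohort") {
  n <- n_adc + n_scc
  labels <- rep(c("ADC", "SCC"), c(n_adc, n_scc))
  krt5 <- ifelse(labels == "SCC", 7, 3)
  agr2 <- ifelse(labels == "SCC", 3, 7)
  if (err_adc > 0) {
    i <- seq_len(err_adc)
    krt5[i] <- 7; agr2[i] <- 3
  }
  if (err_scc > 0) {
    i <- n_adc + seq_len(err_scc)
    krt5[i] <- 3; agr2[i] <- 7
  }
  toy_em(rbind(krt5, agr2, 5), labels,
         genes = c("KRT5", "AGR2", "FILLER"),
         samples = sprintf("%s_%03d", labels, seq_len(n)), id = id)
}

# Exact two-sided rank-sum permutation p by enumeration of all assignments
# of the pooled observations to group 1 (average ranks on ties).
perm_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  W <- colSums(matrix(r[idx], nrow = n1))
  EW <- n1 * (length(pooled) + 1) / 2
  Wobs <- sum(r[seq_len(n1)])
  mean(abs(W - EW) >= abs(Wobs - EW) - 1e-9)
}

# One-sided (greater-in-SCC) Fisher p by enumerating every subset of samples
# that could carry the pattern, given the table margins.
enum_fisher_greater <- function(x_scc, n_scc, x_adc, n_adc) {
  N <- n_scc + n_adc
  k <- x_scc + x_adc
  if (k == 0) return(1)
  idx <- utils::combn(N, k)
  overlap <- colSums(idx <= n_scc)
  mean(overlap >= x_scc)
}

# Random strictly increasing per-sample transform (family chosen by `i`).
random_monotone <- function(i) {
  fam <- i %% 4L
  a <- 0.5 + (i %% 7L) / 3
  b <- (i %% 5L) - 2
  switch(as.character(fam),
         "0" = function(x) a * x + b,
         "1" = function(x) exp(x / (2 + a)),
         "2" = function(x) (x - b)^3,
         "3" = function(x) 1 / (1 + exp(-(x - b) / a)))
}

apply_monotone_per_sample <- function(m, seed_offset = 0L) {
  v <- m$values
  for (j in seq_len(ncol(v)))
    v[, j] <- random_monotone(j + seed_offset)(v[, j])
  expression_matrix(v, m$gene_ids, m$sample_ids, m$labels, m$dataset_id)
}

# Encode a designed vote matrix (pairs x samples, TRUE = SCC vote) as an
# expression matrix over 2 genes per pair: P<j>a > P<j>b iff vote.
votes_to_matrix <- function(V, labels) {
  k <- nrow(V); n <- ncol(V)
  vals <- matrix(5, 2L * k, n)
  genes <- character(2L * k)
  for (j in seq_len(k)) {
    genes[2L * j - 1L] <- sprintf("P%02da", j)
    genes[2L * j] <- sprintf("P%02db", j)
    vals[2L * j - 1L, ] <- 5 + ifelse(V[j, ], 1, -1)
  }
  toy_em(vals, labels, genes = genes,
         samples = sprintf("%s_%02d", labels, seq_len(n)))
}

# Designed vote scenario for the forward-selection oracle checks:
# 15 ADC then 15 SCC samples; pair A errs on ADC 1-2 and SCC 16 (acc 27/30);
# B errs on ADC 3-5; C errs on ADC 6-8; D-H err on five SCC samples each.
# No single pair beats A's 0.90; sets of pairs can reach accuracy 1.
design_votes <- function() {
  labels <- rep(c("ADC", "SCC"), each = 15)
  truth <- labels == "SCC"
  V <- matrix(rep(truth, 8), nrow = 8, byrow = TRUE)
  V[1, c(1, 2, 16)] <- c(TRUE, TRUE, FALSE)   # A
  V[2, 3:5] <- TRUE                           # B
  V[3, 6:8] <- TRUE                           # C
  for (j in 4:8) V[j, 15 + ((1:5 + j) %% 15) + 1] <- FALSE  # D..H
  list(V = V, labels = labels, truth = truth)
}

# independent accuracy oracle: direct vote counting on the raw matrix
oracle_set_accuracy <- function(m, pairs_df) {
  labels <- m$labels
  keep <- labels %in% c("ADC", "SCC")
  votes <- sapply(which(keep), function(s) {
    sum(m$values[pairs_df$scc_high, s] > m$values[pairs_df$scc_low, s])
  })
  calls <- ifelse(votes > nrow(pairs_df) / 2, "SCC", "ADC")
  mean(calls == labels[keep])
}

make_opposite_set <- function(gene_id, dir_adc, dir_scc, dataset_id) {
  out <- data.frame(gene_id = gene_id, dir_adc = dir_adc, dir_scc = dir_scc,
                    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset_id
  class(out) <- c("opposite_gene_set", "data.frame")
  out
}

make_direction_table <- function(gene_id, direction) {
  data.frame(gene_id = gene_id, direction = direction,
             stringsAsFactors = FALSE)
}
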
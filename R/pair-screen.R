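#' Count REO pattern occurrences of a gene pair
#'
#' The REO (relative expression ordering) pattern of an oriented pair
#' `(a, b)` holds in a sample iff the expression of `a` strictly exceeds the
#' expression of `b` within that sample. Ties never satisfy the pattern.
#' Counts are taken separately over SCC- and ADC-labelled samples; other
#' labels are ignored.
#'
#' @param m labelled `ExpressionMatrix`.
#' @param gene_a,gene_b gene identifiers; the pattern tested is
#'   `E[gene_a] > E[gene_b]`.
#' @return named integer vector
#'   `(n_scc_pattern, n_scc, n_adc_pattern, n_adc)`.
#' @export
reo_counts <- function(m, gene_a, gene_b) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  for (g in c(gene_a, gene_b))
    if (!(g %in% m$gene_ids)) stop("gene not present in matrix: ", g)
  patt <- m$values[gene_a, ] > m$values[gene_b, ]
  scc <- m$labels == "SCC"
  adc <- m$labels == "ADC"
  c(n_scc_pattern = sum(patt & scc), n_scc = sum(scc),
    n_adc_pattern = sum(patt & adc), n_adc = sum(adc))
}

#' One-sided Fisher exact test for REO pattern enrichment in SCC
#'
#' Tests whether the pattern frequency in SCC samples is higher than in ADC
#' samples: the p value is the upper hypergeometric tail
#' `P(X >= n_scc_pattern)` conditional on the 2x2 table margins.
#'
#' @param n_scc_pattern,n_scc,n_adc_pattern,n_adc cell counts; pattern counts
#'   must not exceed their group sizes and both groups must be non-empty.
#' @return p value in (0, 1].
#' @export
fisher_one_sided <- function(n_scc_pattern, n_scc, n_adc_pattern, n_adc) {
  if (n_scc <= 0L || n_adc <= 0L) stop("both groups must be non-empty")
  if (n_scc_pattern > n_scc || n_adc_pattern > n_adc ||
      n_scc_pattern < 0L || n_adc_pattern < 0L)
    stop("invalid 2x2 table")
  k <- n_scc_pattern + n_adc_pattern
  stats::phyper(n_scc_pattern - 1L, k, n_scc + n_adc - k, n_scc,
                lower.tail = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sum of probabilities of all tables (under fixed margins) no more likely
#' than the observed one — the convention of [stats::fisher.test()].
#'
#' @inheritParams fisher_one_sided
#' @return p value in (0, 1].
#' @export
fisher_two_sided <- function(n_scc_pattern, n_scc, n_adc_pattern, n_adc) {
  if (n_scc <= 0L || n_adc <= 0L) stop("both groups must be non-empty")
  k <- n_scc_pattern + n_adc_pattern
  x <- max(0L, k - n_adc):min(k, n_scc)
  d <- stats::dhyper(x, k, n_scc + n_adc - k, n_scc)
  obs <- stats::dhyper(n_scc_pattern, k, n_scc + n_adc - k, n_scc)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Enumerate all unordered pairs of a gene set
#'
#' @param gene_ids character vector (>= 2 unique ids).
#' @return two-column character matrix with `choose(n, 2)` rows.
#' @export
enumerate_pairs <- function(gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) < 2L) stop("need at least 2 genes")
  idx <- utils::combn(length(gene_ids), 2L)
  cbind(gene_a = gene_ids[idx[1L, ]], gene_b = gene_ids[idx[2L, ]])
}

# Logical vote matrix: row per oriented pair, column per sample,
# TRUE where E[scc_high] > E[scc_low] in that sample.
reo_vote_matrix <- function(m, scc_high, scc_low) {
  ia <- match(scc_high, m$gene_ids)
  ib <- match(scc_low, m$gene_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("gene not present in matrix: ",
         paste(c(scc_high[is.na(ia)], scc_low[is.na(ib)]), collapse = ", "))
  v <- m$values[ia, , drop = FALSE] > m$values[ib, , drop = FALSE]
  rownames(v) <- paste(scc_high, scc_low, sep = ">")
  v
}

# Per-sample average-tie ranks over the full gene universe of m.
rank_matrix <- function(m) apply(m$values, 2L, rank)

# Rank-difference statistic for oriented pairs given a precomputed rank
# matrix; zero differences are floored at 1 to keep the geometric mean
# defined.
rank_diff_from_ranks <- function(R, labels, scc_high, scc_low) {
  ia <- match(scc_high, rownames(R))
  ib <- match(scc_low, rownames(R))
  D <- pmax(abs(R[ia, , drop = FALSE] - R[ib, , drop = FALSE]), 1)
  adc <- labels == "ADC"
  scc <- labels == "SCC"
  if (!any(adc) || !any(scc)) stop("need samples of both classes")
  exp((rowMeans(log(D[, adc, drop = FALSE])) +
       rowMeans(log(D[, scc, drop = FALSE]))) / 2)
}

#' Rank-difference statistic of a gene pair
#'
#' Within each sample, all genes of the matrix are ranked (average ranks on
#' ties) and the absolute rank difference of the pair is taken. The per-class
#' value is the geometric mean of those absolute differences over the class's
#' samples, and the statistic is the square root of the product of the ADC
#' and SCC values — i.e. the geometric mean of the two class-level geometric
#' means. A zero within-sample difference contributes 1.
#'
#' Large values indicate the two genes sit far apart in the within-sample
#' ordering, making the pair's REO robust to small measurement noise.
#'
#' @param m labelled `ExpressionMatrix` with both classes present.
#' @param gene_a,gene_b gene identifiers.
#' @return single numeric value >= 1.
#' @export
rank_diff_stat <- function(m, gene_a, gene_b) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  for (g in c(gene_a, gene_b))
    if (!(g %in% m$gene_ids)) stop("gene not present in matrix: ", g)
  R <- rank_matrix(m)
  rownames(R) <- m$gene_ids
  unname(rank_diff_from_ranks(R, m$labels, gene_a, gene_b))
}

#' Apparent accuracy of a single oriented gene pair
#'
#' Each labelled sample is called SCC iff `E[gene_a] > E[gene_b]` (otherwise
#' ADC) and the calls are compared with the pathology labels. "Apparent"
#' because pathology labels are themselves imperfect. Unlabeled
#' (UNKNOWN/NORMAL) samples are excluded from the report.
#'
#' @param m labelled `ExpressionMatrix`.
#' @param gene_a,gene_b oriented pair: `gene_a` is the SCC-high gene.
#' @return an `accuracy_report` (see [accuracy_report()]).
#' @export
pair_apparent_accuracy <- function(m, gene_a, gene_b) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  for (g in c(gene_a, gene_b))
    if (!(g %in% m$gene_ids)) stop("gene not present in matrix: ", g)
  calls <- ifelse(m$values[gene_a, ] > m$values[gene_b, ], "SCC", "ADC")
  accuracy_report(m$sample_ids, m$labels, calls)
}

#' Summarize classification calls against pathology labels
#'
#' Bookkeeping shared by the pair screen and the cohort classifier:
#' `C` correct calls out of `M` labelled samples, apparent accuracy `C/M`,
#' sensitivity (fraction of pathology-ADC samples called ADC), specificity
#' (fraction of pathology-SCC samples called SCC), and the reclassified
#' sample lists (pADC called SCC; pSCC called ADC). Samples whose label is
#' not ADC or SCC are dropped.
#'
#' @param sample_ids character vector.
#' @param labels pathology labels, same length.
#' @param calls signature calls in `{ADC, SCC}`, same length.
#' @return list of class `accuracy_report` with fields `C`, `M`, `accuracy`,
#'   `sensitivity`, `specificity`, `n_adc`, `n_scc`, `reclassified_to_SCC`,
#'   `reclassified_to_ADC`. Rates are proportions in `[0, 1]`; class-level
#'   rates are `NA` when the class is absent.
#' @export
accuracy_report <- function(sample_ids, labels, calls) {
  keep <- labels %in% c("ADC", "SCC")
  sample_ids <- sample_ids[keep]
  labels <- labels[keep]
  calls <- calls[keep]
  if (!length(labels))
    stop("no ADC/SCC-labelled samples to score")
  adc <- labels == "ADC"
  scc <- labels == "SCC"
  correct <- calls == labels
  out <- list(
    C = sum(correct), M = length(labels),
    accuracy = mean(correct),
    sensitivity = if (any(adc)) mean(correct[adc]) else NA_real_,
    specificity = if (any(scc)) mean(correct[scc]) else NA_real_,
    n_adc = sum(adc), n_scc = sum(scc),
    reclassified_to_SCC = sample_ids[adc & !correct],
    reclassified_to_ADC = sample_ids[scc & !correct])
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("apparent accuracy %s%% (C = %d / M = %d)\n",
              format(percent(x$C, x$M), nsmall = 2), x$C, x$M))
  if (!is.na(x$sensitivity))
    cat(sprintf("  sensitivity (pADC): %s%%  [%d pADC, %d reclassified to SCC]\n",
                format(percent(round(x$sensitivity * x$n_adc), x$n_adc),
                       nsmall = 2),
                x$n_adc, length(x$reclassified_to_SCC)))
  if (!is.na(x$specificity))
    cat(sprintf("  specificity (pSCC): %s%%  [%d pSCC, %d reclassified to ADC]\n",
                format(percent(round(x$specificity * x$n_scc), x$n_scc),
                       nsmall = 2),
                x$n_scc, length(x$reclassified_to_ADC)))
  invisible(x)
}

#' Statistics for one oriented gene pair
#'
#' Computes the full record for a pair in the given orientation (no
#' re-orientation is performed): REO pattern counts, one-sided Fisher p,
#' apparent accuracy, and the rank-difference statistic.
#'
#' @param m labelled `ExpressionMatrix`.
#' @param gene_a,gene_b oriented pair (`gene_a` SCC-high).
#' @return one-row data.frame with columns `scc_high`, `scc_low`,
#'   `n_scc_pattern`, `n_scc`, `n_adc_pattern`, `n_adc`, `p`, `fdr` (NA),
#'   `apparent_accuracy`, `rank_diff`.
#' @export
pair_stats <- function(m, gene_a, gene_b) {
  cts <- reo_counts(m, gene_a, gene_b)
  acc <- (cts["n_scc_pattern"] + cts["n_adc"] - cts["n_adc_pattern"]) /
    (cts["n_scc"] + cts["n_adc"])
  data.frame(scc_high = gene_a, scc_low = gene_b,
             n_scc_pattern = unname(cts["n_scc_pattern"]),
             n_scc = unname(cts["n_scc"]),
             n_adc_pattern = unname(cts["n_adc_pattern"]),
             n_adc = unname(cts["n_adc"]),
             p = fisher_one_sided(cts["n_scc_pattern"], cts["n_scc"],
                                  cts["n_adc_pattern"], cts["n_adc"]),
             fdr = NA_real_,
             apparent_accuracy = unname(acc),
             rank_diff = rank_diff_stat(m, gene_a, gene_b),
             stringsAsFactors = FALSE)
}

#' Screen all gene pairs of a subtype-opposite gene set
#'
#' Enumerates every unordered pair of the supplied genes (`n(n-1)/2` pairs),
#' orients each so that its REO pattern (`E[scc_high] > E[scc_low]`) is at
#' least as frequent in SCC as in ADC training samples, tests enrichment with
#' the one-sided Fisher exact test, and adjusts over all enumerated pairs
#' with Benjamini-Hochberg. Orientation is fixed here, on training data, and
#' stored with each pair; test data never re-orients.
#'
#' @param m labelled training `ExpressionMatrix` (ADC and SCC samples).
#' @param genes an `opposite_gene_set`, or a character vector of gene ids.
#' @param fdr_alpha FDR threshold; pairs with `fdr < fdr_alpha` are retained
#'   (default 0.05).
#' @param keep_all if `TRUE`, return all enumerated pairs with a
#'   `significant` column instead of filtering.
#' @return data.frame of pair statistics (columns as in [pair_stats()] plus
#'   `significant`), sorted by apparent accuracy descending, then Fisher FDR
#'   ascending, then gene ids.
#' @export
screen_pairs <- function(m, genes, fdr_alpha = 0.05, keep_all = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(as.character(genes))
  genes <- genes[genes %in% m$gene_ids]
  if (length(genes) < 2L) stop("need >= 2 genes present in the matrix")
  if (!any(m$labels == "ADC") || !any(m$labels == "SCC"))
    stop("matrix must contain both ADC and SCC samples")
  pr <- enumerate_pairs(genes)
  scc <- m$labels == "SCC"
  adc <- m$labels == "ADC"
  v <- reo_vote_matrix(m, pr[, 1L], pr[, 2L])
  n_scc <- sum(scc); n_adc <- sum(adc)
  a_scc <- rowSums(v[, scc, drop = FALSE])  # pattern counts, orientation a>b
  a_adc <- rowSums(v[, adc, drop = FALSE])
  flip <- a_scc / n_scc < a_adc / n_adc
  scc_high <- ifelse(flip, pr[, 2L], pr[, 1L])
  scc_low <- ifelse(flip, pr[, 1L], pr[, 2L])
  # counts under the chosen orientation; ties satisfy neither orientation
  v_flip <- reo_vote_matrix(m, pr[flip, 2L], pr[flip, 1L])
  n_scc_pattern <- a_scc
  n_adc_pattern <- a_adc
  if (any(flip)) {
    n_scc_pattern[flip] <- rowSums(v_flip[, scc, drop = FALSE])
    n_adc_pattern[flip] <- rowSums(v_flip[, adc, drop = FALSE])
  }
  p <- stats::phyper(n_scc_pattern - 1L, n_scc_pattern + n_adc_pattern,
                     n_scc + n_adc - n_scc_pattern - n_adc_pattern,
                     n_scc, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  acc <- (n_scc_pattern + (n_adc - n_adc_pattern)) / (n_scc + n_adc)
  R <- rank_matrix(m)
  rownames(R) <- m$gene_ids
  rd <- rank_diff_from_ranks(R, m$labels, scc_high, scc_low)
  out <- data.frame(scc_high = scc_high, scc_low = scc_low,
                    n_scc_pattern = n_scc_pattern, n_scc = n_scc,
                    n_adc_pattern = n_adc_pattern, n_adc = n_adc,
                    p = p, fdr = fdr, apparent_accuracy = acc,
                    rank_diff = unname(rd),
                    significant = fdr < fdr_alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$apparent_accuracy, out$fdr, out$scc_high,
                   out$scc_low), , drop = FALSE]
  rownames(out) <- NULL
  if (!keep_all) out <- out[out$significant, , drop = FALSE]
  out
}

#' Write pair statistics as TSV
#'
#' @param stats data.frame from [screen_pairs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pair_stats <- function(stats, path) {
  utils::write.table(stats[order(-stats$apparent_accuracy), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
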
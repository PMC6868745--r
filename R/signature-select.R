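#' Construct a gene-pair signature
#'
#' A signature is an ordered set of oriented gene pairs plus the
#' strict-majority voting rule: a sample is called SCC iff more than half of
#' the pairs show their SCC pattern (`E[scc_high] > E[scc_low]`) within that
#' sample, otherwise ADC. An exact half (possible for an even number of
#' pairs) therefore falls to ADC.
#'
#' @param scc_high,scc_low character vectors of equal length: per pair, the
#'   gene expected higher in SCC and the gene expected lower.
#' @param provenance optional list of free-form provenance fields (training
#'   dataset ids, apparent accuracy achieved, rank-difference summary, ...).
#' @return object of class `reo_signature`.
#' @export
reo_signature <- function(scc_high, scc_low, provenance = list()) {
  scc_high <- as.character(scc_high)
  scc_low <- as.character(scc_low)
  if (!length(scc_high) || length(scc_high) != length(scc_low))
    stop("need matching non-empty scc_high / scc_low vectors")
  if (any(scc_high == scc_low))
    stop("a pair cannot contain the same gene twice: ",
         scc_high[scc_high == scc_low][1])
  key <- paste(pmin(scc_high, scc_low), pmax(scc_high, scc_low))
  if (anyDuplicated(key))
    stop("duplicated gene pair: ", key[duplicated(key)][1])
  structure(list(pairs = data.frame(scc_high = scc_high, scc_low = scc_low,
                                    stringsAsFactors = FALSE),
                 rule = "strict_majority",
                 provenance = provenance),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("REO signature: %d pair(s), strict-majority vote (SCC if > half)\n",
              nrow(x$pairs)))
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s > %s  => SCC vote\n",
                x$pairs$scc_high[i], x$pairs$scc_low[i]))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' The frozen two-gene lung subtyping rule
#'
#' The built-in signature for distinguishing lung adenocarcinoma from
#' squamous cell carcinoma: a sample is SCC iff its KRT5 expression strictly
#' exceeds its AGR2 expression, otherwise ADC. KRT5 (a basal keratin) is the
#' SCC-high gene; AGR2 (an adenocarcinoma-associated antigen) is the
#' ADC-high gene.
#'
#' @return `reo_signature` with the single pair KRT5 > AGR2.
#' @export
builtin_signature <- function() {
  reo_signature("KRT5", "AGR2",
                provenance = list(name = "KRT5-AGR2 lung ADC/SCC rule",
                                  training = "frozen"))
}

# integer number of correct calls of a vote-count vector against labels
.majority_correct <- function(vote_counts, k, is_scc) {
  calls_scc <- vote_counts > k / 2
  sum(calls_scc == is_scc)
}

#' Greedy forward selection of a gene-pair set from a seed pair
#'
#' Starting from the seed alone, repeatedly adds the candidate pair whose
#' addition yields the highest apparent accuracy of the set under
#' strict-majority voting, stopping as soon as no addition strictly increases
#' accuracy. Ties among candidates are broken by candidate order (the
#' screening sort: apparent accuracy descending, then FDR, then gene ids),
#' which makes the procedure fully deterministic.
#'
#' @param m labelled training `ExpressionMatrix`.
#' @param seed one-row data.frame (or list) with `scc_high`, `scc_low`, or an
#'   integer row index into `candidates`.
#' @param candidates data.frame of screened pairs ([screen_pairs()] output);
#'   the seed must appear among them (it is added if missing).
#' @return list with `pairs` (data.frame `scc_high`, `scc_low`), `accuracy`
#'   (apparent accuracy in `[0, 1]`), `C` and `M` (correct / total counts).
#' @export
forward_select <- function(m, seed, candidates) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.numeric(seed)) seed <- candidates[seed, ]
  if (is.null(candidates) || !nrow(candidates))
    candidates <- data.frame(scc_high = character(0), scc_low = character(0))
  in_cand <- any(candidates$scc_high == seed$scc_high &
                 candidates$scc_low == seed$scc_low)
  if (!in_cand)
    candidates <- rbind(
      data.frame(scc_high = seed$scc_high, scc_low = seed$scc_low,
                 stringsAsFactors = FALSE),
      candidates[, c("scc_high", "scc_low"), drop = FALSE])
  keep <- m$labels %in% c("ADC", "SCC")
  if (!any(keep)) stop("no labelled samples")
  mlab <- em_subset(m, samples = which(keep))
  is_scc <- mlab$labels == "SCC"
  V <- reo_vote_matrix(mlab, candidates$scc_high, candidates$scc_low)
  storage.mode(V) <- "integer"
  n <- ncol(V)
  seed_idx <- which(candidates$scc_high == seed$scc_high &
                    candidates$scc_low == seed$scc_low)[1]
  sel <- seed_idx
  cnt <- V[seed_idx, ]
  best_correct <- .majority_correct(cnt, 1L, is_scc)
  repeat {
    free <- setdiff(seq_len(nrow(candidates)), sel)
    if (!length(free)) break
    k_new <- length(sel) + 1L
    M_new <- V[free, , drop = FALSE] +
      matrix(cnt, length(free), n, byrow = TRUE) > k_new / 2
    correct <- as.integer(
      rowSums(M_new[, is_scc, drop = FALSE]) +
      rowSums(!M_new[, !is_scc, drop = FALSE]))
    j <- which.max(correct)  # first maximum = candidate-order tie-break
    if (correct[j] <= best_correct) break
    sel <- c(sel, free[j])
    cnt <- cnt + V[free[j], ]
    best_correct <- correct[j]
  }
  list(pairs = candidates[sel, c("scc_high", "scc_low"), drop = FALSE],
       accuracy = best_correct / n, C = best_correct, M = n)
}

#' Select the final signature by seeded forward selection
#'
#' Runs [forward_select()] from each of the top `n_seeds` screened pairs
#' (ranked by apparent accuracy; ties at the boundary broken by Fisher FDR,
#' then gene ids). Among the resulting pair sets, the maximum-accuracy ones
#' are kept and ties are broken by (1) fewest pairs, (2) largest
#' rank-difference summary (median over the set's pairs of the per-pair
#' rank-difference statistic), (3) lexicographic order of the concatenated
#' gene ids. The whole procedure is deterministic.
#'
#' @param m labelled training `ExpressionMatrix`.
#' @param pair_stats screened pairs from [screen_pairs()]; only significant
#'   pairs should be supplied.
#' @param n_seeds number of seeds (default 50).
#' @return `reo_signature` with provenance recording the training dataset,
#'   the achieved apparent accuracy and the rank-difference summary.
#' @export
select_signature <- function(m, pair_stats, n_seeds = 50L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(pair_stats) || !nrow(pair_stats))
    stop("no significant pairs to select from")
  if (n_seeds < 1L) stop("n_seeds must be >= 1")
  ord <- order(-pair_stats$apparent_accuracy, pair_stats$fdr,
               pair_stats$scc_high, pair_stats$scc_low)
  pair_stats <- pair_stats[ord, , drop = FALSE]
  seeds <- seq_len(min(n_seeds, nrow(pair_stats)))
  sets <- lapply(seeds, function(i) forward_select(m, i, pair_stats))
  correct <- vapply(sets, `[[`, integer(1), "C")
  best <- which(correct == max(correct))
  sizes <- vapply(sets[best], function(s) nrow(s$pairs), integer(1))
  best <- best[sizes == min(sizes)]
  rd_summary <- vapply(sets[best], function(s) {
    idx <- match(paste(s$pairs$scc_high, s$pairs$scc_low),
                 paste(pair_stats$scc_high, pair_stats$scc_low))
    rd <- pair_stats$rank_diff[idx]
    if (anyNA(rd))
      rd <- mapply(rank_diff_stat, s$pairs$scc_high, s$pairs$scc_low,
                   MoreArgs = list(m = m))
    stats::median(rd)
  }, numeric(1))
  best <- best[rd_summary == max(rd_summary)]
  if (length(best) > 1L) {
    keys <- vapply(sets[best], function(s)
      paste(sort(paste(s$pairs$scc_high, s$pairs$scc_low, sep = ">")),
            collapse = "|"), character(1))
    best <- best[order(keys)][1]
  }
  chosen <- sets[[best[1]]]
  reo_signature(chosen$pairs$scc_high, chosen$pairs$scc_low,
                provenance = list(
                  training = m$dataset_id,
                  apparent_accuracy = chosen$accuracy,
                  C = chosen$C, M = chosen$M,
                  rank_diff_median = max(rd_summary),
                  n_seeds = length(seeds),
                  n_candidates = nrow(pair_stats)))
}

#' Save / load a signature as JSON
#'
#' The JSON layout is
#' `{"pairs": [{"scc_high": "...", "scc_low": "..."}, ...],
#'   "rule": "strict_majority", "provenance": {...}}`.
#' Round trips are lossless; malformed files and invariant violations
#' (duplicate pairs, a pair of one gene) raise errors on load.
#'
#' @param s `reo_signature`.
#' @param path JSON file path.
#' @return `save_signature` returns `path` invisibly; `load_signature`
#'   returns the `reo_signature`.
#' @export
save_signature <- function(s, path) {
  stopifnot(inherits(s, "reo_signature"))
  jsonlite::write_json(
    list(pairs = s$pairs, rule = s$rule, provenance = s$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_signature
#' @export
load_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$pairs) || !all(c("scc_high", "scc_low") %in% names(x$pairs)))
    stop("malformed signature JSON (missing pairs/scc_high/scc_low): ", path)
  if (!is.null(x$rule) && !identical(x$rule, "strict_majority"))
    stop("unsupported voting rule: ", x$rule)
  prov <- if (is.null(x$provenance)) list() else as.list(x$provenance)
  reo_signature(x$pairs$scc_high, x$pairs$scc_low, provenance = prov)
}
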
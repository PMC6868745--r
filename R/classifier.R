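#' Classify a single sample with a gene-pair signature
#'
#' Applies the strict-majority REO rule to one sample: each pair votes SCC
#' iff its SCC-high gene strictly exceeds its SCC-low gene in this sample
#' (ties vote ADC); the sample is called SCC iff SCC votes exceed half the
#' pairs. Only the ordering of values within this sample is used — no other
#' sample, reference distribution or normalization enters, which is what
#' makes the call robust to batch effects and monotone distortions.
#'
#' @param expr named numeric vector mapping gene ids to expression values for
#'   one sample (any monotone-within-sample scale).
#' @param s `reo_signature` (default: the built-in KRT5/AGR2 rule).
#' @param sample_id identifier recorded on the result.
#' @return list of class `reo_call` with fields `sample_id`, `call`
#'   (`"ADC"` or `"SCC"`), `votes_scc`, `votes_total`.
#' @examples
#' classify_sample(c(KRT5 = 7.1, AGR2 = 3.2))$call  # "SCC"
#' @export
classify_sample <- function(expr, s = builtin_signature(),
                            sample_id = "sample") {
  stopifnot(inherits(s, "reo_signature"))
  need <- unique(c(s$pairs$scc_high, s$pairs$scc_low))
  miss <- setdiff(need, names(expr))
  if (length(miss))
    stop("signature gene(s) missing from sample: ",
         paste(miss, collapse = ", "))
  votes <- expr[s$pairs$scc_high] > expr[s$pairs$scc_low]
  k <- nrow(s$pairs)
  out <- list(sample_id = sample_id,
              call = if (sum(votes) > k / 2) "SCC" else "ADC",
              votes_scc = sum(votes), votes_total = k)
  class(out) <- "reo_call"
  out
}

#' @export
print.reo_call <- function(x, ...) {
  cat(sprintf("%s: %s (%d/%d pair votes for SCC)\n",
              x$sample_id, x$call, x$votes_scc, x$votes_total))
  invisible(x)
}

#' Classify every sample of a cohort and summarize against pathology
#'
#' Each sample is classified independently with [classify_sample()]'s rule
#' (the implementation is vectorized but uses no cross-sample information).
#' When ADC/SCC pathology labels are present, an [accuracy_report()] is
#' attached: apparent accuracy `C/M`, sensitivity (pADC agreement),
#' specificity (pSCC agreement) and the reclassified-sample lists. Samples
#' labelled UNKNOWN or NORMAL are classified but excluded from the report.
#'
#' @param m `ExpressionMatrix`.
#' @param s `reo_signature` (default: built-in KRT5/AGR2 rule).
#' @return list with `calls` (data.frame `sample_id`, `call`, `votes_scc`,
#'   `votes_total`, `pathology`) and `report` (`accuracy_report`, or `NULL`
#'   when no sample carries an ADC/SCC label).
#' @export
classify_cohort <- function(m, s = builtin_signature()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(s, "reo_signature"))
  V <- reo_vote_matrix(m, s$pairs$scc_high, s$pairs$scc_low)
  k <- nrow(s$pairs)
  votes <- colSums(V)
  calls <- data.frame(sample_id = m$sample_ids,
                      call = ifelse(votes > k / 2, "SCC", "ADC"),
                      votes_scc = as.integer(votes),
                      votes_total = k,
                      pathology = m$labels,
                      stringsAsFactors = FALSE)
  report <- if (any(m$labels %in% c("ADC", "SCC")))
    accuracy_report(m$sample_ids, m$labels, calls$call) else NULL
  list(calls = calls, report = report)
}

#' Write cohort calls and report block as TSV + text
#'
#' Writes the per-sample calls as TSV and, when a report is present, appends
#' a commented report block with counts and percentages rounded half-up to
#' two decimals.
#'
#' @param res result of [classify_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(res, path) {
  utils::write.table(res$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(res$report)) {
    r <- res$report
    lines <- c(
      sprintf("# C=%d M=%d", r$C, r$M),
      sprintf("# apparent_accuracy=%.2f%%", percent(r$C, r$M)),
      if (!is.na(r$sensitivity))
        sprintf("# sensitivity=%.2f%% (pADC n=%d, reclassified_to_SCC=%d)",
                round_half_up(100 * r$sensitivity, 2), r$n_adc,
                length(r$reclassified_to_SCC)),
      if (!is.na(r$specificity))
        sprintf("# specificity=%.2f%% (pSCC n=%d, reclassified_to_ADC=%d)",
                round_half_up(100 * r$specificity, 2), r$n_scc,
                length(r$reclassified_to_ADC)),
      if (length(r$reclassified_to_SCC))
        paste0("# reclassified_to_SCC: ",
               paste(r$reclassified_to_SCC, collapse = ",")),
      if (length(r$reclassified_to_ADC))
        paste0("# reclassified_to_ADC: ",
               paste(r$reclassified_to_ADC, collapse = ",")))
    cat(lines, file = path, sep = "\n", append = TRUE)
  }
  invisible(path)
}
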
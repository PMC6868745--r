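#' Combine expression matrices on their common gene universe
#'
#' Column-binds samples of several datasets, restricting to the genes shared
#' by all of them. Sample ids must be globally unique.
#'
#' @param mats list of `ExpressionMatrix` objects.
#' @param dataset_id identifier of the combined matrix.
#' @return `ExpressionMatrix`.
#' @export
em_cbind <- function(mats, dataset_id = "integrated") {
  stopifnot(length(mats) >= 1L)
  if (length(mats) == 1L) return(mats[[1]])
  common <- Reduce(intersect, lapply(mats, `[[`, "gene_ids"))
  if (length(common) < 2L) stop("datasets share fewer than 2 genes")
  mats <- lapply(mats, em_subset, genes = common)
  expression_matrix(do.call(cbind, lapply(mats, `[[`, "values")),
                    common,
                    unlist(lapply(mats, `[[`, "sample_ids")),
                    unlist(lapply(mats, `[[`, "labels")),
                    dataset_id)
}

#' Run the full signature discovery pipeline
#'
#' Mirrors the discovery workflow end to end. Per dataset: (1) call
#' tumor-vs-normal dysregulation directions for ADC and for SCC samples
#' against that dataset's normal controls ([call_directions()]); (2) extract
#' subtype-opposite genes ([find_subtype_opposite()]). Across datasets the
#' per-dataset sets are integrated with the cross-dataset direction
#' consistency rule ([integrate_opposite_sets()]). Then, on the pooled ADC
#' and SCC samples of all datasets, every pair of subtype-opposite genes is
#' screened ([screen_pairs()]) and the signature is chosen by seeded forward
#' selection ([select_signature()]).
#'
#' @param matrices a labelled `ExpressionMatrix` (labels in
#'   ADC/SCC/NORMAL) or a list of them, one per dataset; each dataset needs
#'   >= 2 ADC, >= 2 SCC and >= 2 NORMAL samples.
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @param fdr_alpha FDR threshold for pair screening (default 0.05).
#' @param n_seeds forward-selection seeds (default 50).
#' @return list with `signature` (`reo_signature`), `pair_stats` (screened
#'   significant pairs), `opposite` (integrated `opposite_gene_set`),
#'   `per_dataset` (per-dataset direction calls and opposite sets), and
#'   `report` (training [accuracy_report()] of the signature).
#' @export
discover_signature <- function(matrices, alpha = 0.05, fdr_alpha = 0.05,
                               n_seeds = 50L) {
  if (inherits(matrices, "ExpressionMatrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  per_dataset <- vector("list", length(matrices))
  sets <- vector("list", length(matrices))
  directions <- list()
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    stopifnot(inherits(m, "ExpressionMatrix"))
    adc <- em_subset(m, samples = which(m$labels == "ADC"))
    scc <- em_subset(m, samples = which(m$labels == "SCC"))
    nrm <- em_subset(m, samples = which(m$labels == "NORMAL"))
    if (ncol(nrm$values) < 2L)
      stop("dataset '", m$dataset_id, "' has < 2 normal controls")
    adc_calls <- call_directions(adc, nrm, "ADC", alpha = alpha)
    scc_calls <- call_directions(scc, nrm, "SCC", alpha = alpha)
    opp <- find_subtype_opposite(adc_calls, scc_calls,
                                 dataset_id = m$dataset_id)
    per_dataset[[i]] <- list(adc_calls = adc_calls, scc_calls = scc_calls,
                             opposite = opp)
    sets[[i]] <- opp
    directions[[m$dataset_id]] <- list(ADC = adc_calls, SCC = scc_calls)
  }
  opposite <- if (length(sets) > 1L)
    integrate_opposite_sets(sets, directions) else sets[[1]]
  tumors <- em_cbind(lapply(matrices, function(m)
    em_subset(m, samples = which(m$labels %in% c("ADC", "SCC")))),
    dataset_id = paste(vapply(matrices, `[[`, character(1), "dataset_id"),
                       collapse = "+"))
  if (nrow(opposite) < 2L)
    stop("no significant pairs to select from ",
         "(fewer than 2 subtype-opposite genes)")
  pair_stats <- screen_pairs(tumors, opposite, fdr_alpha = fdr_alpha)
  if (!nrow(pair_stats))
    stop("no significant pairs to select from ",
         "(no pair passed the Fisher FDR screen)")
  signature <- select_signature(tumors, pair_stats, n_seeds = n_seeds)
  report <- classify_cohort(tumors, signature)$report
  list(signature = signature, pair_stats = pair_stats, opposite = opposite,
       per_dataset = per_dataset, report = report)
}
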
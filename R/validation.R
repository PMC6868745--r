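#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); printed
#' clinical percentages conventionally round half up (65.625 -> 65.63), so
#' the package's report formatting uses this variant.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param count numerator.
#' @param total denominator (> 0).
#' @return `100 * count / total`, rounded half-up to 2 decimals.
#' @examples
#' percent(63, 96)  # 65.63
#' @export
percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  round_half_up(100 * count / total, 2)
}

#' Per-sample proliferation score
#'
#' The arithmetic mean, within each sample, of the expression of a
#' proliferation-associated gene panel (conventionally 44 genes; the panel is
#' supplied by the caller). A higher score indicates more proliferative
#' activity, which in NSCLC is characteristic of squamous tumors — so
#' reclassified samples are expected to shift toward their new class's score
#' distribution.
#'
#' @param m `ExpressionMatrix`.
#' @param gene_list character vector of panel gene ids.
#' @param allow_missing if `TRUE`, genes absent from the matrix are dropped
#'   with a warning instead of raising an error.
#' @return named numeric vector of per-sample scores.
#' @export
proliferation_score <- function(m, gene_list, allow_missing = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  gene_list <- unique(as.character(gene_list))
  if (!length(gene_list)) stop("empty gene list")
  miss <- setdiff(gene_list, m$gene_ids)
  if (length(miss)) {
    if (!allow_missing)
      stop("panel gene(s) missing from matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    warning(length(miss), " panel gene(s) missing; averaging the rest")
    gene_list <- setdiff(gene_list, miss)
    if (!length(gene_list)) stop("no panel genes present in matrix")
  }
  colMeans(m$values[gene_list, , drop = FALSE])
}

#' Immunohistochemistry staining index and category
#'
#' The staining index is the product of average staining intensity (1-4) and
#' staining extent (1-4), giving a 16-point scale. Index < 5 is low
#' expression, 5-10 medium, 11-16 high.
#'
#' @param intensity,extent integer vectors with values in 1..4.
#' @return data.frame with columns `intensity`, `extent`, `index`,
#'   `category` (factor low/medium/high).
#' @examples
#' ihc_category(2, 3)  # index 6, medium
#' @export
ihc_category <- function(intensity, extent) {
  if (any(!(intensity %in% 1:4)) || any(!(extent %in% 1:4)))
    stop("intensity and extent must be integers in 1..4")
  idx <- as.integer(intensity) * as.integer(extent)
  cat <- cut(idx, breaks = c(0, 4, 10, 16),
             labels = c("low", "medium", "high"))
  data.frame(intensity = as.integer(intensity), extent = as.integer(extent),
             index = idx, category = cat)
}

#' Crosstab of high-expression frequencies for two proteins
#'
#' Compares the frequency of high expression of a protein between two sample
#' groups (e.g. Krt5 in pADC vs pSCC): percentages rounded half-up to two
#' decimals and Fisher exact p values (one-sided: higher frequency in group
#' b; and two-sided).
#'
#' @param high_a,total_a high-expression count and group size in group a.
#' @param high_b,total_b same for group b.
#' @return list with `pct_a`, `pct_b`, `p_one_sided`
#'   (enrichment in group b), `p_two_sided`.
#' @export
ihc_crosstab <- function(high_a, total_a, high_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("group totals must be positive")
  if (high_a > total_a || high_b > total_b || high_a < 0 || high_b < 0)
    stop("invalid counts")
  list(pct_a = percent(high_a, total_a),
       pct_b = percent(high_b, total_b),
       p_one_sided = fisher_one_sided(high_b, total_b, high_a, total_a),
       p_two_sided = fisher_two_sided(high_b, total_b, high_a, total_a))
}

#' Default subtype-specific marker panel
#'
#' SCC markers (KRT5, TP63), ADC markers (NAPSA, TTF1) and neuroendocrine
#' markers (CD56, SYP, CHGA).
#'
#' @return named character vector; names give the marker class.
#' @export
default_marker_panel <- function() {
  c(SCC = "KRT5", SCC = "TP63", ADC = "NAPSA", ADC = "TTF1",
    NE = "CD56", NE = "SYP", NE = "CHGA")
}

#' Marker-gene contrast between two sample groups
#'
#' For each marker gene, reports the dysregulation direction in `group_a`
#' relative to `group_b` (sign of the median shift) and a two-sided Wilcoxon
#' rank-sum p value. Typical use: contrast signature-reclassified samples
#' against signature-confirmed samples and check that subtype markers move
#' the expected way. (A rank-product statistic is sometimes used for this in
#' the literature; the rank-sum test is this package's rank-based stand-in.)
#'
#' @param m `ExpressionMatrix`.
#' @param group_a,group_b disjoint, non-empty vectors of sample ids.
#' @param markers marker gene ids (default [default_marker_panel()]).
#' @return data.frame with columns `gene_id`, `direction` (`UP`/`DOWN`/`TIE`
#'   in `group_a`), `p`.
#' @export
marker_contrast <- function(m, group_a, group_b,
                            markers = default_marker_panel()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  miss <- setdiff(c(group_a, group_b), m$sample_ids)
  if (length(miss)) stop("sample(s) not present: ", paste(miss, collapse = ", "))
  markers <- as.character(markers)
  missg <- setdiff(markers, m$gene_ids)
  if (length(missg)) stop("marker(s) not present: ", paste(missg, collapse = ", "))
  ia <- match(group_a, m$sample_ids)
  ib <- match(group_b, m$sample_ids)
  res <- lapply(markers, function(g) {
    x <- m$values[g, ia]
    y <- m$values[g, ib]
    shift <- stats::median(x) - stats::median(y)
    data.frame(gene_id = g,
               direction = if (shift > 0) "UP" else if (shift < 0) "DOWN" else "TIE",
               p = wilcoxon_de(x, y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
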
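#' Call per-gene tumor-vs-normal dysregulation directions
#'
#' For each gene, tests tumor versus normal samples with a two-sided Wilcoxon
#' rank-sum test and adjusts p values over all genes with the
#' Benjamini-Hochberg procedure. The dysregulation direction is the sign of
#' the median tumor-minus-normal shift and is reported for every gene whether
#' or not it is significant (the unthresholded directions are needed by
#' [integrate_opposite_sets()]'s cross-dataset consistency check). Genes with
#' an exactly zero median shift get direction `"TIE"` and are never
#' significant.
#'
#' The test engine is pluggable through `de_fun` so that a different
#' differential-expression statistic (e.g. a moderated or permutation-based
#' one) can be substituted; only `(p, direction)` per gene is consumed
#' downstream.
#'
#' @param tumor `ExpressionMatrix` of one tumor subtype (>= 2 samples).
#' @param normal `ExpressionMatrix` of normal controls (>= 2 samples), same
#'   gene universe.
#' @param subtype subtype being tested, `"ADC"` or `"SCC"`; recorded on the
#'   output.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @param de_fun function `(tumor_values, normal_values) -> p` applied per
#'   gene row pair; default is a two-sided Wilcoxon rank-sum test.
#' @return data.frame of class `direction_calls` with columns `gene_id`,
#'   `subtype`, `direction` (`UP`/`DOWN`/`TIE`), `p`, `fdr`, `significant`.
#' @export
call_directions <- function(tumor, normal, subtype = c("ADC", "SCC"),
                            alpha = 0.05, de_fun = wilcoxon_de) {
  subtype <- match.arg(subtype)
  stopifnot(inherits(tumor, "ExpressionMatrix"),
            inherits(normal, "ExpressionMatrix"))
  if (ncol(tumor$values) < 2L || ncol(normal$values) < 2L)
    stop("need >= 2 samples in both tumor and normal groups")
  if (!identical(tumor$gene_ids, normal$gene_ids)) {
    common <- intersect(tumor$gene_ids, normal$gene_ids)
    if (!length(common)) stop("tumor and normal share no genes")
    tumor <- em_subset(tumor, genes = common)
    normal <- em_subset(normal, genes = common)
  }
  g <- tumor$gene_ids
  p <- vapply(seq_along(g), function(i)
    de_fun(tumor$values[i, ], normal$values[i, ]), numeric(1))
  p[is.na(p)] <- 1
  shift <- apply(tumor$values, 1L, stats::median) -
    apply(normal$values, 1L, stats::median)
  direction <- ifelse(shift > 0, "UP", ifelse(shift < 0, "DOWN", "TIE"))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = g, subtype = subtype, direction = direction,
                    p = p, fdr = fdr,
                    significant = fdr < alpha & direction != "TIE",
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "dataset_id") <- tumor$dataset_id
  class(out) <- c("direction_calls", "data.frame")
  out
}

# Two-sided Wilcoxon rank-sum p; degenerate (all-tied) input yields p = 1.
wilcoxon_de <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Extract subtype-opposite genes from two direction-call tables
#'
#' A gene is subtype-opposite when it is significantly differentially
#' expressed against normals in both subtypes but with opposite directions
#' (e.g. up in ADC, down in SCC).
#'
#' @param adc_calls,scc_calls `direction_calls` tables from
#'   [call_directions()] for the ADC and SCC contrasts of one dataset.
#' @param dataset_id identifier stored on the result; defaults to the one
#'   recorded on `adc_calls`.
#' @return data.frame of class `opposite_gene_set` with columns `gene_id`,
#'   `dir_adc`, `dir_scc`; possibly zero rows.
#' @export
find_subtype_opposite <- function(adc_calls, scc_calls, dataset_id = NULL) {
  stopifnot(is.data.frame(adc_calls), is.data.frame(scc_calls))
  if (is.null(dataset_id))
    dataset_id <- attr(adc_calls, "dataset_id") %||% "unnamed"
  common <- intersect(adc_calls$gene_id, scc_calls$gene_id)
  a <- adc_calls[match(common, adc_calls$gene_id), ]
  s <- scc_calls[match(common, scc_calls$gene_id), ]
  keep <- a$significant & s$significant & a$direction != s$direction &
    a$direction != "TIE" & s$direction != "TIE"
  out <- data.frame(gene_id = common[keep],
                    dir_adc = a$direction[keep],
                    dir_scc = s$direction[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset_id") <- dataset_id
  class(out) <- c("opposite_gene_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate subtype-opposite gene sets across datasets
#'
#' Takes the union of per-dataset subtype-opposite gene sets, then excludes
#' every gene whose unthresholded dysregulation directions in any other
#' dataset conflict with its stored directions. A gene present in several
#' input sets must agree on both directions everywhere to be retained; a
#' `"TIE"` direction in another dataset counts as a conflict. The result does
#' not depend on the order in which datasets are supplied.
#'
#' @param sets list of `opposite_gene_set` objects (one per dataset).
#' @param directions list, parallel to the datasets involved, of per-dataset
#'   direction tables: each element a list with components `ADC` and `SCC`
#'   holding the full (unthresholded) `direction_calls` tables of that
#'   dataset. Element names must match the `dataset_id` attributes of `sets`.
#' @return `opposite_gene_set` with `dataset_id` `"integrated"`. Excluded
#'   genes are recorded in the `"excluded"` attribute.
#' @export
integrate_opposite_sets <- function(sets, directions = NULL) {
  if (!length(sets)) stop("need at least one opposite_gene_set")
  ids <- vapply(sets, function(s) attr(s, "dataset_id") %||% "unnamed",
                character(1))
  # stored directions per gene; conflicts between sets mark the gene excluded
  union_genes <- sort(unique(unlist(lapply(sets, `[[`, "gene_id"))))
  dir_adc <- dir_scc <- stats::setNames(rep(NA_character_, length(union_genes)),
                                        union_genes)
  conflicted <- character(0)
  for (s in sets) {
    for (i in seq_len(nrow(s))) {
      g <- s$gene_id[i]
      if (is.na(dir_adc[g])) {
        dir_adc[g] <- s$dir_adc[i]
        dir_scc[g] <- s$dir_scc[i]
      } else if (dir_adc[g] != s$dir_adc[i] || dir_scc[g] != s$dir_scc[i]) {
        conflicted <- c(conflicted, g)
      }
    }
  }
  # cross-dataset consistency on unthresholded directions
  inconsistent <- character(0)
  if (!is.null(directions)) {
    for (ds in names(directions)) {
      tab <- directions[[ds]]
      for (g in union_genes) {
        # skip the check against the dataset(s) that contributed g
        from <- ids[vapply(sets, function(s) g %in% s$gene_id, logical(1))]
        if (ds %in% from) next
        da <- tab$ADC$direction[match(g, tab$ADC$gene_id)]
        dsn <- tab$SCC$direction[match(g, tab$SCC$gene_id)]
        if (is.na(da) && is.na(dsn)) next  # gene not measured there
        if (is.na(da) || is.na(dsn) ||
            da != dir_adc[g] || dsn != dir_scc[g])
          inconsistent <- c(inconsistent, g)
      }
    }
  }
  drop <- unique(c(conflicted, inconsistent))
  keep <- setdiff(union_genes, drop)
  out <- data.frame(gene_id = keep,
                    dir_adc = unname(dir_adc[keep]),
                    dir_scc = unname(dir_scc[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dataset_id") <- "integrated"
  attr(out, "excluded") <- sort(drop)
  attr(out, "source_datasets") <- ids
  class(out) <- c("opposite_gene_set", "data.frame")
  out
}

#' Write direction calls as TSV
#'
#' @param calls `direction_calls` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_direction_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
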
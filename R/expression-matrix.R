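#' @keywords internal
"_PACKAGE"

SUBTYPE_LABELS <- c("ADC", "SCC", "NORMAL", "UNKNOWN")

#' Construct an expression matrix with sample labels
#'
#' The central container of the package: a numeric gene-by-sample matrix on a
#' log-like scale, with unique gene and sample identifiers, a per-sample class
#' label in `{ADC, SCC, NORMAL, UNKNOWN}`, and a dataset identifier. No
#' normalization is applied anywhere in the package: every downstream statistic
#' uses only the ordering of values within one sample, so input is assumed to
#' be whatever (monotone-within-sample) scale the upstream pipeline produced.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Dimnames
#'   are used as `gene_ids`/`sample_ids` when those arguments are missing.
#' @param gene_ids character vector of unique, non-empty gene identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @param labels per-sample class labels; recycled `"UNKNOWN"` if `NULL`.
#'   May be a named vector (matched by sample id) or positional.
#' @param dataset_id single string naming the dataset (cohort accession etc.).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `labels`, `dataset_id`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
#'   labels = c("ADC", "SCC"))
#' dim(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              labels = NULL, dataset_id = "unnamed") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required (dimnames or arguments)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  if (anyDuplicated(gene_ids)) {
    d <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene id(s): ", paste(utils::head(d, 5), collapse = ", "))
  }
  if (any(!nzchar(gene_ids))) stop("empty gene id")
  if (anyDuplicated(sample_ids)) {
    d <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicated sample id(s): ", paste(utils::head(d, 5), collapse = ", "))
  }
  if (anyNA(values))
    stop("expression matrix contains missing values; ",
         "use read_expression(..., na_action = \"drop\") to drop such genes")
  if (is.null(labels)) {
    labels <- rep("UNKNOWN", length(sample_ids))
  } else if (!is.null(names(labels))) {
    full <- rep("UNKNOWN", length(sample_ids))
    hit <- match(sample_ids, names(labels))
    full[!is.na(hit)] <- as.character(labels)[hit[!is.na(hit)]]
    labels <- full
  } else {
    labels <- as.character(labels)
  }
  if (length(labels) != length(sample_ids))
    stop("length(labels) != number of samples")
  bad <- setdiff(unique(labels), SUBTYPE_LABELS)
  if (length(bad))
    stop("invalid label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(SUBTYPE_LABELS, collapse = ", "), ")")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels, dataset_id = as.character(dataset_id)[1]),
    class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$labels, levels = SUBTYPE_LABELS))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param m `ExpressionMatrix`.
#' @param genes,samples character vectors of identifiers, or indices; `NULL`
#'   keeps everything.
#' @return `ExpressionMatrix`.
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else {
    if (is.character(genes)) {
      miss <- setdiff(genes, m$gene_ids)
      if (length(miss)) stop("gene(s) not present: ", paste(miss, collapse = ", "))
      match(genes, m$gene_ids)
    } else genes
  }
  si <- if (is.null(samples)) seq_along(m$sample_ids) else {
    if (is.character(samples)) {
      miss <- setdiff(samples, m$sample_ids)
      if (length(miss)) stop("sample(s) not present: ", paste(miss, collapse = ", "))
      match(samples, m$sample_ids)
    } else samples
  }
  expression_matrix(m$values[gi, si, drop = FALSE],
                    m$gene_ids[gi], m$sample_ids[si],
                    m$labels[si], m$dataset_id)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV is the canonical format: a header row of sample ids, first column gene
#' identifiers, tab-separated numeric cells. The GCT v1.2 dialect (two header
#' lines `#1.2` / dimensions, then `Name`/`Description` columns) is accepted
#' read-only. Labels can be supplied as a two-column sidecar TSV
#' (`sample_id<TAB>label`) or a named vector; samples without a label default
#' to `UNKNOWN`.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"gct"`.
#' @param labels optional path to a label TSV, or a named character vector.
#' @param dataset_id dataset identifier stored on the result; defaults to the
#'   file name without extension.
#' @param na_action `"error"` (default) rejects files with missing values;
#'   `"drop"` removes gene rows containing any missing value. Values are never
#'   imputed.
#' @return `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("tsv", "gct"), labels = NULL,
                            dataset_id = NULL,
                            na_action = c("error", "drop")) {
  format <- match.arg(format)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (!startsWith(hdr[1], "#1.2"))
      stop("not a GCT v1.2 file (missing '#1.2' header): ", path)
    tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("GCT file has no sample columns: ", path)
    ids <- as.character(tab[[1]])
    sample_ids <- colnames(tab)[-c(1L, 2L)]  # before subsetting: data.frame
    tab <- tab[, -c(1L, 2L), drop = FALSE]   # subsetting de-duplicates names
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("expression TSV has no sample columns: ", path)
    ids <- as.character(tab[[1]])
    sample_ids <- colnames(tab)[-1L]
    tab <- tab[, -1L, drop = FALSE]
  }
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & !(col %in% c("NA", "")))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     col[bad[1]], ids[bad[1]], sample_ids[j]))
      tab[[j]] <- num
    }
  }
  values <- as.matrix(tab)
  if (anyNA(values)) {
    if (na_action == "error")
      stop("missing values in expression matrix (na_action = \"error\")")
    keep <- !apply(is.na(values), 1L, any)
    values <- values[keep, , drop = FALSE]
    ids <- ids[keep]
    if (!nrow(values)) stop("all gene rows dropped due to missing values")
  }
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- read_labels(labels)
  expression_matrix(values, ids, sample_ids, labels, dataset_id)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the TSV format; round trips are
#' value-identical up to numeric formatting (15 significant digits).
#'
#' @param m `ExpressionMatrix`.
#' @param path output file.
#' @param id_column header of the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(m$gene_ids, format(m$values, digits = 15, trim = TRUE,
                                      scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label TSV
#'
#' @param path TSV with columns `sample_id`, `label` (header optional but
#'   recommended).
#' @return named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file needs two columns: sample_id, label")
  # tolerate a headerless file whose first line is actually data
  if (!all(c(colnames(tab)[2]) %in% c("label", "Label", "class", "subtype")) &&
      colnames(tab)[2] %in% SUBTYPE_LABELS) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  }
  labs <- toupper(as.character(tab[[2]]))
  names(labs) <- as.character(tab[[1]])
  labs
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (`probe_id`, `gene_id`). A probe may appear on several rows
#' (multi-mapped) or with an empty gene id (unmapped); both are flagged for
#' removal by [collapse_probes()].
#'
#' @param path TSV file.
#' @return data.frame with character columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("probe map needs two columns: probe_id, gene_id")
  data.frame(probe_id = tab[[1]], gene_id = tab[[2]],
             stringsAsFactors = FALSE)
}

#' Collapse probe-level expression to gene level
#'
#' Probe measurements mapping to the same gene are averaged (arithmetic mean)
#' within each sample. Probes mapping to no gene, to an empty gene id, or to
#' more than one distinct gene are removed before averaging.
#'
#' @param m `ExpressionMatrix` whose rows are probes.
#' @param map probe map data.frame from [read_probe_map()], or any data.frame
#'   with columns `probe_id` and `gene_id`.
#' @return `ExpressionMatrix` keyed by gene.
#' @export
collapse_probes <- function(m, map) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!all(c("probe_id", "gene_id") %in% colnames(map)))
    stop("map must have columns probe_id, gene_id")
  map <- map[nzchar(map$gene_id) & !is.na(map$gene_id), , drop = FALSE]
  map <- unique(map)
  n_genes <- tapply(map$gene_id, map$probe_id, function(g) length(unique(g)))
  multi <- names(n_genes)[n_genes > 1L]
  map <- map[!(map$probe_id %in% multi), , drop = FALSE]
  keep <- m$gene_ids %in% map$probe_id
  if (!any(keep))
    stop("no probes left after removing unmapped/multi-mapped probes")
  vals <- m$values[keep, , drop = FALSE]
  genes <- map$gene_id[match(m$gene_ids[keep], map$probe_id)]
  gl <- sort(unique(genes))
  out <- rowsum(vals, group = genes, reorder = TRUE) /
    as.vector(table(factor(genes, levels = gl)))
  expression_matrix(out, gl, m$sample_ids, m$labels, m$dataset_id)
}
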
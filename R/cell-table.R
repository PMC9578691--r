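#' Cells-by-genes count table with per-cell metadata
#'
#' Wraps a nonnegative integer count matrix (cells in rows, genes in
#' columns) together with per-cell metadata. QC statistics — number of
#' detected features, total counts and mitochondrial fraction (genes whose
#' name starts with "mt-", case-insensitively) — are computed on
#' construction.
#'
#' @param counts cells x genes matrix of nonnegative counts.
#' @param gene_names,cell_ids optional dimension names (defaults taken from
#'   `dimnames(counts)`); gene names must be unique.
#' @param condition per-cell condition label (recycled if length 1).
#' @param annotation optional per-cell cell-state annotation.
#' @return A `cell_table`: list with `counts`, `gene_names`, `cell_ids`,
#'   `cell_meta` (data frame: `condition`, `annotation`, `n_features`,
#'   `total_counts`, `mito_fraction`).
#' @export
cell_table <- function(counts, gene_names = colnames(counts),
                       cell_ids = rownames(counts),
                       condition = NA_character_, annotation = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- nrow(counts); g <- ncol(counts)
  if (is.null(gene_names)) gene_names <- sprintf("gene_%d", seq_len(g))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  gene_names <- as.character(gene_names); cell_ids <- as.character(cell_ids)
  if (length(gene_names) != g || length(cell_ids) != n)
    stop("dimension names inconsistent with the count matrix", call. = FALSE)
  if (anyDuplicated(gene_names))
    stop("gene names must be unique", call. = FALSE)
  dimnames(counts) <- list(cell_ids, gene_names)
  total <- rowSums(counts)
  mito <- grepl("^mt-", gene_names, ignore.case = TRUE)
  meta <- data.frame(
    condition = rep_len(as.character(condition), n),
    annotation = if (is.null(annotation)) rep(NA_character_, n)
                 else rep_len(as.character(annotation), n),
    n_features = as.integer(rowSums(counts > 0)),
    total_counts = total,
    mito_fraction = ifelse(total > 0, rowSums(counts[, mito, drop = FALSE]) / total, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = counts, gene_names = gene_names,
                 cell_ids = cell_ids, cell_meta = meta),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table: %d cells x %d genes; conditions: %s>\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cell_meta$condition), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

# subset cells, preserving order and metadata
subset_cells <- function(table, keep) {
  ct <- cell_table(table$counts[keep, , drop = FALSE],
                   gene_names = table$gene_names,
                   cell_ids = table$cell_ids[keep],
                   condition = table$cell_meta$condition[keep],
                   annotation = table$cell_meta$annotation[keep])
  ct
}
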
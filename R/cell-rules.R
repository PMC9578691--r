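#' Standard single-cell quality-control filter
#'
#' Keeps cells with `min_features <= n_features <= max_features` and a
#' mitochondrial fraction at most `max_mito` (the bounds themselves are
#' kept: only cells with fewer than 200 or more than 2500 features, or a
#' mitochondrial fraction above 5%, are removed under the defaults). Cell
#' order is preserved.
#'
#' @param table a [cell_table()].
#' @param min_features,max_features bounds on per-cell detected features.
#' @param max_mito maximum mitochondrial fraction.
#' @return list with `table` (filtered [cell_table()]) and `report`, a
#'   per-cell data frame (`cell_id`, QC stats, `kept`).
#' @export
qc_filter <- function(table, min_features = 200, max_features = 2500,
                      max_mito = 0.05) {
  stopifnot(inherits(table, "cell_table"))
  if (nrow(table$counts) == 0L) stop("empty cell table", call. = FALSE)
  m <- table$cell_meta
  kept <- m$n_features >= min_features & m$n_features <= max_features &
    m$mito_fraction <= max_mito
  report <- data.frame(cell_id = table$cell_ids, n_features = m$n_features,
                       total_counts = m$total_counts,
                       mito_fraction = m$mito_fraction, kept = kept,
                       stringsAsFactors = FALSE)
  list(table = subset_cells(table, kept), report = report)
}

#' Filter lowly expressed genes by counts per million
#'
#' CPM is each count divided by its sample's total, times one million. A
#' gene is kept iff its CPM is strictly greater than `min_cpm` in at least
#' `min_samples` samples.
#'
#' @param counts samples x genes count matrix (bulk samples in rows).
#' @param min_cpm CPM threshold (strict inequality).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return Character vector of kept gene names (column indices if the
#'   matrix has no column names).
#' @export
cpm_filter <- function(counts, min_cpm = 0.4, min_samples = 2) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- if (!is.null(rownames(counts))) rownames(counts)[totals == 0]
           else which(totals == 0)
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cpm <- counts / totals * 1e6
  keep <- colSums(cpm > min_cpm) >= min_samples
  if (!is.null(colnames(counts))) colnames(counts)[keep]
  else as.character(which(keep))
}

expressed_matrix <- function(table, rules) {
  table$counts >= rules$expressed_threshold
}

#' Hox / brain-like / spinal-cord-like neural categorization
#'
#' Sequential rule precedence: (1) a cell expressing at least one Hox gene
#' of the rule set's subset is `hox_positive`; (2) otherwise, a cell
#' expressing at least `brain_min_markers` fore/midbrain markers and not
#' expressing the spinal-cord exclusion gene is `brain_like`; (3) all
#' remaining cells are `spinal_like`. Every cell receives exactly one
#' label.
#'
#' @param table a [cell_table()].
#' @param rules a [rule_set()]; all its genes must be present in the table.
#' @return Factor of labels (`hox_positive`, `brain_like`, `spinal_like`),
#'   one per cell.
#' @export
classify_neural <- function(table, rules) {
  stopifnot(inherits(table, "cell_table"), inherits(rules, "rule_set"))
  resolve_genes(c(rules$hox_genes, rules$brain_markers,
                  rules$spinal_exclusion_gene), table$gene_names, "neural rule")
  expr <- expressed_matrix(table, rules)
  hox_any <- rowSums(expr[, rules$hox_genes, drop = FALSE]) > 0
  brain_n <- rowSums(expr[, rules$brain_markers, drop = FALSE])
  excl <- expr[, rules$spinal_exclusion_gene]
  lab <- ifelse(hox_any, "hox_positive",
                ifelse(brain_n >= rules$brain_min_markers & !excl,
                       "brain_like", "spinal_like"))
  factor(lab, levels = c("hox_positive", "brain_like", "spinal_like"))
}

#' Dorsal / midline / ventral module assignment
#'
#' A cell is assigned to a dorsal-ventral module iff it expresses at least
#' one of that module's genes and none of the other two modules' genes;
#' cells matching zero or two or more modules are `unassigned`. The
#' fraction of assigned cells is attached as attribute
#' `assigned_fraction`.
#'
#' @inheritParams classify_neural
#' @return Factor with levels `dorsal`, `midline`, `ventral`, `unassigned`.
#' @export
classify_dv <- function(table, rules) {
  stopifnot(inherits(table, "cell_table"), inherits(rules, "rule_set"))
  mods <- rules$dv_modules
  if (!length(mods)) stop("rule set has no dorsal-ventral modules", call. = FALSE)
  if (anyDuplicated(unlist(mods)))
    stop("configuration error: dorsal/midline/ventral gene lists overlap", call. = FALSE)
  resolve_genes(unlist(mods), table$gene_names, "dorsal-ventral rule")
  expr <- expressed_matrix(table, rules)
  hits <- vapply(mods, function(g) rowSums(expr[, g, drop = FALSE]) > 0,
                 logical(nrow(table$counts)))
  hits <- matrix(hits, ncol = length(mods), dimnames = list(NULL, names(mods)))
  n_mod <- rowSums(hits)
  lab <- rep("unassigned", nrow(hits))
  one <- n_mod == 1
  lab[one] <- colnames(hits)[max.col(hits[one, , drop = FALSE])]
  out <- factor(lab, levels = c("dorsal", "midline", "ventral", "unassigned"))
  attr(out, "assigned_fraction") <- mean(out != "unassigned")
  out
}

#' Differential cell-type abundance between conditions
#'
#' For each cell state, the per-condition proportion is its cell count
#' divided by that condition's total cell count. The result reports, for
#' every non-reference condition, log2(proportion / reference proportion).
#' States with fewer than `min_cells` cells in total across all conditions
#' are excluded; a state absent from exactly one side yields an infinite
#' log-ratio, which is kept and flagged rather than dropped.
#'
#' @param annotations per-cell cell-state labels.
#' @param conditions per-cell condition labels (same length).
#' @param reference_condition condition used as the denominator.
#' @param min_cells minimum total cells across conditions for a state to
#'   be reported.
#' @return data frame: `state`, `condition`, `n_state`, `prop`,
#'   `prop_reference`, `log2_ratio`, `infinite` flag.
#' @export
relative_abundance <- function(annotations, conditions, reference_condition,
                               min_cells = 10) {
  annotations <- as.character(annotations); conditions <- as.character(conditions)
  stopifnot(length(annotations) == length(conditions))
  if (!reference_condition %in% conditions)
    stop(sprintf("reference condition '%s' has no cells", reference_condition),
         call. = FALSE)
  states <- sort(unique(annotations))
  totals <- table(factor(annotations, levels = states))
  states <- states[totals[states] >= min_cells]
  cond_n <- table(conditions)
  other <- setdiff(unique(conditions), reference_condition)
  ref_n <- cond_n[[reference_condition]]
  out <- do.call(rbind, lapply(other, function(cc) {
    do.call(rbind, lapply(states, function(s) {
      n_s <- sum(annotations == s & conditions == cc)
      n_r <- sum(annotations == s & conditions == reference_condition)
      p <- n_s / cond_n[[cc]]
      pr <- n_r / ref_n
      lr <- log2(p / pr)
      data.frame(state = s, condition = cc, n_state = n_s, prop = p,
                 prop_reference = pr, log2_ratio = lr,
                 infinite = is.infinite(lr) || is.nan(lr),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Pseudo-bulk mean expression per group
#'
#' Averages expression over cells within each group defined by one or more
#' metadata keys (e.g. condition and annotation). Expression is either raw
#' counts or, by default, counts scaled to 10,000 per cell and log1p
#' transformed (log-normalization).
#'
#' @param table a [cell_table()].
#' @param group_keys metadata column names to group by.
#' @param normalize `"lognorm"` (counts per 10k, log1p) or `"raw"`.
#' @return Numeric matrix, groups x genes; group names join the key values
#'   with "_".
#' @export
pseudo_bulk <- function(table, group_keys = "condition",
                        normalize = c("lognorm", "raw")) {
  stopifnot(inherits(table, "cell_table"))
  normalize <- match.arg(normalize)
  missing_keys <- setdiff(group_keys, colnames(table$cell_meta))
  if (length(missing_keys))
    stop(sprintf("unknown group key(s): %s", paste(missing_keys, collapse = ", ")),
         call. = FALSE)
  if (nrow(table$counts) == 0L) stop("empty cell table", call. = FALSE)
  x <- table$counts
  if (normalize == "lognorm") {
    totals <- pmax(table$cell_meta$total_counts, 1)
    x <- log1p(x / totals * 1e4)
  }
  g <- interaction(table$cell_meta[group_keys], drop = TRUE, sep = "_")
  sums <- rowsum(x, g)
  sums / as.vector(table(g)[rownames(sums)])
}
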
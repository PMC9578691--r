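#' Parameters for the synthetic single-cell count generator
#'
#' @param n_cells_per_class named integer vector over the classes
#'   `hox_positive`, `brain_like`, `spinal_like`, `dorsal`, `midline`,
#'   `ventral`, `background` (any subset; unknown names are an error).
#' @param marker_mean_expression expected count of an "on" marker before
#'   dropout (>= 1).
#' @param dropout_rate probability in [0, 1) that an "on" marker reads 0.
#' @param library_noise coefficient of variation of a per-cell gamma
#'   library-size factor (0 disables it).
#' @param seed integer RNG seed.
#' @param n_background_genes number of non-marker genes expressed at a low
#'   level in every cell; when >= 2, the first two are named with an "mt-"
#'   prefix so that mitochondrial QC statistics are exercised.
#' @param background_mean expected count of a background gene.
#' @param condition condition label stamped on every cell.
#' @return A list of class `cell_sim_params`.
#' @export
cell_sim_params <- function(n_cells_per_class, marker_mean_expression = 5,
                            dropout_rate = 0, library_noise = 0, seed = 1,
                            n_background_genes = 20, background_mean = 0.3,
                            condition = "sim") {
  known <- c("hox_positive", "brain_like", "spinal_like", "dorsal",
             "midline", "ventral", "background")
  if (is.null(names(n_cells_per_class)) ||
      !all(names(n_cells_per_class) %in% known))
    stop(sprintf("unknown class name(s) in n_cells_per_class (allowed: %s)",
                 paste(known, collapse = ", ")), call. = FALSE)
  if (any(n_cells_per_class < 0)) stop("cell counts must be >= 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (marker_mean_expression < 1)
    stop("marker_mean_expression must be >= 1", call. = FALSE)
  structure(list(n_cells_per_class = n_cells_per_class,
                 marker_mean_expression = marker_mean_expression,
                 dropout_rate = dropout_rate, library_noise = library_noise,
                 seed = as.integer(seed),
                 n_background_genes = as.integer(n_background_genes),
                 background_mean = background_mean,
                 condition = as.character(condition)),
            class = "cell_sim_params")
}

# the marker genes a planted class switches "on"
class_on_markers <- function(class, rules) {
  switch(class,
         hox_positive = rules$hox_genes,
         brain_like   = rules$brain_markers,
         spinal_like  = rules$spinal_exclusion_gene,
         dorsal       = rules$dv_modules$dorsal,
         midline      = rules$dv_modules$midline,
         ventral      = rules$dv_modules$ventral,
         background   = character(0))
}

#' Simulate a marker-structured single-cell count table with known labels
#'
#' Each cell of a planted class expresses all of that class's "on" markers
#' (Hox genes for `hox_positive`, fore/midbrain markers for `brain_like`,
#' the spinal exclusion gene for `spinal_like`, the respective
#' dorsal-ventral module genes for `dorsal`/`midline`/`ventral`) and none
#' of the other classes' markers. An "on" marker count is drawn as
#' 1 + Poisson(m·f − 1), where m is `marker_mean_expression` and f a
#' per-cell gamma library factor — the mean is exactly m·f and the count is
#' guaranteed nonzero — and is then zeroed with probability `dropout_rate`.
#' Background genes receive low Poisson counts in every cell. The RNG is
#' consumed per class block (library factors, marker counts, dropout mask)
#' and then for background counts, so identical parameters and seed give
#' identical tables.
#'
#' @param params a [cell_sim_params()].
#' @param rules a [rule_set()] supplying the marker lists.
#' @return list with `table` (a [cell_table()]) and `labels` (factor of
#'   planted classes, one per cell).
#' @export
simulate_cell_table <- function(params, rules = default_rules()) {
  stopifnot(inherits(params, "cell_sim_params"), inherits(rules, "rule_set"))
  p <- params
  classes <- names(p$n_cells_per_class)
  marker_genes <- unique(unlist(lapply(
    c("hox_positive", "brain_like", "spinal_like", "dorsal", "midline", "ventral"),
    class_on_markers, rules = rules)))
  bg_genes <- character(0)
  if (p$n_background_genes > 0) {
    bg_genes <- sprintf("bg_%02d", seq_len(p$n_background_genes))
    if (p$n_background_genes >= 2)
      bg_genes[1:2] <- c("mt-Nd1", "mt-Co1")
  }
  genes <- c(marker_genes, bg_genes)
  n_total <- sum(p$n_cells_per_class)
  counts <- matrix(0L, n_total, length(genes), dimnames = list(NULL, genes))
  labels <- character(n_total)

  with_seed(p$seed, {
    row0 <- 0L
    for (cl in classes) {
      n <- p$n_cells_per_class[[cl]]
      if (n == 0) next
      idx <- row0 + seq_len(n)
      labels[idx] <- cl
      on <- class_on_markers(cl, rules)
      f <- if (p$library_noise > 0) {
        shp <- 1 / p$library_noise^2
        rgamma(n, shape = shp, rate = shp)
      } else rep(1, n)
      if (length(on)) {
        lam <- pmax(outer(f * p$marker_mean_expression, rep(1, length(on))) - 1, 0)
        cnt <- 1L + matrix(rpois(n * length(on), lam), n, length(on))
        if (p$dropout_rate > 0) {
          drop <- matrix(runif(n * length(on)) < p$dropout_rate, n, length(on))
          cnt[drop] <- 0L
        }
        counts[idx, on] <- cnt
      }
      row0 <- row0 + n
    }
    if (length(bg_genes) && n_total > 0) {
      counts[, bg_genes] <- matrix(
        rpois(n_total * length(bg_genes), p$background_mean),
        n_total, length(bg_genes))
    }
  })

  ids <- if (n_total > 0) sprintf("%s_%04d", labels, seq_len(n_total)) else character(0)
  tab <- cell_table(counts, gene_names = genes, cell_ids = ids,
                    condition = p$condition, annotation = labels)
  list(table = tab,
       labels = factor(labels, levels = unique(c(classes, unique(labels)))))
}
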
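#' Marker-gene rule set for cell categorization
#'
#' Bundles the marker lists and thresholds that drive the rule-based
#' classifiers: a Hox gene subset (any expressed gene assigns the Hox
#' code), fore/midbrain markers with a minimum-count rule and a spinal-cord
#' exclusion gene, and mutually exclusive dorsal / midline / ventral
#' modules. A gene is "expressed" when its raw count is at least
#' `expressed_threshold`.
#'
#' The shipped default lists (see [default_rules()]) are populated from
#' standard mouse gene nomenclature and are meant to be replaced with the
#' user's own curated lists for real analyses.
#'
#' @param hox_genes character vector of Hox genes (conventionally 28).
#' @param brain_markers fore/midbrain marker genes (conventionally the top
#'   30 in vivo markers).
#' @param brain_min_markers minimum number of expressed brain markers
#'   (default 5).
#' @param spinal_exclusion_gene spinal-cord marker whose expression vetoes
#'   a brain-like call (default "Fgfbp3").
#' @param dv_modules named list with elements `dorsal`, `midline`,
#'   `ventral`: non-overlapping gene lists.
#' @param expressed_threshold minimum count for a gene to count as
#'   expressed (default 1, i.e. count > 0).
#' @return A `rule_set` object.
#' @export
rule_set <- function(hox_genes, brain_markers, brain_min_markers = 5,
                     spinal_exclusion_gene = "Fgfbp3",
                     dv_modules = list(), expressed_threshold = 1) {
  if (brain_min_markers > length(brain_markers))
    stop("brain_min_markers exceeds the number of brain markers", call. = FALSE)
  if (length(dv_modules)) {
    if (!all(c("dorsal", "midline", "ventral") %in% names(dv_modules)))
      stop("dv_modules must name dorsal, midline and ventral lists", call. = FALSE)
    all_dv <- unlist(dv_modules, use.names = FALSE)
    if (anyDuplicated(all_dv))
      stop("dorsal/midline/ventral gene lists must not overlap", call. = FALSE)
  }
  structure(list(hox_genes = as.character(hox_genes),
                 brain_markers = as.character(brain_markers),
                 brain_min_markers = as.integer(brain_min_markers),
                 spinal_exclusion_gene = as.character(spinal_exclusion_gene),
                 dv_modules = lapply(dv_modules, as.character),
                 expressed_threshold = expressed_threshold),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf(paste0("<rule_set: %d Hox genes; %d brain markers (>= %d, ",
                     "excluding %s); DV modules: %s; expressed = count >= %s>\n"),
              length(x$hox_genes), length(x$brain_markers),
              x$brain_min_markers, x$spinal_exclusion_gene,
              if (length(x$dv_modules))
                paste(sprintf("%s (%d)", names(x$dv_modules),
                              lengths(x$dv_modules)), collapse = ", ")
              else "none", x$expressed_threshold))
  invisible(x)
}

#' Default rule set shipped with the package
#'
#' Reads `extdata/rules/default_rules.yaml`: a 28-gene mouse Hox subset,
#' 30 fore/midbrain markers, the Fgfbp3 spinal exclusion, and three-gene
#' dorsal / midline / ventral modules. These are placeholders drawn from
#' standard mouse nomenclature — replace them with curated lists for any
#' real dataset.
#'
#' @return A `rule_set`.
#' @export
default_rules <- function() {
  read_rules(system.file("extdata", "rules", "default_rules.yaml",
                         package = "gastruquant", mustWork = TRUE))
}

#' Read / write a rule set as YAML
#'
#' @param path YAML file with keys `hox_genes`, `brain_markers`,
#'   `brain_min_markers`, `spinal_exclusion_gene`, `dv_modules`
#'   (dorsal/midline/ventral), `expressed_threshold`.
#' @return `read_rules`: a `rule_set`. `write_rules`: the path, invisibly.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rule_set(hox_genes = y$hox_genes, brain_markers = y$brain_markers,
           brain_min_markers = y$brain_min_markers %||% 5,
           spinal_exclusion_gene = y$spinal_exclusion_gene %||% "Fgfbp3",
           dv_modules = y$dv_modules %||% list(),
           expressed_threshold = y$expressed_threshold %||% 1)
}

#' @rdname read_rules
#' @param rules a `rule_set`.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  atomic_write(path, function(tmp) yaml::write_yaml(unclass(rules), tmp))
  invisible(path)
}

# all rule genes must exist in the table's gene names
resolve_genes <- function(genes, gene_names, what) {
  missing <- setdiff(genes, gene_names)
  if (length(missing))
    stop(sprintf("configuration error: %s gene(s) not in table: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  genes
}
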
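# Shared fixtures: rasterized shapes with analytic ground truth, toy count
# tables, and brute-force oracles kept deliberately independent of the
# package's own code paths.

# label raster containing one filled shape (value 1) on background 0
raster_disk <- function(radius_px, pad = 4) {
  n <- 2 * (radius_px + pad) + 1
  ctr <- (n - 1) / 2
  m <- matrix(0L, n, n)
  m[(row(m) - 1 - ctr)^2 + (col(m) - 1 - ctr)^2 <= radius_px^2] <- 1L
  m
}

raster_square <- function(side_px, pad = 4) {
  n <- side_px + 2 * pad
  m <- matrix(0L, n, n)
  m[pad + seq_len(side_px), pad + seq_len(side_px)] <- 1L
  m
}

raster_ellipse <- function(a_px, b_px, pad = 4) {
  nr <- 2 * (b_px + pad) + 1; nc <- 2 * (a_px + pad) + 1
  r0 <- (nr - 1) / 2; c0 <- (nc - 1) / 2
  m <- matrix(0L, nr, nc)
  m[((col(m) - 1 - c0) / a_px)^2 + ((row(m) - 1 - r0) / b_px)^2 <= 1] <- 1L
  m
}

# an axial_profile built directly from positions/values (unit test entry
# into bin_profile without going through image extraction)
make_profile <- function(rel, reporter, dapi = rep(1, length(rel)), length_um = 100) {
  structure(list(structure_id = 1L,
                 samples = data.frame(absolute_position = rel * length_um,
                                      reporter = reporter, dapi = dapi),
                 length = length_um,
                 relative_positions = rel),
            class = "axial_profile")
}

# small random count table with controllable QC stats
random_cell_table <- function(n_cells, n_genes = 30, max_count = 6,
                              mito_genes = 2, condition = "c1") {
  genes <- c(if (mito_genes > 0) paste0("mt-g", seq_len(mito_genes)),
             paste0("g", seq_len(n_genes - mito_genes)))
  counts <- matrix(rpois(n_cells * n_genes, 1.2) *
                     (matrix(runif(n_cells * n_genes), n_cells) < 0.6),
                   n_cells, n_genes)
  counts <- pmin(counts, max_count)
  cell_table(counts, gene_names = genes,
             cell_ids = paste0("c", seq_len(n_cells)), condition = condition)
}

# brute-force QC scan: per-cell loop applying the three rules literally
oracle_qc_keep <- function(counts, gene_names, min_f, max_f, max_mito) {
  vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    nf <- sum(x > 0)
    tot <- sum(x)
    mito <- if (tot > 0)
      sum(x[grepl("^mt-", gene_names, ignore.case = TRUE)]) / tot else 0
    nf >= min_f && nf <= max_f && mito <= max_mito
  }, logical(1))
}

# brute-force CPM filter: per-gene loop
oracle_cpm_keep <- function(counts, min_cpm, min_samples) {
  vapply(seq_len(ncol(counts)), function(j) {
    over <- 0
    for (i in seq_len(nrow(counts)))
      if (counts[i, j] / sum(counts[i, ]) * 1e6 > min_cpm) over <- over + 1
    over >= min_samples
  }, logical(1))
}

# brute-force abundance: explicit counting of proportions
oracle_log2_ratio <- function(ann, cond, state, condition, reference) {
  p <- sum(ann == state & cond == condition) / sum(cond == condition)
  pr <- sum(ann == state & cond == reference) / sum(cond == reference)
  log2(p / pr)
}

# toy rule set small enough to enumerate by hand
toy_rules <- function(expressed_threshold = 1) {
  rule_set(hox_genes = c("HoxA", "HoxB"),
           brain_markers = paste0("Br", 1:6), brain_min_markers = 3,
           spinal_exclusion_gene = "Fgfbp3",
           dv_modules = list(dorsal = c("D1", "D2"), midline = c("M1", "M2"),
                             ventral = c("V1", "V2")),
           expressed_threshold = expressed_threshold)
}

# cell table over the toy rule gene universe from an explicit matrix
toy_table <- function(mat, condition = "c1") {
  genes <- c("HoxA", "HoxB", paste0("Br", 1:6), "Fgfbp3",
             "D1", "D2", "M1", "M2", "V1", "V2")
  stopifnot(ncol(mat) == length(genes))
  cell_table(mat, gene_names = genes,
             cell_ids = paste0("cell", seq_len(nrow(mat))),
             condition = condition)
}
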
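test_that("QC keeps the stated feature and mito windows, bounds inclusive", {
  counts <- matrix(0L, 4, 3000,
                   dimnames = list(paste0("c", 1:4), paste0("g", 1:3000)))
  counts[1, 1:150] <- 1L    # 150 features: below the window
  counts[2, 1:200] <- 1L    # exactly 200: kept
  counts[3, 1:2500] <- 1L   # exactly 2500: kept
  counts[4, 1:2501] <- 1L   # 2501: above the window
  tab <- cell_table(counts)
  res <- qc_filter(tab)
  expect_identical(res$report$kept, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(res$table$cell_ids, c("c2", "c3"))

  genes <- c("mt-Nd1", paste0("g", 1:399))
  m2 <- matrix(1L, 2, 400, dimnames = list(c("a", "b"), genes))
  m2[1, 1] <- 21L           # 21 / 420 = 5% mito exactly: kept
  m2[2, 1] <- 22L           # above 5%: dropped
  res2 <- qc_filter(cell_table(m2))
  expect_identical(res2$report$kept, c(TRUE, FALSE))
  expect_error(qc_filter(cell_table(matrix(0L, 0, 5))), "empty")
})

test_that("QC agrees with an independent brute-force scan on random tables", {
  set.seed(61)
  for (i in 1:20) {
    tab <- random_cell_table(50, n_genes = 40)
    got <- qc_filter(tab, min_features = 10, max_features = 25, max_mito = 0.1)
    want <- oracle_qc_keep(tab$counts, tab$gene_names, 10, 25, 0.1)
    expect_identical(got$report$kept, want)
    expect_identical(got$table$cell_ids, tab$cell_ids[want])  # order preserved
  }
})

test_that("CPM filter uses a strict threshold and flags zero-total samples", {
  counts <- matrix(c(0, 0, 0,        # all-zero gene: dropped
                     2, 2, 2,        # ~0.4 CPM in all samples
                     10, 10, 10),    # 2 CPM everywhere: kept
                   nrow = 3, dimnames = list(paste0("s", 1:3), c("gz", "gb", "gk")))
  filler <- matrix(c(5e6, 5e6, 5e6) - rowSums(counts), 3, 1,
                   dimnames = list(NULL, "filler"))
  m <- cbind(counts, filler)
  boundary_cpm <- 2 / 5e6 * 1e6               # the value 'gb' attains
  keep <- cpm_filter(m, min_cpm = boundary_cpm, min_samples = 2)
  expect_false("gb" %in% keep)                # equal to threshold: dropped
  expect_false("gz" %in% keep)
  expect_true("gk" %in% keep)
  expect_false("gb" %in% cpm_filter(m, min_cpm = 0.4, min_samples = 2))

  bad <- rbind(m, s4 = 0)
  expect_error(cpm_filter(bad), "s4")
})

test_that("CPM filter matches a brute-force recomputation on random tables", {
  set.seed(62)
  for (i in 1:20) {
    m <- matrix(rpois(6 * 30, 3), 6, 30,
                dimnames = list(paste0("s", 1:6), paste0("g", 1:30)))
    m[, 1] <- m[, 1] + 1                     # ensure no zero-total sample
    keep <- cpm_filter(m, min_cpm = 0.4, min_samples = 2)
    want <- colnames(m)[oracle_cpm_keep(m, 0.4, 2)]
    expect_identical(keep, want)
  }
})

test_that("neural categorization follows Hox > brain > spinal precedence", {
  rules <- toy_rules()
  g <- function(...) {
    x <- rep(0, 15); x[c(...)] <- 3; x  # gene order: HoxA HoxB Br1-6 Fgfbp3 D M V
  }
  mat <- rbind(
    g(1, 3:8),      # one Hox + all brain markers -> hox wins by precedence
    g(3:8),         # 6 brain markers, no Fgfbp3 -> brain_like
    g(3:8, 9),      # 6 brain markers but Fgfbp3 expressed -> spinal_like
    g(3, 4),        # only 2 brain markers (< 3) -> spinal_like
    rep(0, 15)      # all-zero cell -> spinal_like (remainder rule)
  )
  lab <- classify_neural(toy_table(mat), rules)
  expect_identical(as.character(lab),
                   c("hox_positive", "brain_like", "spinal_like",
                     "spinal_like", "spinal_like"))
  expect_identical(sum(table(lab)), 5L)      # every cell labelled exactly once
})

test_that("dorsal-ventral assignment is mutually exclusive", {
  rules <- toy_rules()
  g <- function(...) { x <- rep(0, 15); x[c(...)] <- 1; x }
  mat <- rbind(
    g(14),          # V1 only -> ventral
    g(10),          # D1 only -> dorsal
    g(12, 13),      # both midline genes -> midline
    g(10, 14),      # dorsal + ventral -> unassigned
    rep(0, 15)      # no module genes -> unassigned
  )
  lab <- classify_dv(toy_table(mat), rules)
  expect_identical(as.character(lab),
                   c("ventral", "dorsal", "midline", "unassigned", "unassigned"))
  expect_equal(attr(lab, "assigned_fraction"), 3 / 5)
  expect_identical(sum(lab != "unassigned") + sum(lab == "unassigned"), 5L)

  expect_error(
    rule_set(hox_genes = "HoxA", brain_markers = paste0("Br", 1:6),
             brain_min_markers = 3,
             dv_modules = list(dorsal = "D1", midline = "D1", ventral = "V1")),
    "must not overlap")
})

test_that("rule genes missing from the table raise a configuration error", {
  tab <- cell_table(matrix(1, 2, 2), gene_names = c("a", "b"))
  expect_error(classify_neural(tab, toy_rules()), "configuration error")
  expect_error(classify_dv(tab, toy_rules()), "configuration error")
})

test_that("planted labels are recovered exactly without dropout", {
  rules <- default_rules()
  sim <- simulate_cell_table(cell_sim_params(
    c(hox_positive = 40, brain_like = 40, spinal_like = 40,
      dorsal = 25, midline = 25, ventral = 25),
    dropout_rate = 0, seed = 71), rules)
  truth <- as.character(sim$labels)
  neural <- truth %in% c("hox_positive", "brain_like", "spinal_like")
  dv <- truth %in% c("dorsal", "midline", "ventral")
  nl <- as.character(classify_neural(sim$table, rules))
  dl <- as.character(classify_dv(sim$table, rules))
  expect_identical(nl[neural], truth[neural])
  expect_identical(dl[dv], truth[dv])
})

test_that("dropout can only reduce neural recovery accuracy", {
  rules <- default_rules()
  acc <- function(dropout, seed) {
    sim <- simulate_cell_table(cell_sim_params(
      c(hox_positive = 25, brain_like = 25, spinal_like = 25),
      dropout_rate = dropout, marker_mean_expression = 3, seed = seed), rules)
    mean(as.character(classify_neural(sim$table, rules)) ==
           as.character(sim$labels))
  }
  a0 <- mean(vapply(1:20, function(s) acc(0, s), numeric(1)))
  a3 <- mean(vapply(1:20, function(s) acc(0.3, s), numeric(1)))
  expect_identical(a0, 1)
  expect_gte(a0, a3)
})

test_that("abundance ratios reproduce closed-form and brute-force values", {
  ann <- c(rep("A", 10), rep("B", 10), rep("A", 5), rep("B", 10), rep("C", 5))
  cond <- c(rep("ref", 20), rep("alt", 20))
  res <- relative_abundance(ann, cond, "ref", min_cells = 1)
  # state A: 5/20 vs 10/20 -> log2(0.5) = -1; state B: 10/20 vs 10/20 -> 0
  expect_equal(res$log2_ratio[res$state == "A"], -1)
  expect_equal(res$log2_ratio[res$state == "B"], 0)
  # state C: absent in the reference -> +Inf, flagged, not dropped
  expect_true(is.infinite(res$log2_ratio[res$state == "C"]))
  expect_true(res$infinite[res$state == "C"])

  set.seed(63)
  for (i in 1:10) {
    ann <- sample(LETTERS[1:4], 120, replace = TRUE)
    cond <- sample(c("ref", "x", "y"), 120, replace = TRUE)
    res <- relative_abundance(ann, cond, "ref", min_cells = 1)
    for (j in seq_len(nrow(res)))
      expect_equal(res$log2_ratio[j],
                   oracle_log2_ratio(ann, cond, res$state[j], res$condition[j], "ref"))
  }
})

test_that("rare states are excluded and duplication leaves ratios unchanged", {
  ann <- c(rep("common", 30), rep("rare", 6))
  cond <- rep(c("ref", "alt"), 18)
  res <- relative_abundance(ann, cond, "alt", min_cells = 10)
  expect_false("rare" %in% res$state)      # 6 < 10 cells across conditions
  res1 <- relative_abundance(ann, cond, "alt", min_cells = 1)
  res2 <- relative_abundance(rep(ann, 2), rep(cond, 2), "alt", min_cells = 1)
  expect_equal(res1$log2_ratio, res2$log2_ratio)
  expect_error(relative_abundance(ann, cond, "missing"), "no cells")
})

test_that("pseudo-bulk means equal brute-force group means", {
  counts <- matrix(c(2, 4, 6, 0, 1, 5), 3, 2,
                   dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  tab <- cell_table(counts, condition = c("a", "a", "b"))
  pb <- pseudo_bulk(tab, "condition", normalize = "raw")
  expect_equal(unname(pb["a", "g1"]), 3)    # mean of 2 and 4
  expect_equal(unname(pb["b", ]), c(6, 5))  # single-cell group: the cell itself

  sim <- simulate_cell_table(cell_sim_params(
    c(brain_like = 15, ventral = 10), seed = 8))
  tab2 <- sim$table
  pb2 <- pseudo_bulk(tab2, c("condition", "annotation"))
  norm <- log1p(tab2$counts / pmax(tab2$cell_meta$total_counts, 1) * 1e4)
  grp <- paste(tab2$cell_meta$condition, tab2$cell_meta$annotation, sep = "_")
  for (g in unique(grp))
    expect_equal(unname(pb2[g, ]), unname(colMeans(norm[grp == g, , drop = FALSE])))
  expect_error(pseudo_bulk(tab2, "nope"), "unknown group key")
})
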
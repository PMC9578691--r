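#' Run a full synthetic-data analysis pipeline from a configuration
#'
#' Two stage chains are available. `pipeline: image` simulates `n_structures`
#' gastruloid images, segments each, measures morphometry, extracts and bins
#' the A-P reporter profile and clusters the binned profiles
#' (simulate -> morphometry -> profile -> cluster). `pipeline: cells`
#' simulates one count table per configured condition, applies QC, runs the
#' neural and dorsal-ventral classifiers and computes differential
#' cell-type abundance against a reference condition. All outputs are
#' staged in a temporary directory and moved into `out_dir` only on
#' success, together with a JSON run manifest recording parameters, seed,
#' package version and the MD5 hash of every output file.
#'
#' @param config a named list, or the path to a YAML file encoding one.
#'   Common keys: `pipeline` ("image" or "cells"), `seed`, `out_dir`.
#'   Image chain: `n_structures`, `polarized_fraction`, `k`, plus any
#'   [image_sim_params()] argument under `image_params`. Cells chain:
#'   `conditions` (named list: condition -> named class-count list),
#'   `reference_condition`, plus any [cell_sim_params()] argument under
#'   `cell_params`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  pipeline <- config$pipeline %||% stop("config must set `pipeline`", call. = FALSE)
  out_dir <- config$out_dir %||% stop("config must set `out_dir`", call. = FALSE)
  seed <- as.integer(config$seed %||% stop("config must set `seed`", call. = FALSE))
  stage_dir <- tempfile("gastruquant_stage_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)

  stages <- switch(pipeline,
                   image = pipeline_image(config, seed, stage_dir),
                   cells = pipeline_cells(config, seed, stage_dir),
                   stop(sprintf("unknown pipeline '%s'", pipeline), call. = FALSE))

  outputs <- list.files(stage_dir, recursive = TRUE)
  manifest <- list(pipeline = pipeline, seed = seed,
                   parameters = config,
                   package_version = as.character(utils::packageVersion("gastruquant")),
                   stages = stages,
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(stage_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage_dir, recursive = TRUE)) {
    dir.create(dirname(file.path(out_dir, f)), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(stage_dir, f), file.path(out_dir, f), overwrite = TRUE)
  }
  invisible(manifest)
}

pipeline_image <- function(config, seed, stage_dir) {
  n <- config$n_structures %||% 20
  pol_frac <- config$polarized_fraction %||% 0.3
  k <- config$k %||% 2
  ip <- config$image_params %||% list()
  n_pol <- round(pol_frac * n)
  morph <- vector("list", n); binned <- matrix(NA_real_, n, 100)
  for (i in seq_len(n)) {
    args <- utils::modifyList(
      list(reporter_polarized = i <= n_pol, seed = seed + i), ip)
    sim <- simulate_gastruloid_image(do.call(image_sim_params, args))
    labels <- segment_structures(sim$image, "dapi")
    if (max(labels) == 0) stop(sprintf("segmentation found no structure in image %d", i),
                               call. = FALSE)
    main <- which.max(tabulate(labels[labels > 0]))
    m <- measure_structure(labels, main, sim$image$pixel_size)
    m$image <- i
    morph[[i]] <- m
    prof <- extract_profile(sim$image, labels == main)
    binned[i, ] <- bin_profile(prof, normalize_to_dapi = TRUE)
  }
  res <- cluster_profiles(binned, k = k, seed = seed)
  write_csv_atomic(do.call(rbind, morph), file.path(stage_dir, "morphometry.csv"))
  write_csv_atomic(as.data.frame(binned), file.path(stage_dir, "profiles.csv"))
  write_csv_atomic(data.frame(structure = seq_len(n), cluster = res$labels),
                   file.path(stage_dir, "clusters.csv"))
  write_csv_atomic(as.data.frame(res$centroids), file.path(stage_dir, "centroids.csv"))
  c("simulate", "morphometry", "profile", "cluster")
}

pipeline_cells <- function(config, seed, stage_dir) {
  conds <- config$conditions %||% stop("cells pipeline needs `conditions`", call. = FALSE)
  rules <- if (!is.null(config$rules)) read_rules(config$rules) else default_rules()
  cp <- config$cell_params %||% list()
  tabs <- list(); labs <- list()
  for (i in seq_along(conds)) {
    cname <- names(conds)[i]
    args <- utils::modifyList(
      list(n_cells_per_class = unlist(conds[[i]]), seed = seed + i,
           condition = cname), cp)
    sim <- simulate_cell_table(do.call(cell_sim_params, args), rules)
    tabs[[cname]] <- sim$table; labs[[cname]] <- as.character(sim$labels)
  }
  counts <- do.call(rbind, lapply(tabs, function(t) t$counts))
  tab <- cell_table(counts,
                    cell_ids = make.unique(unlist(lapply(tabs, function(t) t$cell_ids))),
                    condition = unlist(lapply(tabs, function(t) t$cell_meta$condition)),
                    annotation = unlist(labs))
  qc <- qc_filter(tab,
                  min_features = config$qc_min_features %||% 200,
                  max_features = config$qc_max_features %||% 2500,
                  max_mito = config$qc_max_mito %||% 0.05)
  neural <- classify_neural(qc$table, rules)
  dv <- classify_dv(qc$table, rules)
  ref <- config$reference_condition %||% names(conds)[1]
  ab <- relative_abundance(qc$table$cell_meta$annotation,
                           qc$table$cell_meta$condition, ref,
                           min_cells = config$min_cells %||% 10)
  write_csv_atomic(qc$report, file.path(stage_dir, "qc_report.csv"))
  write_csv_atomic(data.frame(cell_id = qc$table$cell_ids,
                              condition = qc$table$cell_meta$condition,
                              planted = qc$table$cell_meta$annotation,
                              neural = as.character(neural),
                              dv = as.character(dv)),
                   file.path(stage_dir, "classification.csv"))
  write_csv_atomic(ab, file.path(stage_dir, "abundance.csv"))
  c("simulate-cells", "qc", "classify", "abundance")
}
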
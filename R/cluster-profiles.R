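#' k-means clustering of binned A-P expression profiles
#'
#' Euclidean k-means on 100-bin profiles with k-means++ initialization and
#' `nstart` restarts under a fixed seed (best total within-cluster sum of
#' squares wins). Clusters are renumbered by descending centroid mean, so
#' cluster 1 is always the highest-signal ("reporter-high") group. A
#' polarized cluster is called when some centroid's posterior-quartile mean
#' exceeds its anterior-quartile mean by more than
#' `polarized_sd_factor` times the SD of all profile values.
#'
#' @param profiles numeric matrix (structures x 100 bins), or a list of
#'   100-vectors.
#' @param k number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed RNG seed (mandatory; clustering is deterministic given it).
#' @param conditions optional per-profile condition labels; when given,
#'   per-condition cluster occupancy fractions are reported.
#' @param polarized_sd_factor threshold multiplier for the polarized call.
#' @param nstart number of k-means++ restarts.
#' @return A `profile_clusters` object: `k`, `labels` (1..k), `centroids`
#'   (k x 100), `occupancy` (condition x cluster fractions, rows sum to 1,
#'   or NULL), `polarized_cluster_id` (integer or NULL), `tot_withinss`.
#' @export
cluster_profiles <- function(profiles, k, seed, conditions = NULL,
                             polarized_sd_factor = 2, nstart = 10) {
  x <- if (is.list(profiles) && !is.matrix(profiles))
    do.call(rbind, profiles) else as.matrix(profiles)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= number of profiles", call. = FALSE)
  if (!is.null(conditions) && length(conditions) != n)
    stop("conditions must have one label per profile", call. = FALSE)

  fit <- with_seed(seed, {
    best <- NULL
    for (rep in seq_len(nstart)) {
      centers <- kmeanspp_init(x, k)
      km <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    best
  })
  if (is.null(fit)) {
    # fewer distinct profiles than k (e.g. all identical): collapse to the
    # distinct rows, deterministically, leaving the surplus clusters empty
    uq <- unique(x)
    lab <- match(do.call(paste, as.data.frame(x)), do.call(paste, as.data.frame(uq)))
    cent <- uq[c(seq_len(nrow(uq)), rep(1L, k - nrow(uq))), , drop = FALSE]
    fit <- list(cluster = lab, centers = cent,
                tot.withinss = 0)
  }
  ord <- order(rowMeans(fit$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[fit$cluster]
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL

  occupancy <- NULL
  if (!is.null(conditions)) {
    tab <- table(condition = conditions, cluster = factor(labels, levels = seq_len(k)))
    occupancy <- prop.table(tab, 1)
  }

  post <- rowMeans(centroids[, 76:100, drop = FALSE])
  ant <- rowMeans(centroids[, 1:25, drop = FALSE])
  excess <- post - ant
  thr <- polarized_sd_factor * stats::sd(as.vector(x))
  pol <- which.max(excess)
  polarized <- if (length(excess) && is.finite(thr) && excess[pol] > thr)
    as.integer(pol) else NULL

  structure(list(k = as.integer(k), labels = labels, centroids = centroids,
                 occupancy = occupancy, polarized_cluster_id = polarized,
                 tot_withinss = fit$tot.withinss, seed = seed),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("<profile_clusters: k = %d, n = %d, polarized cluster: %s>\n",
              x$k, length(x$labels),
              if (is.null(x$polarized_cluster_id)) "none" else x$polarized_cluster_id))
  cat("cluster sizes:", tabulate(x$labels, x$k), "\n")
  invisible(x)
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    idx[j] <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' Fraction of structures in the polarized cluster, per condition
#'
#' @param result a `profile_clusters` with a polarized cluster call.
#' @param condition_labels per-profile condition labels.
#' @return data frame: `condition`, `n` (profiles), `n_polarized`, `rate`.
#' @export
polarization_rate <- function(result, condition_labels) {
  stopifnot(inherits(result, "profile_clusters"))
  if (is.null(result$polarized_cluster_id))
    stop("no polarized cluster was identified", call. = FALSE)
  if (length(condition_labels) != length(result$labels))
    stop("condition_labels must have one entry per profile", call. = FALSE)
  pol <- result$labels == result$polarized_cluster_id
  conds <- unique(as.character(condition_labels))
  out <- do.call(rbind, lapply(conds, function(cc) {
    sel <- condition_labels == cc
    data.frame(condition = cc, n = sum(sel), n_polarized = sum(pol & sel),
               rate = sum(pol & sel) / sum(sel))
  }))
  rownames(out) <- NULL
  out
}
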
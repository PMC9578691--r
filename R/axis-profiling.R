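#' Extract a reporter/DAPI intensity profile along a structure's A-P midline
#'
#' Samples reporter and DAPI intensity at 1-pixel steps along a midline.
#' In `"auto"` mode the midline is the principal-axis chord through the mask
#' centroid, clipped to the mask; alternatively a polyline (drawn
#' anterior-to-posterior, as in a manual line profile) may be supplied.
#' The profile is oriented so that the reporter-brighter half sits at
#' relative position 1 (the posterior pole); an exact tie keeps the original
#' orientation.
#'
#' @param image a [labeled_image()].
#' @param mask logical or 0/1 matrix selecting the structure.
#' @param reporter_channel,dapi_channel channel names.
#' @param midline `"auto"`, or an n x 2 matrix of 0-based (row, col) pixel
#'   coordinates tracing the midline.
#' @param structure_id carried into the result.
#' @return An `axial_profile`: list with `structure_id`, `samples` (data
#'   frame `absolute_position` µm, `reporter`, `dapi`), `length` (µm) and
#'   `relative_positions` in [0, 1].
#' @export
extract_profile <- function(image, mask, reporter_channel = "reporter",
                            dapi_channel = "dapi", midline = "auto",
                            structure_id = 1L) {
  rep_ch <- get_channel(image, reporter_channel)
  dapi_ch <- get_channel(image, dapi_channel)
  ps <- image$pixel_size
  if (is.character(midline) && identical(midline, "auto")) {
    if (!any(mask != 0)) stop("mask is empty", call. = FALSE)
    path <- principal_axis_chord(mask != 0)
  } else {
    path <- as.matrix(midline)
    if (ncol(path) != 2L) stop("polyline midline must be an n x 2 matrix", call. = FALSE)
    if (any(path[, 1] < 0) || any(path[, 2] < 0) ||
        any(path[, 1] > nrow(rep_ch) - 1) || any(path[, 2] > ncol(rep_ch) - 1))
      stop("polyline lies outside the image", call. = FALSE)
  }
  pts <- resample_polyline(path, step = 1)
  if (nrow(pts$points) < 2L) stop("degenerate midline", call. = FALSE)
  rep_v <- bilinear(rep_ch, pts$points)
  dapi_v <- bilinear(dapi_ch, pts$points)
  rel <- pts$arclen / max(pts$arclen)
  # orient: reporter-brighter half -> posterior (relative position 1)
  if (mean(rep_v[rel < 0.5]) > mean(rep_v[rel > 0.5])) {
    ord <- rev(seq_along(rel))
    rep_v <- rep_v[ord]; dapi_v <- dapi_v[ord]
    pts$arclen <- max(pts$arclen) - pts$arclen[ord]
  }
  structure(list(structure_id = structure_id,
                 samples = data.frame(absolute_position = pts$arclen * ps,
                                      reporter = rep_v, dapi = dapi_v),
                 length = max(pts$arclen) * ps,
                 relative_positions = pts$arclen / max(pts$arclen)),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("<axial_profile structure %s: %d samples over %.1f µm>\n",
              x$structure_id, nrow(x$samples), x$length))
  invisible(x)
}

# longest chord through the mask centroid along the principal axis,
# clipped to the mask; returns a 2 x 2 matrix of (row, col) endpoints
principal_axis_chord <- function(mask) {
  coords <- which(mask, arr.ind = TRUE) - 1
  ctr <- colMeans(coords)
  v <- if (nrow(coords) < 3L) c(0, 1) else {
    ev <- eigen(stats::cov(coords), symmetric = TRUE)
    ev$vectors[, 1]
  }
  inside <- function(p) {
    r <- round(p[1]) + 1; c <- round(p[2]) + 1
    r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c]
  }
  walk <- function(dir) {
    t <- 0
    while (inside(ctr + (t + 0.25) * dir)) t <- t + 0.25
    t
  }
  t1 <- walk(v); t2 <- walk(-v)
  if (t1 + t2 < 2) stop("degenerate midline: mask thinner than 2 px along axis",
                        call. = FALSE)
  rbind(ctr - t2 * v, ctr + t1 * v)
}

# sample a polyline at fixed arc-length steps (plus the final endpoint)
resample_polyline <- function(path, step = 1) {
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  pts <- t(vapply(s, function(d) {
    i <- max(which(cum <= d + 1e-12)); i <- min(i, nrow(path) - 1L)
    f <- if (seg[i] > 0) (d - cum[i]) / seg[i] else 0
    path[i, ] + f * (path[i + 1L, ] - path[i, ])
  }, numeric(2)))
  list(points = pts, arclen = s)
}

# bilinear interpolation at 0-based (row, col) points
bilinear <- function(m, pts) {
  r <- clamp(pts[, 1], 0, nrow(m) - 1); c <- clamp(pts[, 2], 0, ncol(m) - 1)
  r0 <- pmin(floor(r), nrow(m) - 2); c0 <- pmin(floor(c), ncol(m) - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i <- function(rr, cc) m[cbind(rr + 1, cc + 1)]
  (1 - fr) * (1 - fc) * i(r0, c0) + (1 - fr) * fc * i(r0, c0 + 1) +
    fr * (1 - fc) * i(r0 + 1, c0) + fr * fc * i(r0 + 1, c0 + 1)
}

#' Bin an axial profile into 100 equal-length bins
#'
#' Relative positions are the absolute positions divided by the total
#' length; intensities are averaged in 0.01-wide bins, giving exactly 100
#' values over the A-P axis. With `normalize_to_dapi`, each sample's
#' reporter value is divided by its DAPI value before averaging (DAPI
#' floored at 1e-6 of its maximum). Bin i averages samples with relative
#' position in [i/100, (i+1)/100), the last bin closed; empty bins are
#' filled by linear interpolation from the nearest non-empty bins.
#'
#' @param profile an `axial_profile` from [extract_profile()].
#' @param normalize_to_dapi divide reporter by DAPI per sample first.
#' @return Numeric vector of length 100.
#' @export
bin_profile <- function(profile, normalize_to_dapi = FALSE) {
  stopifnot(inherits(profile, "axial_profile"))
  s <- profile$samples
  if (nrow(s) < 1L) stop("profile has no samples", call. = FALSE)
  v <- s$reporter
  if (normalize_to_dapi) {
    if (max(s$dapi) <= 0)
      stop("cannot normalize to DAPI: all DAPI values are zero", call. = FALSE)
    v <- v / pmax(s$dapi, 1e-6 * max(s$dapi))
  }
  rel <- profile$relative_positions
  idx <- pmin(floor(rel * 100), 99) + 1   # last bin closed at rel = 1
  out <- rep(NA_real_, 100)
  means <- tapply(v, idx, mean)
  out[as.integer(names(means))] <- means
  if (anyNA(out)) {
    known <- which(!is.na(out))
    out <- if (length(known) == 1L) rep(out[known], 100)
    else stats::approx(known, out[known], xout = 1:100, rule = 2)$y
  }
  out
}

#' Rescale a binned profile to the [0, 1] range
#'
#' @param binned numeric vector (typically length 100) of finite values.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_scale <- function(binned) {
  if (!all(is.finite(binned))) stop("profile contains non-finite values", call. = FALSE)
  rng <- range(binned)
  if (diff(rng) == 0) stop("constant profile not scalable", call. = FALSE)
  (binned - rng[1]) / diff(rng)
}
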
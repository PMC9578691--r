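# Feret (caliper) diameters by rotating calipers on the convex hull.
#
# Pixels are treated as unit squares centred on their 0-based (row, col)
# coordinates; the hull is taken over all four corners of every pixel, so a
# square of side s pixels has feret_max exactly s*sqrt(2) and a single row
# of pixels has a nonzero minimum caliper of 1 px.

pixel_corner_hull <- function(coords) {
  # coords: matrix (n x 2) of 0-based (row, col) pixel centres
  r <- coords[, 1]; c <- coords[, 2]
  pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
               c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
  pts <- unique(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  pts[h, , drop = FALSE]
}

# max caliper: diameter of the hull vertex set; min caliper: smallest width
# over directions normal to hull edges (attained at an edge for convex sets)
feret_from_hull <- function(hull) {
  n <- nrow(hull)
  if (n < 2L) return(c(max = 0, min = 0))
  d2 <- as.matrix(stats::dist(hull))
  fmax <- max(d2)
  e <- hull[c(seq_len(n)[-1], 1L), , drop = FALSE] - hull
  len <- sqrt(rowSums(e^2))
  keep <- len > 0
  e <- e[keep, , drop = FALSE] / len[keep]
  widths <- vapply(seq_len(nrow(e)), function(i) {
    nrm <- c(-e[i, 2], e[i, 1])
    proj <- hull %*% nrm
    max(proj) - min(proj)
  }, numeric(1))
  c(max = fmax, min = min(widths))
}

# Feret diameters, in pixels, of one labelled object's pixel set
feret_diameters_px <- function(coords) {
  feret_from_hull(pixel_corner_hull(coords))
}

# circularity as used for the nucleus filters: sqrt(4*area / (pi*FeretMax^2)),
# unitless (computed here in pixel units; invariant to pixel size)
circularity_px <- function(area_px, feret_max_px) {
  sqrt(4 * area_px / (pi * feret_max_px^2))
}
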
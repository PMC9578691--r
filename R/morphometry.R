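#' Segment whole structures from one image channel
#'
#' Gaussian smoothing, a global threshold (Otsu on intensity for confocal
#' projections, or Otsu on a local-variance map for brightfield-type
#' texture), binary hole filling, and distance-transform watershed splitting
#' of touching objects. Small objects (debris) below `min_area` are removed
#' and the surviving labels are renumbered contiguously from 1 (background
#' is 0).
#'
#' @param image a [labeled_image()].
#' @param channel name of the channel to segment.
#' @param method `"otsu"` thresholds smoothed intensity directly;
#'   `"variance"` thresholds a local-variance (texture) map, for
#'   brightfield-like images where objects differ in texture rather than
#'   mean level.
#' @param smooth_sigma Gaussian smoothing sigma in µm (0 to disable).
#' @param min_area smallest structure kept, in µm².
#' @param watershed_tolerance minimum depth (in distance-map pixels) between
#'   two catchment basins for them to stay separate objects.
#' @param variance_window side of the square local-variance window in
#'   pixels (`"variance"` method only).
#' @return Integer label matrix (same size as the channel); attribute
#'   `pixel_size` carries the image's pixel size.
#' @export
segment_structures <- function(image, channel, method = c("otsu", "variance"),
                               smooth_sigma = 1, min_area = 5000,
                               watershed_tolerance = 1, variance_window = 15) {
  method <- match.arg(method)
  x <- get_channel(image, channel)
  ps <- image$pixel_size
  lab <- matrix(0L, nrow(x), ncol(x))
  if (diff(range(x)) == 0) {               # constant image: no structures
    attr(lab, "pixel_size") <- ps
    return(lab)
  }
  xs <- smooth_raster(x, smooth_sigma / ps)
  score <- if (method == "otsu") xs else local_variance(xs, variance_window)
  sn <- (score - min(score)) / diff(range(score))
  mask <- sn > EBImage::otsu(EBImage::Image(sn))
  mask <- EBImage::fillHull(mask)
  wl <- EBImage::watershed(EBImage::distmap(mask), tolerance = watershed_tolerance)
  lab <- relabel_filtered(as.matrix(EBImage::imageData(wl)), min_area / ps^2)
  attr(lab, "pixel_size") <- ps
  lab
}

smooth_raster <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma_px)))
}

local_variance <- function(x, window) {
  w <- matrix(1 / window^2, window, window)
  mu <- as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(x), w)))
  mu2 <- as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(x^2), w)))
  pmax(mu2 - mu^2, 0)
}

# drop objects below min_area_px and renumber labels 1..n in scan order
relabel_filtered <- function(lab, min_area_px) {
  lab <- round(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    first <- vapply(keep, function(k) which(lab == k)[1], numeric(1))
    keep <- keep[order(first)]
    for (i in seq_along(keep)) out[lab == keep[i]] <- i
  }
  out
}

#' Morphometry of one segmented structure
#'
#' Area from the pixel count, Feret diameters by rotating calipers on the
#' convex hull of the object's pixel corners, and the elongation index
#' (aspect ratio Feret max / Feret min).
#'
#' @param labels integer label matrix from [segment_structures()].
#' @param structure_id label of the object to measure.
#' @param pixel_size µm per pixel; defaults to the matrix's `pixel_size`
#'   attribute when present.
#' @return A one-row data frame: `structure_id`, `area` (µm²), `feret_max`,
#'   `feret_min` (µm), `elongation_index`.
#' @export
measure_structure <- function(labels, structure_id,
                              pixel_size = attr(labels, "pixel_size") %||% 1) {
  coords <- which(labels == structure_id, arr.ind = TRUE) - 1  # 0-based
  if (nrow(coords) == 0L)
    stop(sprintf("structure %s not present in label raster", structure_id),
         call. = FALSE)
  if (nrow(coords) < 2L)
    stop("degenerate object: single-pixel structures have undefined Feret min",
         call. = FALSE)
  f <- feret_diameters_px(coords)
  data.frame(structure_id = structure_id,
             area = nrow(coords) * pixel_size^2,
             feret_max = f[["max"]] * pixel_size,
             feret_min = f[["min"]] * pixel_size,
             elongation_index = f[["max"]] / f[["min"]])
}

#' Measure every structure in a label raster
#'
#' @inheritParams measure_structure
#' @return data frame with one row per label, as in [measure_structure()].
#' @export
measure_structures <- function(labels,
                               pixel_size = attr(labels, "pixel_size") %||% 1) {
  ids <- sort(unique(labels[labels > 0]))
  do.call(rbind, lapply(ids, measure_structure, labels = labels,
                        pixel_size = pixel_size))
}

#' Segment nuclei and quantify per-nucleus channel intensities
#'
#' Nuclei are segmented from the DAPI (counterstain) channel: Gaussian
#' smoothing, morphological background subtraction (grayscale opening with a
#' disc of radius `background_radius`), Otsu thresholding and
#' distance-transform watershed splitting. Every nucleus is measured and
#' returned; `passed_filters` flags the ones satisfying the standard
#' area (100–1000 µm²) and circularity (0.6–1) rules that downstream
#' quantification should use. Circularity fractionally above 1 from
#' rasterization (up to 1.05) is clamped to 1 before filtering.
#'
#' @param image a [labeled_image()].
#' @param dapi_channel channel used for segmentation.
#' @param measure_channels channels to quantify per nucleus (default: all
#'   others).
#' @param smooth_sigma Gaussian sigma in µm.
#' @param background_radius disc radius in µm for background subtraction.
#' @param min_area_filter,max_area_filter area window (µm²) of the filter.
#' @param min_circularity lower circularity bound of the filter.
#' @param watershed_tolerance passed to the watershed split.
#' @return data frame with one row per nucleus: `nucleus_id`, `area` (µm²),
#'   `circularity`, `passed_filters`, and per measured channel
#'   `mean_<ch>` (mean pixel intensity) and `norm_<ch>` (integrated
#'   intensity / area in µm²; equal to the mean at 1 µm pixels).
#' @export
quantify_nuclei <- function(image, dapi_channel = "dapi",
                            measure_channels = setdiff(names(image$channels), dapi_channel),
                            smooth_sigma = 1, background_radius = 50,
                            min_area_filter = 100, max_area_filter = 1000,
                            min_circularity = 0.6, watershed_tolerance = 1) {
  x <- get_channel(image, dapi_channel)
  ps <- image$pixel_size
  empty <- data.frame(nucleus_id = integer(), area = numeric(),
                      circularity = numeric(), passed_filters = logical())
  if (diff(range(x)) == 0) return(empty)
  xs <- smooth_raster(x, smooth_sigma / ps)
  xb <- subtract_background(xs, background_radius / ps)
  if (diff(range(xb)) == 0) return(empty)
  sn <- (xb - min(xb)) / diff(range(xb))
  mask <- sn > EBImage::otsu(EBImage::Image(sn))
  mask <- EBImage::fillHull(mask)
  wl <- as.matrix(EBImage::imageData(
    EBImage::watershed(EBImage::distmap(mask), tolerance = watershed_tolerance)))
  ids <- sort(unique(wl[wl > 0]))
  rows <- lapply(ids, function(id) {
    coords <- which(wl == id, arr.ind = TRUE)
    if (nrow(coords) < 2L) return(NULL)  # single-pixel specks are noise
    n_px <- nrow(coords)
    f <- feret_diameters_px(coords - 1)
    circ <- circularity_px(n_px, f[["max"]])
    circ_eff <- if (circ <= 1.05) min(circ, 1) else circ
    area <- n_px * ps^2
    rec <- data.frame(nucleus_id = id, area = area, circularity = circ,
                      passed_filters = area >= min_area_filter &
                        area <= max_area_filter &
                        circ_eff >= min_circularity & circ_eff <= 1)
    for (ch in measure_channels) {
      v <- get_channel(image, ch)[coords]
      rec[[paste0("mean_", ch)]] <- sum(v) / n_px
      rec[[paste0("norm_", ch)]] <- sum(v) / area
    }
    rec
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# grayscale opening with a disc structuring element approximates the
# rolling-ball background; the opened image is the background estimate
subtract_background <- function(x, radius_px) {
  if (radius_px < 1) return(x)
  side <- 2L * as.integer(ceiling(radius_px)) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  bg <- as.matrix(EBImage::imageData(EBImage::opening(EBImage::Image(x), brush)))
  pmax(x - bg, 0)
}
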
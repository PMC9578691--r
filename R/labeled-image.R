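#' Multi-channel 2D image with physical pixel size
#'
#' Container for a set of equally sized 2D intensity rasters (one per
#' channel) plus the physical pixel size in micrometres. Rasters are plain
#' numeric matrices in (row, col) order; coordinates used throughout the
#' package are pixel-centred and 0-based.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions. Typical names: `"dapi"`, `"reporter"`.
#' @param pixel_size physical size of one pixel in micrometres (> 0).
#' @param image_id identifier string carried through to output tables.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(channels, pixel_size = 1, image_id = "image") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels) - 1L)
  dims <- vapply(channels, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) stop("each channel must be a numeric matrix", call. = FALSE)
    dim(m)
  }, integer(2))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop("all channels must share identical raster dimensions", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (µm/pixel)", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 image_id = as.character(image_id)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<labeled_image '%s': %d x %d px, %.4g µm/px, channels: %s>\n",
              x$image_id, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(image, channel) {
  stopifnot(inherits(image, "labeled_image"))
  if (!channel %in% names(image$channels))
    stop(sprintf("channel '%s' not found (available: %s)", channel,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  image$channels[[channel]]
}
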
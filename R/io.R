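# Atomic file writes: write to a temp file in the same directory, then
# rename, so a failed run never leaves a partial output in place.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop(sprintf("could not write %s", path), call. = FALSE)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) utils::write.csv(df, tmp, row.names = FALSE))
}

#' Write / read a multi-channel image as TIFF plus JSON sidecar
#'
#' Channels are stored as one 16-bit grayscale page each, rescaled by a
#' common intensity scale recorded in the sidecar together with the pixel
#' size and channel names. Reading without a sidecar falls back to a pixel
#' size of 1 µm and channels named `ch0..chN`, with a warning.
#'
#' @param image a [labeled_image()].
#' @param path TIFF path; the sidecar defaults to `<path>.json`.
#' @param sidecar JSON sidecar path.
#' @return `write_image`: the path, invisibly. `read_image`: a
#'   [labeled_image()].
#' @export
write_image <- function(image, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(image, "labeled_image"))
  scale <- max(1e-12, max(vapply(image$channels, max, numeric(1))))
  # quantize to 16-bit ourselves (round, then sit half a step up) so that
  # writeTIFF's float32 truncation stores exactly the intended level and
  # write -> read -> write is byte-stable
  pages <- lapply(image$channels, function(m)
    pmin((round(m / scale * 65535) + 0.5) / 65535, 1))
  atomic_write(path, function(tmp)
    tiff::writeTIFF(pages, tmp, bits.per.sample = 16L))
  meta <- list(pixel_size = image$pixel_size, channels = names(image$channels),
               intensity_scale = scale, image_id = image$image_id)
  atomic_write(sidecar, function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # tolerate RGB pages
    p
  })
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning(sprintf("no sidecar for %s; assuming pixel_size 1 µm, channels ch0..ch%d",
                    path, length(pages) - 1L))
    meta <- list(pixel_size = 1, channels = paste0("ch", seq_along(pages) - 1L),
                 intensity_scale = 1, image_id = basename(path))
  }
  dims <- vapply(pages, dim, integer(2))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop("TIFF pages have mismatched sizes", call. = FALSE)
  channels <- lapply(pages, function(p) p * as.numeric(meta$intensity_scale))
  names(channels) <- meta$channels
  labeled_image(channels, pixel_size = as.numeric(meta$pixel_size),
                image_id = meta$image_id %||% basename(path))
}

#' Write a label raster as 16-bit TIFF
#'
#' @param labels integer label matrix.
#' @param path output TIFF.
#' @export
write_labels <- function(labels, path) {
  atomic_write(path, function(tmp)
    tiff::writeTIFF(labels / 65535, tmp, bits.per.sample = 16L))
  invisible(path)
}

#' Read / write a cell table (MTX triplet or CSV)
#'
#' The MTX triplet follows the Cell Ranger layout: `matrix.mtx` is genes x
#' cells, `genes.tsv` one gene name per line, `barcodes.tsv` one cell id
#' per line. The CSV layout is cells x genes with a header row of gene
#' names and cell ids in the first column. Duplicate gene names are
#' deduplicated with a suffix and a warning; dimension mismatches are
#' fatal. Optional per-cell metadata (columns `condition`, `annotation`)
#' is read from `meta` and matched by cell id.
#'
#' @param path a directory containing `matrix.mtx` + `genes.tsv` +
#'   `barcodes.tsv`, or a `.csv` file.
#' @param meta optional CSV with columns `cell_id` and any of
#'   `condition`, `annotation`.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, meta = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop(sprintf("missing file: %s", f), call. = FALSE)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1]]
    barcodes <- read.delim(bf, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop("genes.tsv length does not match matrix rows", call. = FALSE)
    if (length(barcodes) != ncol(m))
      stop("barcodes.tsv length does not match matrix columns", call. = FALSE)
    counts <- t(m)
    dimnames(counts) <- list(barcodes, genes)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    colnames(counts) <- names(df)[-1]   # keep raw header (subsetting dedupes)
    rownames(counts) <- as.character(df[[1]])
  }
  if (anyDuplicated(colnames(counts))) {
    warning("duplicate gene names deduplicated with suffixes")
    colnames(counts) <- make.unique(colnames(counts))
  }
  if (all(counts == round(counts)) && max(counts) < .Machine$integer.max)
    storage.mode(counts) <- "integer"
  condition <- NA_character_; annotation <- NULL
  if (!is.null(meta)) {
    md <- utils::read.csv(meta, stringsAsFactors = FALSE)
    i <- match(rownames(counts), md$cell_id)
    if (anyNA(i)) stop("metadata is missing some cell ids", call. = FALSE)
    if ("condition" %in% names(md)) condition <- md$condition[i]
    if ("annotation" %in% names(md)) annotation <- md$annotation[i]
  }
  cell_table(counts, condition = condition, annotation = annotation)
}

#' @rdname read_cell_table
#' @param table a [cell_table()].
#' @param format `"mtx"` writes the triplet into directory `path`; `"csv"`
#'   writes a single CSV file.
#' @export
write_cell_table <- function(table, path, format = c("mtx", "csv")) {
  stopifnot(inherits(table, "cell_table"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    atomic_write(file.path(path, "matrix.mtx"), function(tmp)
      Matrix::writeMM(Matrix::Matrix(t(table$counts), sparse = TRUE), tmp))
    atomic_write(file.path(path, "genes.tsv"), function(tmp)
      writeLines(table$gene_names, tmp))
    atomic_write(file.path(path, "barcodes.tsv"), function(tmp)
      writeLines(table$cell_ids, tmp))
  } else {
    df <- data.frame(cell_id = table$cell_ids, table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_csv_atomic(df, path)
  }
  invisible(path)
}
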
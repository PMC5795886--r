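#' Grayscale image container
#'
#' An 8-bit grayscale raster: an integer matrix with values in 0-255, row 1
#' at the top of the image, column 1 at the left (row-major raster
#' convention, matching sequential top-left pixel analysis).
#'
#' @param pixels numeric or integer matrix; values must be integral and in
#'   `[0, 255]`.
#' @return An integer matrix of class `"gray_image"`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1", call. = FALSE)
  p <- as.vector(pixels)
  if (anyNA(p) || any(p < 0) || any(p > 255) || any(p != trunc(p)))
    stop("pixel intensities must be integers in [0, 255]", call. = FALSE)
  out <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  class(out) <- c("gray_image", "matrix", "array")
  out
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, intensity range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

as_gray_matrix <- function(image) {
  if (!is_gray_image(image)) image <- gray_image(image)
  unclass(image)
}

# collapse channels (mean, half-up) after dropping any alpha plane
reduce_channels <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3]
  if (nch == 2L || nch == 4L) arr <- arr[, , -nch, drop = FALSE]  # drop alpha
  if (dim(arr)[3] == 1L) return(arr[, , 1L])
  round_half_up(apply(arr, c(1, 2), mean))
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("corrupt PNG: ", path, call. = FALSE)
  as.integer(hdr[25L])  # IHDR bit-depth byte
}

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= length(raw) && is_space(raw[pos])) pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(0x23)) {  # '#' comment
        while (pos <= length(raw) && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(raw) && !is_space(raw[pos])) pos <<- pos + 1L
    if (start > length(raw)) stop("truncated PGM header: ", path, call. = FALSE)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (magic != "P5")
    stop("unsupported PGM variant '", magic, "' (only binary P5)", call. = FALSE)
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  pos <- pos + 1L  # single whitespace after maxval
  if (maxval < 1L || maxval > 65535L)
    stop("invalid PGM maxval ", maxval, call. = FALSE)
  n <- width * height
  if (maxval <= 255L) {
    vals <- as.integer(readBin(raw[pos:length(raw)], "integer",
                               n = n, size = 1L, signed = FALSE))
  } else {
    vals <- readBin(raw[pos:length(raw)], "integer", n = n, size = 2L,
                    signed = FALSE, endian = "big")
  }
  if (length(vals) < n) stop("truncated PGM pixel data: ", path, call. = FALSE)
  list(pixels = matrix(vals, nrow = height, ncol = width, byrow = TRUE),
       maxval = maxval)
}

#' Read an 8-bit grayscale image
#'
#' Reads PNG, TIFF or binary PGM (P5) into a [gray_image()]. Multi-channel
#' images are reduced to one channel by the arithmetic mean of the color
#' channels (rounded half up; an alpha plane is discarded) -- shadow images
#' are intrinsically monochrome, so any fixed channel policy is acceptable
#' and this one is deterministic. Inputs deeper than 8 bits are rejected
#' unless `downscale = TRUE`, because every sentinel and threshold in the
#' analysis is defined on the 8-bit scale; with the flag, 16-bit samples are
#' divided by 257 and rounded half up.
#'
#' @param path path to a `.png`, `.tif`/`.tiff` or `.pgm` file.
#' @param downscale logical; allow deep (> 8-bit) inputs by scaling them to
#'   8 bits. Default `FALSE`.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, downscale = FALSE) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  deep_err <- function(bits) {
    stop(sprintf("%d-bit input requires downscale = TRUE: %s", bits, path),
         call. = FALSE)
  }
  if (ext == "png") {
    depth <- png_bit_depth(path)
    if (depth > 8L && !downscale) deep_err(depth)
    arr <- png::readPNG(path)
    scale <- if (depth > 8L) 65535 else 255
    vals <- reduce_channels(round_half_up(arr * scale))
    if (depth > 8L) vals <- round_half_up(vals / 257)
    gray_image(vals)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(arr) > 255) 16L else 8L
    bits <- max(bits)
    if (bits > 16L) stop("unsupported TIFF bit depth ", bits, call. = FALSE)
    if (bits > 8L && !downscale) deep_err(bits)
    vals <- reduce_channels(arr)
    if (bits > 8L) vals <- round_half_up(vals / 257)
    gray_image(vals)
  } else if (ext == "pgm") {
    pgm <- read_pgm(path)
    if (pgm$maxval > 255L && !downscale) deep_err(16L)
    vals <- pgm$pixels
    if (pgm$maxval > 255L) vals <- round_half_up(vals * 255 / pgm$maxval)
    gray_image(vals)
  } else {
    stop("unsupported image format '.", ext, "' (PNG, TIFF or PGM)",
         call. = FALSE)
  }
}

#' Write an 8-bit grayscale image
#'
#' Format is chosen from the file extension (`.png`, `.tif`/`.tiff`,
#' `.pgm`). The written file round-trips losslessly through
#' [read_gray_image()].
#'
#' @param image a [gray_image()] (or a matrix coercible to one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  m <- as_gray_matrix(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con,
              eos = NULL)
    writeBin(as.raw(as.vector(t(m))), con)
  } else {
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

RESULT_SCHEMA <- "shadowcount/analysis-result/1"

empty_detections <- function() {
  data.frame(id = integer(), row = integer(), col = integer(),
             bbox_top = integer(), bbox_left = integer(),
             bbox_h = integer(), bbox_w = integer(),
             ppd = numeric(), state = character(),
             stringsAsFactors = FALSE)
}

#' Analysis result container
#'
#' Bundles the quantities the analyzer reports for one image: total, live
#' and dead counts, concentration, viability percentage and the size
#' distribution (histogram of bounding-box diagonals in pixels), plus the
#' per-cell detection table.
#'
#' @param n_total,n_live,n_dead cell counts; `n_live + n_dead` must equal
#'   `n_total`.
#' @param concentration cells/mL (may be `NA` when no conversion parameters
#'   were supplied).
#' @param viability percent in `[0, 100]`, or `NA` when undefined (no cells).
#' @param size_distribution a list with numeric `breaks` and integer
#'   `counts` (as from [graphics::hist()]).
#' @param detections a data frame with columns `id, row, col, bbox_top,
#'   bbox_left, bbox_h, bbox_w, ppd, state`.
#' @return A list of class `"analysis_result"`.
#' @export
analysis_result <- function(n_total, n_live, n_dead,
                            concentration = NA_real_,
                            viability = NA_real_,
                            size_distribution = list(breaks = numeric(),
                                                     counts = integer()),
                            detections = empty_detections()) {
  stopifnot(n_total >= 0, n_live >= 0, n_dead >= 0)
  if (n_live + n_dead != n_total)
    stop("n_live + n_dead must equal n_total", call. = FALSE)
  if (!is.na(viability) && (viability < 0 || viability > 100))
    stop("viability must be in [0, 100] or NA", call. = FALSE)
  structure(list(
    n_total = as.integer(n_total),
    n_live = as.integer(n_live),
    n_dead = as.integer(n_dead),
    concentration = as.numeric(concentration),
    viability = as.numeric(viability),
    size_distribution = list(
      breaks = as.numeric(size_distribution$breaks),
      counts = as.integer(size_distribution$counts)),
    detections = detections
  ), class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("Shadow-image analysis result\n")
  cat(sprintf("  cells: %d total (%d live, %d dead)\n",
              x$n_total, x$n_live, x$n_dead))
  cat(sprintf("  viability: %s\n",
              if (is.na(x$viability)) "undefined (no cells)"
              else sprintf("%.2f %%", x$viability)))
  cat(sprintf("  concentration: %s\n",
              if (is.na(x$concentration)) "not converted"
              else sprintf("%.3g cells/mL", x$concentration)))
  invisible(x)
}

#' Write / read an analysis result as JSON
#'
#' The JSON document is schema-versioned and round-trips losslessly through
#' [read_result()].
#'
#' @param result an [analysis_result()].
#' @param path output (input) file path.
#' @return `write_result()` returns `path` invisibly; `read_result()`
#'   returns the reconstructed [analysis_result()].
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "analysis_result"))
  doc <- list(
    schema = RESULT_SCHEMA,
    n_total = result$n_total,
    n_live = result$n_live,
    n_dead = result$n_dead,
    concentration = result$concentration,
    viability = result$viability,
    size_distribution = list(breaks = result$size_distribution$breaks,
                             counts = result$size_distribution$counts),
    detections = result$detections
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, RESULT_SCHEMA))
    stop("unrecognized result schema: ", doc$schema, call. = FALSE)
  det <- if (is.data.frame(doc$detections) && nrow(doc$detections) > 0) {
    d <- doc$detections
    d$id <- as.integer(d$id); d$row <- as.integer(d$row)
    d$col <- as.integer(d$col); d$bbox_top <- as.integer(d$bbox_top)
    d$bbox_left <- as.integer(d$bbox_left); d$bbox_h <- as.integer(d$bbox_h)
    d$bbox_w <- as.integer(d$bbox_w); d$ppd <- as.numeric(d$ppd)
    d
  } else empty_detections()
  analysis_result(
    n_total = doc$n_total, n_live = doc$n_live, n_dead = doc$n_dead,
    concentration = if (is.null(doc$concentration)) NA_real_ else doc$concentration,
    viability = if (is.null(doc$viability)) NA_real_ else doc$viability,
    size_distribution = doc$size_distribution,
    detections = det
  )
}

#' Write a detection table as CSV
#'
#' Columns: `id,row,col,bbox_h,bbox_w,ppd,state`.
#'
#' @param detections detection data frame (from [mark_centers()] /
#'   [analyze()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  cols <- c("id", "row", "col", "bbox_h", "bbox_w", "ppd", "state")
  utils::write.csv(detections[, cols], path, row.names = FALSE)
  invisible(path)
}
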
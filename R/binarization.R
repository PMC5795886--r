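#' Binarization configuration
#'
#' The image is divided into `grid_rows * grid_cols` rectangular areas
#' (16 under the instrument-faithful 4x4 default). Each area gets its own
#' binarization determination value: the area's mean intensity minus
#' `gray_offset`, an empirically set constant that differs per cell line.
#' Pixels darker than their area's determination value become shadow
#' candidates; everything else is background. The tiling compensates the
#' gentle illumination non-uniformity of a bare-sensor light path.
#'
#' @param gray_offset intensity offset (8-bit counts, `>= 0`) subtracted
#'   from each area mean. No canonical per-cell-line values exist; it must
#'   be supplied (or calibrated) per cell line.
#' @param grid_rows,grid_cols tiling of the image, default 4 x 4.
#' @return A list of class `"binarization_config"`.
#' @export
binarization_config <- function(gray_offset, grid_rows = 4L, grid_cols = 4L) {
  stopifnot(length(gray_offset) == 1L, gray_offset >= 0,
            grid_rows >= 1L, grid_cols >= 1L)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 gray_offset = as.numeric(gray_offset)),
            class = "binarization_config")
}

# tile boundaries along one dimension; remainder pixels are absorbed by the
# last tile so exactly `n_tiles` areas always result
tile_edges <- function(extent, n_tiles) {
  step <- extent %/% n_tiles
  start <- (seq_len(n_tiles) - 1L) * step + 1L
  end <- c(start[-1L] - 1L, extent)
  cbind(start = start, end = end)
}

tile_index <- function(extent, n_tiles) {
  e <- tile_edges(extent, n_tiles)
  rep(seq_len(n_tiles), times = e[, "end"] - e[, "start"] + 1L)
}

#' Per-area mean intensities
#'
#' @param image a [gray_image()].
#' @param config a [binarization_config()].
#' @return A `grid_rows x grid_cols` numeric matrix of area means.
#' @export
compute_region_means <- function(image, config) {
  m <- as_gray_matrix(image)
  if (nrow(m) < config$grid_rows || ncol(m) < config$grid_cols)
    stop("image smaller than the binarization grid", call. = FALSE)
  ri <- tile_index(nrow(m), config$grid_rows)
  ci <- tile_index(ncol(m), config$grid_cols)
  means <- tapply(as.vector(m), list(ri[row(m)], ci[col(m)]), mean)
  matrix(as.numeric(means), config$grid_rows, config$grid_cols)
}

#' Per-area binarization determination values
#'
#' `threshold = mean - gray_offset`, clamped to `[0, 255]`.
#'
#' @param means matrix from [compute_region_means()].
#' @param config a [binarization_config()].
#' @return Numeric matrix of thresholds, same shape as `means`.
#' @export
compute_determination_values <- function(means, config) {
  clip8(means - config$gray_offset)
}

#' Binarize an image into a candidate/background label plane
#'
#' Each pixel strictly below its area's determination value becomes a
#' shadow CANDIDATE (96); pixels at or above it become BACKGROUND (255).
#' Equality maps to background -- the conservative reading, yielding fewer
#' false candidates. The source image is never modified (the analyzer works
#' on a duplicate of the photographed image); states live in a separate
#' label plane.
#'
#' @param image a [gray_image()].
#' @param thresholds matrix from [compute_determination_values()]; if
#'   `NULL`, computed from `image` and `config`.
#' @param config a [binarization_config()].
#' @return An integer matrix of class `"label_plane"` with values in
#'   `{96, 255}`.
#' @export
binarize <- function(image, thresholds = NULL, config) {
  m <- as_gray_matrix(image)
  if (is.null(thresholds))
    thresholds <- compute_determination_values(
      compute_region_means(image, config), config)
  if (nrow(thresholds) != config$grid_rows ||
      ncol(thresholds) != config$grid_cols)
    stop("thresholds do not match the configured grid", call. = FALSE)
  ri <- tile_index(nrow(m), config$grid_rows)
  ci <- tile_index(ncol(m), config$grid_cols)
  thr_plane <- thresholds[ri, ci, drop = FALSE]
  plane <- matrix(ifelse(m < thr_plane, SENTINELS$candidate,
                         SENTINELS$background),
                  nrow(m), ncol(m))
  label_plane(plane)
}

#' Label plane constructor
#'
#' A per-pixel state plane over the sentinel values of [SENTINELS].
#'
#' @param states integer matrix over `{96, 175, 60, 255}`.
#' @return An integer matrix of class `"label_plane"`.
#' @export
label_plane <- function(states) {
  if (!is.matrix(states)) stop("`states` must be a matrix", call. = FALSE)
  allowed <- unlist(SENTINELS, use.names = FALSE)
  if (!all(states %in% allowed))
    stop("label plane states must be in {96, 175, 60, 255}", call. = FALSE)
  out <- matrix(as.integer(states), nrow(states), ncol(states))
  class(out) <- c("label_plane", "matrix", "array")
  out
}

#' @export
print.label_plane <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c(96, 175, 60, 255),
                      labels = c("candidate", "cluster", "center",
                                 "background")))
  cat(sprintf("<label_plane %d x %d>\n", nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

#' Export a label plane as a debug image
#'
#' Renders the sentinel values (96/175/60/255) literally as 8-bit
#' intensities, matching the instrument's intermediate displays.
#'
#' @param plane a [label_plane()].
#' @param path output image path (`.png`, `.tif`, `.pgm`).
#' @return `path`, invisibly.
#' @export
export_label_plane <- function(plane, path) {
  write_gray_image(gray_image(unclass(plane)), path)
}
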
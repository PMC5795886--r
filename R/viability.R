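#' Viability configuration
#'
#' Viability is judged from the peak-to-peak distance (PPD): the difference
#' between the highest and lowest intensity inside a square window (11x11
#' by default) centered on each detected cell, evaluated on the unmodified
#' duplicate of the photographed image. Dead cells have ruptured, flattened
#' membranes and cast higher-contrast shadows (up to 3.54x that of live
#' cells), so a cell is DEAD when its PPD reaches the per-cell-line
#' viability constant.
#'
#' @param ppd_threshold the cell viability constant, in 8-bit intensity
#'   units, in `(0, 255]`. Empirical and cell-line specific; no canonical
#'   values exist.
#' @param window_side side of the PPD window in pixels; odd, `>= 3`.
#'   Default 11.
#' @return A list of class `"viability_config"`.
#' @export
viability_config <- function(ppd_threshold, window_side = 11L) {
  stopifnot(length(ppd_threshold) == 1L,
            ppd_threshold > 0, ppd_threshold <= 255)
  window_side <- as.integer(window_side)
  if (window_side < 3L || window_side %% 2L == 0L)
    stop("window_side must be odd and >= 3", call. = FALSE)
  structure(list(window_side = window_side,
                 ppd_threshold = as.numeric(ppd_threshold)),
            class = "viability_config")
}

#' Peak-to-peak distance at a cell center
#'
#' Max minus min intensity over the `window_side` square centered on
#' `(center_row, center_col)`, clipped to the image bounds (border windows
#' are truncated, never padded -- padding would fabricate intensities into
#' the extrema). Computed on the raw image, never on the label plane.
#'
#' @param image a [gray_image()].
#' @param center_row,center_col 1-based center coordinates.
#' @param config a [viability_config()].
#' @return PPD in intensity units, in `[0, 255]`.
#' @export
compute_ppd <- function(image, center_row, center_col, config) {
  m <- as_gray_matrix(image)
  H <- nrow(m); W <- ncol(m)
  if (center_row < 1L || center_row > H || center_col < 1L || center_col > W)
    stop("PPD center outside the image", call. = FALSE)
  h <- (config$window_side - 1L) %/% 2L
  win <- m[max(1L, center_row - h):min(H, center_row + h),
           max(1L, center_col - h):min(W, center_col + h)]
  as.numeric(max(win) - min(win))
}

#' Classify one PPD value as live or dead
#'
#' DEAD iff `ppd >= ppd_threshold` (dead cells show the higher contrast;
#' ties count as dead). Vectorized.
#'
#' @param ppd PPD value(s), `>= 0`.
#' @param config a [viability_config()].
#' @return Character vector over `{"LIVE", "DEAD"}`.
#' @export
classify_viability <- function(ppd, config) {
  stopifnot(all(ppd >= 0))
  ifelse(ppd >= config$ppd_threshold, "DEAD", "LIVE")
}

#' Fill PPD and live/dead state for a detection table
#'
#' @param image the raw [gray_image()] (the unmodified duplicate).
#' @param detections detection data frame from [mark_centers()].
#' @param config a [viability_config()].
#' @return The detection data frame with `ppd` and `state` filled in.
#' @export
classify_detections <- function(image, detections, config) {
  if (nrow(detections) == 0L) return(detections)
  detections$ppd <- vapply(seq_len(nrow(detections)), function(i) {
    compute_ppd(image, detections$row[i], detections$col[i], config)
  }, numeric(1))
  detections$state <- classify_viability(detections$ppd, config)
  detections
}

#' Calibrate a PPD viability constant from a sample
#'
#' Convenience helper, not an instrument constant: given PPD values from a
#' sample, returns the midpoint between the live and dead PPD modes. With
#' known labels the modes are the per-group medians; without labels the two
#' modes are located by a deterministic two-cluster split of the sorted
#' values (1-D k-means seeded at the lower/upper quartiles). The instrument
#' itself uses constants determined in advance per cell line; this helper
#' only bootstraps one from a labeled or well-separated sample.
#'
#' @param ppd numeric PPD values.
#' @param state optional character vector of `"LIVE"`/`"DEAD"` truth labels.
#' @return A single threshold in intensity units.
#' @export
calibrate_ppd_threshold <- function(ppd, state = NULL) {
  stopifnot(length(ppd) >= 2L)
  if (!is.null(state)) {
    lo <- stats::median(ppd[state == "LIVE"])
    hi <- stats::median(ppd[state == "DEAD"])
  } else {
    centers <- matrix(stats::quantile(ppd, c(0.25, 0.75), names = FALSE))
    if (diff(centers) == 0) return(as.numeric(centers[1L]))
    km <- stats::kmeans(matrix(ppd), centers = centers)
    lo <- min(km$centers); hi <- max(km$centers)
  }
  if (is.na(lo) || is.na(hi))
    stop("calibration needs both live and dead examples", call. = FALSE)
  as.numeric((lo + hi) / 2)
}
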
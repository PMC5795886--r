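#' Pipeline configuration
#'
#' Bundles the per-cell-line constants and conversion parameters the full
#' analysis needs. Per-cell-line constants (`gray_offset`,
#' `ppd_threshold`) can be given directly or looked up by `cell_line` from
#' a YAML/JSON config file mapping line names to
#' `{gray_offset, ppd_threshold}`.
#'
#' @param gray_offset binarization gray offset (see
#'   [binarization_config()]).
#' @param ppd_threshold cell viability constant (see
#'   [viability_config()]).
#' @param grid_rows,grid_cols binarization tiling, default 4 x 4.
#' @param window_side PPD window side, default 11.
#' @param concentration a [concentration_params()], or `NULL` to skip
#'   concentration conversion.
#' @param pixel_pitch_um pixel pitch used to derive the FOV area when
#'   `concentration` is in area_volume mode without an explicit
#'   `fov_area_mm2`, and for optional size conversion. Default 2.2.
#' @param cell_line optional cell-line name to look up in `config_file`.
#' @param config_file optional YAML or JSON file of per-cell-line
#'   constants.
#' @param debug_dir optional directory; when set, [analyze()] writes the
#'   intermediate binarized/expanded/center label planes there as PNG.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(gray_offset = NULL, ppd_threshold = NULL,
                            grid_rows = 4L, grid_cols = 4L,
                            window_side = 11L, concentration = NULL,
                            pixel_pitch_um = 2.2, cell_line = NULL,
                            config_file = NULL, debug_dir = NULL) {
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    ext <- tolower(tools::file_ext(config_file))
    cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config_file)
           else jsonlite::read_json(config_file, simplifyVector = TRUE)
    if (is.null(cell_line))
      stop("cell_line must be given with config_file", call. = FALSE)
    line <- cfg[[cell_line]]
    if (is.null(line))
      stop("cell line '", cell_line, "' not in config file", call. = FALSE)
    if (is.null(gray_offset)) gray_offset <- line$gray_offset
    if (is.null(ppd_threshold)) ppd_threshold <- line$ppd_threshold
  }
  if (is.null(gray_offset) || is.null(ppd_threshold))
    stop("gray_offset and ppd_threshold are required (directly or via a ",
         "cell-line config file)", call. = FALSE)
  if (!is.null(concentration))
    stopifnot(inherits(concentration, "concentration_params"))
  structure(list(
    binarization = binarization_config(gray_offset, grid_rows, grid_cols),
    viability = viability_config(ppd_threshold, window_side),
    concentration = concentration,
    pixel_pitch_um = pixel_pitch_um,
    cell_line = cell_line,
    debug_dir = debug_dir
  ), class = "pipeline_config")
}

size_histogram <- function(detections) {
  if (nrow(detections) == 0L)
    return(list(breaks = numeric(), counts = integer()))
  diag_px <- sqrt(detections$bbox_h^2 + detections$bbox_w^2)
  upper <- max(4, 2 * ceiling(max(diag_px) / 2))
  h <- graphics::hist(diag_px, breaks = seq(0, upper, by = 2),
                      plot = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Run the full shadow-image analysis
#'
#' Executes the complete chain on one image: duplicate the image, derive
#' the 16 per-area determination values and binarize (copy 1), grow
#' candidate pixels into cluster matrices by 3x3 expansion, apply the
#' singlet/doublet/noise size rules and mark cell centers, then measure
#' each cell's PPD on the untouched duplicate (copy 2) and classify
#' live/dead against the viability constant. Reports counts, viability,
#' concentration (when conversion parameters are configured) and the
#' bounding-box size distribution.
#'
#' @param image a [gray_image()] (or a path readable by
#'   [read_gray_image()]).
#' @param config a [pipeline_config()].
#' @return An [analysis_result()].
#' @export
analyze <- function(image, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) image <- read_gray_image(image)
  if (!is_gray_image(image)) image <- gray_image(image)

  plane <- binarize(image, config = config$binarization)
  grown <- grow_clusters(plane)
  clusters <- grown$clusters
  clusters$class <- classify_cluster(clusters$bbox_height,
                                     clusters$bbox_width)
  marked <- mark_centers(grown$plane, clusters)
  detections <- classify_detections(image, marked$detections,
                                    config$viability)

  if (!is.null(config$debug_dir)) {
    dir.create(config$debug_dir, showWarnings = FALSE, recursive = TRUE)
    export_label_plane(plane, file.path(config$debug_dir,
                                        "binarized.png"))
    export_label_plane(grown$plane, file.path(config$debug_dir,
                                              "expanded.png"))
    export_label_plane(marked$plane, file.path(config$debug_dir,
                                               "centers.png"))
  }

  n_total <- count_cells(detections)
  n_dead <- sum(detections$state == "DEAD")
  n_live <- n_total - n_dead
  conc <- NA_real_
  if (!is.null(config$concentration)) {
    cp <- config$concentration
    if (cp$mode == "area_volume" && is.null(cp$fov_area_mm2))
      cp$fov_area_mm2 <- nrow(image) * ncol(image) *
        (config$pixel_pitch_um / 1000)^2
    conc <- concentration(n_total, cp)
  }
  viab <- if (n_total > 0) viability_percent(n_live, n_dead) else NA_real_

  analysis_result(n_total = n_total, n_live = n_live, n_dead = n_dead,
                  concentration = conc, viability = viab,
                  size_distribution = size_histogram(detections),
                  detections = detections)
}
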
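#' Concentration conversion parameters
#'
#' Two conversion modes are supported. `"hemocytometer"` multiplies the
#' average grid count by a volume-and-unit conversion factor (10,000 for
#' the standard chamber) and the dilution ratio. `"area_volume"` converts a
#' full field-of-view count through the imaged volume: `count / (fov_area *
#' chamber_depth) * 1000 * dilution` (mm^3 to mL), the conversion a
#' lens-free imager applies to its single wide FOV.
#'
#' @param mode `"hemocytometer"` or `"area_volume"`.
#' @param volume_factor 1/mL, hemocytometer mode; default 10000.
#' @param fov_area_mm2 imaged area in mm^2 (area_volume mode).
#' @param chamber_depth_mm sample chamber depth in mm (area_volume mode).
#'   The default 0.1 mm is a typical counting-chamber depth, supplied as an
#'   illustrative value only -- no canonical instrument depth exists.
#' @param dilution_factor dimensionless dilution ratio, `>= 1`.
#' @return A list of class `"concentration_params"`.
#' @export
concentration_params <- function(mode = c("hemocytometer", "area_volume"),
                                 volume_factor = 10000,
                                 fov_area_mm2 = NULL,
                                 chamber_depth_mm = 0.1,
                                 dilution_factor = 1) {
  mode <- match.arg(mode)
  stopifnot(dilution_factor >= 1)
  if (mode == "hemocytometer") {
    if (volume_factor <= 0) stop("volume_factor must be > 0", call. = FALSE)
  } else {
    if (!is.null(fov_area_mm2) && fov_area_mm2 <= 0)
      stop("fov_area_mm2 must be > 0", call. = FALSE)
    if (chamber_depth_mm <= 0)
      stop("chamber_depth_mm must be > 0", call. = FALSE)
  }
  structure(list(mode = mode, volume_factor = volume_factor,
                 fov_area_mm2 = fov_area_mm2,
                 chamber_depth_mm = chamber_depth_mm,
                 dilution_factor = dilution_factor),
            class = "concentration_params")
}

#' Convert a cell count to concentration (cells/mL)
#'
#' @param count cell count (average grid count in hemocytometer mode, FOV
#'   count in area_volume mode); `>= 0`.
#' @param params a [concentration_params()].
#' @return Concentration in cells/mL.
#' @export
concentration <- function(count, params) {
  stopifnot(all(count >= 0))
  if (params$mode == "hemocytometer") {
    count * params$volume_factor * params$dilution_factor
  } else {
    if (is.null(params$fov_area_mm2))
      stop("fov_area_mm2 required for area_volume mode", call. = FALSE)
    count / (params$fov_area_mm2 * params$chamber_depth_mm) * 1000 *
      params$dilution_factor
  }
}

#' Field-of-view area
#'
#' @param width_mm,height_mm FOV side lengths in mm.
#' @return Area in mm^2.
#' @export
fov_area <- function(width_mm, height_mm) {
  stopifnot(width_mm > 0, height_mm > 0)
  width_mm * height_mm
}

#' Viability percentage
#'
#' The default `"standard"` mode computes `(n_total - n_dead) / n_total *
#' 100`, the fraction of detected cells that are live. The `"as_printed"`
#' mode computes `(n_live - n_dead) / n_live * 100`; it is retained for
#' fidelity with the instrument's published formula but gives 0 % when
#' live and dead counts are equal (a sample usually described as "50 %
#' viable") and can go negative, so it is not the default.
#'
#' @param n_live,n_dead live and dead counts.
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @return Percent; `standard` mode is in `[0, 100]`, `as_printed` is
#'   `<= 100` and may be negative.
#' @export
viability_percent <- function(n_live, n_dead,
                              mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(n_live >= 0, n_dead >= 0)
  n_total <- n_live + n_dead
  if (mode == "standard") {
    if (n_total == 0) stop("viability undefined: no cells", call. = FALSE)
    (n_total - n_dead) / n_total * 100
  } else {
    if (n_live == 0) stop("viability undefined: no live cells", call. = FALSE)
    (n_live - n_dead) / n_live * 100
  }
}

#' Counting error rate against a reference instrument
#'
#' `ER = (sum(reference) - sum(test)) / sum(reference) * 100`, the relative
#' deviation of summed test concentrations from summed reference
#' (hemocytometer) concentrations.
#'
#' @param reference,test paired concentration series (cells/mL), equal
#'   lengths `>= 1`.
#' @return ER in percent.
#' @export
error_rate <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) < 1L)
    stop("reference and test must be paired series of equal length",
         call. = FALSE)
  sr <- sum(reference)
  if (sr <= 0) stop("ER undefined: reference sum is not positive",
                    call. = FALSE)
  (sr - sum(test)) / sr * 100
}

#' Coefficient of variation of replicate measurements
#'
#' Sample standard deviation (n-1 denominator) over the mean, in percent.
#'
#' @param x replicate observations (cells/mL), `length >= 2`.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2L)
    stop("CV needs at least 2 observations", call. = FALSE)
  mu <- mean(x)
  if (mu == 0) stop("CV undefined: mean is zero", call. = FALSE)
  stats::sd(x) / mu * 100
}

#' Improvement ratio between two instruments' metric values
#'
#' For comparison tables of per-category ER or CV values, the mean of the
#' element-wise ratios `reference / test`: how many times smaller the test
#' instrument's error metric is.
#'
#' @param reference,test equal-length vectors of a metric (percent) for the
#'   instrument used as reference and the instrument under test.
#' @return Mean ratio (dimensionless).
#' @export
improvement_ratio <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) < 1L)
    stop("reference and test must have equal length", call. = FALSE)
  if (any(test <= 0)) stop("test metric values must be positive",
                           call. = FALSE)
  mean(reference / test)
}
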
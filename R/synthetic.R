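# run expr with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scene configuration
#'
#' Parameters of the synthetic lens-free shadow scene generator. Defaults
#' emulate a 5-Mpx, 2.2 um-pitch bare CMOS sensor imaging cells of 5-80 um
#' diameter; smaller crops (e.g. 512 x 512) are the practical choice for
#' tests. Dead cells cast shadows with contrast `dead_amplitude_factor`
#' (default 3.54) times that of live cells. The default `live_amplitude`
#' of 55 is the largest live contrast whose 3.54x dead counterpart still
#' fits the 8-bit range around the default background of 200 without
#' clipping, given the renderer's dip/ring split. `noise_sd` of 2 counts
#' emulates typical 8-bit sensor read noise.
#'
#' @param image_height,image_width scene size in pixels (defaults
#'   1944 x 2592, the full 5-Mpx frame).
#' @param pixel_pitch_um sensor pixel pitch, um/pixel (default 2.2).
#' @param background_level background intensity (default 200).
#' @param live_amplitude peak-to-peak contrast of a live-cell pattern
#'   (default 55).
#' @param dead_amplitude_factor dead/live contrast ratio (default 3.54).
#' @param cell_diameter_um_range diameter range cells are drawn from, um
#'   (default 5-80).
#' @param noise_sd additive Gaussian sensor noise, intensity counts
#'   (default 2).
#' @param debris_rate number of sub-cellular debris specks per scene
#'   (default 10); rendered small and at 0.3x live amplitude, so a sensibly
#'   chosen gray offset rejects them at binarization.
#' @param clump_rate number of supra-cellular clumps per scene (default 2);
#'   rendered large enough that their candidate footprint exceeds the 20x20
#'   singlet box and is discarded as noise.
#' @param seed integer RNG seed; required for reproducible scenes.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(image_height = 1944L, image_width = 2592L,
                         pixel_pitch_um = 2.2, background_level = 200,
                         live_amplitude = 55, dead_amplitude_factor = 3.54,
                         cell_diameter_um_range = c(5, 80),
                         noise_sd = 2, debris_rate = 10L, clump_rate = 2L,
                         seed = NULL) {
  stopifnot(image_height >= 32L, image_width >= 32L, pixel_pitch_um > 0,
            live_amplitude > 0, dead_amplitude_factor > 1,
            length(cell_diameter_um_range) == 2L,
            cell_diameter_um_range[1] > 0,
            diff(cell_diameter_um_range) >= 0,
            noise_sd >= 0, debris_rate >= 0L, clump_rate >= 0L)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 pixel_pitch_um = pixel_pitch_um,
                 background_level = background_level,
                 live_amplitude = live_amplitude,
                 dead_amplitude_factor = dead_amplitude_factor,
                 cell_diameter_um_range = cell_diameter_um_range,
                 noise_sd = noise_sd,
                 debris_rate = as.integer(debris_rate),
                 clump_rate = as.integer(clump_rate),
                 seed = seed),
            class = "scene_config")
}

# unscaled radial profile: central dark dip, bright first-order ring,
# smooth taper to zero at the patch edge (radius = diameter)
patch_delta <- function(diameter_px, amplitude) {
  rc <- diameter_px / 2
  R <- diameter_px
  n <- as.integer(ceiling(R))
  ax <- -n:n
  r <- sqrt(outer(ax^2, ax^2, "+"))
  s <- ifelse(r <= R,
              -cos(pi * r / rc) * exp(-r / (2 * rc)) * (1 - (r / R)^2)^2,
              0)
  rng <- max(s) - min(s)
  amplitude * s / rng
}

# clump/island profile: a broad featureless dark blob (an extended opaque
# mass shows no clean single-cell Airy structure); super-Gaussian falloff
clump_delta <- function(diameter_px, amplitude) {
  n <- as.integer(ceiling(0.9 * diameter_px))
  ax <- -n:n
  r <- sqrt(outer(ax^2, ax^2, "+"))
  -amplitude * exp(-(r / (diameter_px / 2))^8)
}

#' Render one synthetic diffraction shadow patch
#'
#' A radially symmetric pattern with a central dark extremum (the
#' zero-order shadow) and a surrounding bright counter-extremum ring (the
#' first-order lobe), scaled so that the peak-to-peak distance over the
#' patch equals `amplitude` to within quantization. This is a parametric
#' stand-in for the physical diffraction pattern: the analysis consumes
#' only contrast and footprint size, so a controlled-PPD profile suffices.
#'
#' @param diameter_px nominal pattern diameter in pixels, `>= 2`.
#' @param amplitude peak-to-peak contrast in intensity counts.
#' @param background background intensity (default 200).
#' @return A [gray_image()] patch of side `2 * ceiling(diameter_px) + 1`.
#' @export
render_shadow_patch <- function(diameter_px, amplitude, background = 200) {
  stopifnot(diameter_px >= 2, amplitude >= 0)
  if (amplitude == 0) {
    n <- as.integer(ceiling(diameter_px))
    return(gray_image(matrix(round_half_up(background), 2L * n + 1L,
                             2L * n + 1L)))
  }
  vals <- round_half_up(background + patch_delta(diameter_px, amplitude))
  if (any(vals < 0) || any(vals > 255))
    warning("pattern amplitude exceeds the 8-bit range; values clipped",
            call. = FALSE)
  gray_image(clip8(vals))
}

place_objects <- function(H, W, diameters, max_tries = 2000L) {
  k <- length(diameters)
  rows <- integer(k); cols <- integer(k)
  ord <- order(diameters, decreasing = TRUE)  # big objects first
  for (idx in seq_len(k)) {
    i <- ord[idx]
    n <- ceiling(diameters[i])
    lo_r <- n + 1L; hi_r <- H - n
    lo_c <- n + 1L; hi_c <- W - n
    if (hi_r < lo_r || hi_c < lo_c)
      stop("object of diameter ", diameters[i],
           " px does not fit in the scene", call. = FALSE)
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      r <- lo_r + sample.int(hi_r - lo_r + 1L, 1L) - 1L
      c <- lo_c + sample.int(hi_c - lo_c + 1L, 1L) - 1L
      prev <- ord[seq_len(idx - 1L)]
      if (idx == 1L) { ok <- TRUE } else {
        mind <- (diameters[i] + diameters[prev]) / 2 + 3
        ok <- all((rows[prev] - r)^2 + (cols[prev] - c)^2 >= mind^2)
      }
      if (ok) { rows[i] <- r; cols[i] <- c; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(
        "scene capacity exceeded: placed %d of %d objects without overlap",
        idx - 1L, k), call. = FALSE)
  }
  cbind(row = rows, col = cols)
}

#' Generate a synthetic shadow scene with ground truth
#'
#' Places the requested live and dead cells (plus the configured debris
#' specks and clumps) at non-overlapping positions, renders each object's
#' diffraction patch additively over a uniform background, adds zero-mean
#' Gaussian sensor noise and quantizes to 8 bits. Reproducible from
#' `config$seed`; the manifest records every object's position, diameter,
#' amplitude and class.
#'
#' @param config a [scene_config()].
#' @param n_live,n_dead numbers of live and dead cells to place.
#' @param diameter_um optional explicit cell diameter(s) in um (recycled
#'   over cells) instead of sampling from the configured range -- e.g. a
#'   monodisperse bead sample.
#' @return A list with `image` (a [gray_image()]) and `manifest` (class
#'   `"scene_manifest"`: `objects` data frame with `row, col, diameter_px,
#'   amplitude, class`, plus `seed` and the `config` snapshot).
#' @export
generate_scene <- function(config, n_live, n_dead, diameter_um = NULL) {
  stopifnot(inherits(config, "scene_config"), n_live >= 0, n_dead >= 0)
  H <- config$image_height; W <- config$image_width
  with_local_seed(config$seed, {
    n_cells <- n_live + n_dead
    drange <- config$cell_diameter_um_range
    cell_d_um <- if (is.null(diameter_um)) {
      stats::runif(n_cells, drange[1], drange[2])
    } else rep_len(diameter_um, n_cells)
    cell_d_px <- pmax(2, cell_d_um / config$pixel_pitch_um)
    n_debris <- config$debris_rate
    n_clump <- config$clump_rate
    debris_d <- if (n_debris) stats::runif(n_debris, 2, 4) else numeric()
    clump_d <- if (n_clump) stats::runif(n_clump, 35, 55) else numeric()
    cls <- c(rep("LIVE", n_live), rep("DEAD", n_dead),
             rep("DEBRIS", n_debris), rep("CLUMP", n_clump))
    amp <- c(rep(config$live_amplitude, n_live),
             rep(config$live_amplitude * config$dead_amplitude_factor,
                 n_dead),
             rep(0.3 * config$live_amplitude, n_debris),
             rep(1.8 * config$live_amplitude, n_clump))
    dia <- c(cell_d_px, debris_d, clump_d)
    delta <- matrix(0, H, W)
    objects <- data.frame(row = integer(0), col = integer(0),
                          diameter_px = numeric(0), amplitude = numeric(0),
                          class = character(0), stringsAsFactors = FALSE)
    if (length(dia)) {
      pos <- place_objects(H, W, dia)
      for (i in seq_along(dia)) {
        pd <- if (cls[i] == "CLUMP") clump_delta(dia[i], amp[i])
              else patch_delta(dia[i], amp[i])
        n <- (nrow(pd) - 1L) %/% 2L
        rr <- (pos[i, "row"] - n):(pos[i, "row"] + n)
        cc <- (pos[i, "col"] - n):(pos[i, "col"] + n)
        delta[rr, cc] <- delta[rr, cc] + pd
      }
      objects <- data.frame(row = pos[, "row"], col = pos[, "col"],
                            diameter_px = dia, amplitude = amp,
                            class = cls, stringsAsFactors = FALSE)
    }
    vals <- config$background_level + delta
    if (config$noise_sd > 0)
      vals <- vals + stats::rnorm(H * W, 0, config$noise_sd)
    image <- gray_image(clip8(round_half_up(vals)))
    manifest <- structure(list(objects = objects, seed = config$seed,
                               config = config),
                          class = "scene_manifest")
    list(image = image, manifest = manifest)
  })
}

#' @export
print.scene_manifest <- function(x, ...) {
  cat(sprintf("<scene_manifest: %d objects (%s), seed %s>\n",
              nrow(x$objects),
              paste(names(table(x$objects$class)),
                    table(x$objects$class), sep = "=", collapse = ", "),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Generate a synthetic serial-dilution series
#'
#' Emulates a bead/cell serial-dilution counting experiment: for each
#' nominal concentration and replicate, one scene whose expected object
#' count is `concentration * fov_area * chamber_depth / 1000` (the imaged
#' volume in mL). By default the expected count is realized with minimal
#' variance (`floor(lambda)` plus a Bernoulli remainder): a desk-scale
#' scene holds tens of objects where the full-size experiment holds
#' thousands, and injecting full Poisson shot noise at that scale would
#' mask the linearity of the counting chain that the series is meant to
#' exercise. `count_mode = "poisson"` gives physical Poisson occupancy
#' instead. Per-scene seeds are derived deterministically from
#' `config$seed`.
#'
#' @param config a [scene_config()]; `config$seed` must be set.
#' @param nominal_concentrations vector of nominal concentrations,
#'   cells/mL (the emulated detection range is 1e4-1e6).
#' @param replicates scenes per concentration (default 3).
#' @param chamber_depth_mm sample chamber depth, mm (default 0.1).
#' @param bead_diameter_um object diameter, um; default 10 (monodisperse
#'   polystyrene beads).
#' @param count_mode `"expected"` (default) or `"poisson"`, see Details.
#' @return A list of class `"dilution_series"`; each element has `image`,
#'   `manifest`, `nominal_concentration`, `replicate` and `n_objects`.
#'   Attributes `fov_area_mm2` and `chamber_depth_mm` carry the geometry.
#' @export
generate_dilution_series <- function(config, nominal_concentrations,
                                     replicates = 3L,
                                     chamber_depth_mm = 0.1,
                                     bead_diameter_um = 10,
                                     count_mode = c("expected", "poisson")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(config, "scene_config"),
            all(nominal_concentrations > 0), replicates >= 1L)
  if (is.null(config$seed))
    stop("a seed is required for a reproducible dilution series",
         call. = FALSE)
  fov_mm2 <- config$image_height * config$image_width *
    (config$pixel_pitch_um / 1000)^2
  lambda <- nominal_concentrations * fov_mm2 * chamber_depth_mm / 1000
  if (any(lambda < 1))
    warning("some nominal concentrations imply an expected count below 1",
            call. = FALSE)
  grid <- expand.grid(replicate = seq_len(replicates),
                      level = seq_along(nominal_concentrations))
  counts <- with_local_seed(config$seed, {
    lam <- lambda[grid$level]
    if (count_mode == "poisson") stats::rpois(nrow(grid), lam)
    else floor(lam) + stats::rbinom(nrow(grid), 1L, lam - floor(lam))
  })
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    sc <- generate_scene(cfg_i, n_live = counts[i], n_dead = 0L,
                         diameter_um = bead_diameter_um)
    out[[i]] <- list(image = sc$image, manifest = sc$manifest,
                     nominal_concentration =
                       nominal_concentrations[grid$level[i]],
                     replicate = grid$replicate[i],
                     n_objects = counts[i])
  }
  structure(out, class = "dilution_series", fov_area_mm2 = fov_mm2,
            chamber_depth_mm = chamber_depth_mm)
}

#' Linearity of counts against nominal concentrations
#'
#' Least-squares fit of observed counts (or concentrations) on nominal
#' concentrations, as used to validate a counting instrument over a
#' dilution series.
#'
#' @param nominal nominal concentrations.
#' @param observed observed counts or concentrations, same length.
#' @return A list with `r_squared`, `slope` and `intercept`.
#' @export
dilution_linearity <- function(nominal, observed) {
  stopifnot(length(nominal) == length(observed), length(nominal) >= 3L)
  fit <- stats::lm(observed ~ nominal)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}

#' Score detections against a scene manifest
#'
#' Greedy nearest-pair matching of detections to the manifest's LIVE/DEAD
#' objects within `max_dist` pixels. Debris and clumps are not counted as
#' true objects (the analyzer is supposed to reject them), so any
#' detection matching nothing counts against precision.
#'
#' @param manifest a `scene_manifest`.
#' @param detections detection data frame ([analyze()] /
#'   [classify_detections()]).
#' @param max_dist maximum center distance for a match, pixels (default 6).
#' @return A list with `n_true`, `n_detected`, `true_positives`, `recall`,
#'   `precision` and `viability_accuracy` (fraction of matched detections
#'   whose live/dead state equals the object's class).
#' @export
evaluate_detections <- function(manifest, detections, max_dist = 6) {
  obj <- manifest$objects
  cells <- obj[obj$class %in% c("LIVE", "DEAD"), , drop = FALSE]
  n_true <- nrow(cells); n_det <- nrow(detections)
  if (n_true == 0L || n_det == 0L)
    return(list(n_true = n_true, n_detected = n_det, true_positives = 0L,
                recall = if (n_true == 0L) NA_real_ else 0,
                precision = if (n_det == 0L) NA_real_ else 0,
                viability_accuracy = NA_real_))
  d2 <- outer(cells$row, detections$row, "-")^2 +
    outer(cells$col, detections$col, "-")^2
  d2[d2 > max_dist^2] <- Inf
  matched_state_ok <- logical(0)
  tp <- 0L
  while (any(is.finite(d2))) {
    k <- arrayInd(which.min(d2), dim(d2))
    tp <- tp + 1L
    matched_state_ok <- c(matched_state_ok,
                          cells$class[k[1L]] == detections$state[k[2L]])
    d2[k[1L], ] <- Inf
    d2[, k[2L]] <- Inf
  }
  list(n_true = n_true, n_detected = n_det, true_positives = tp,
       recall = tp / n_true, precision = tp / n_det,
       viability_accuracy = if (tp) mean(matched_state_ok) else NA_real_)
}
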
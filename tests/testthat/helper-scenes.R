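# Shared scene designs for pipeline-level tests: mid-size cells (15-35 um)
# on a 512x512 crop, with debris and clumps present so the rejection rules
# are always exercised.

test_scene_config <- function(seed, noise_sd = 2, n_debris = 10,
                              n_clumps = 2, diameter_um = c(15, 35)) {
  scene_config(image_height = 512L, image_width = 512L,
               cell_diameter_um_range = diameter_um,
               noise_sd = noise_sd, debris_rate = n_debris,
               clump_rate = n_clumps, seed = seed)
}

# gray offset midway between the debris and live-cell core shadow depths,
# measured from the renderer itself
calibrated_gray_offset <- function(config) {
  bg <- config$background_level
  d_live <- mean(config$cell_diameter_um_range) / config$pixel_pitch_um
  live_depth <- bg - min(render_shadow_patch(d_live, config$live_amplitude,
                                             bg))
  debris_depth <- bg - min(render_shadow_patch(3, 0.3 * config$live_amplitude,
                                               bg))
  (live_depth + debris_depth) / 2
}

# PPD threshold midway between live and dead pattern contrasts
calibrated_ppd_threshold <- function(config) {
  (config$live_amplitude +
     config$live_amplitude * config$dead_amplitude_factor) / 2
}

test_pipeline_config <- function(scene_cfg, ...) {
  pipeline_config(gray_offset = calibrated_gray_offset(scene_cfg),
                  ppd_threshold = calibrated_ppd_threshold(scene_cfg), ...)
}
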
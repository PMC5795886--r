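test_that("rendered patch PPD equals the requested amplitude within quantization", {
  for (d in c(4, 8, 15, 30)) for (a in c(20, 55, 120)) {
    patch <- render_shadow_patch(d, a, background = 130)
    expect_lte(abs((max(patch) - min(patch)) - a), 1,
               label = sprintf("d=%d a=%d", d, a))
  }
  flat <- render_shadow_patch(10, 0, background = 130)
  expect_true(all(flat == 130L))
})

test_that("patches have a dark central extremum and a bright first-order ring", {
  patch <- render_shadow_patch(16, 55, background = 180)
  ctr <- (nrow(patch) + 1L) %/% 2L
  expect_equal(min(patch), patch[ctr, ctr])  # zero-order dark core
  expect_gt(max(patch), 180)                 # ring rises above background
  # radial symmetry: the four axis neighbours at equal radius agree
  expect_equal(patch[ctr + 5, ctr], patch[ctr - 5, ctr])
  expect_equal(patch[ctr, ctr + 5], patch[ctr, ctr - 5])
})

test_that("dead/live patch contrast ratio matches the configured 3.54 factor", {
  live <- render_shadow_patch(12, 55, background = 200)
  dead <- render_shadow_patch(12, 55 * 3.54, background = 200)
  ppd_live <- max(live) - min(live)
  ppd_dead <- max(dead) - min(dead)
  expect_lte(abs(ppd_dead / ppd_live - 3.54), 0.1)
})

test_that("amplitudes beyond the 8-bit range warn and clip", {
  expect_warning(patch <- render_shadow_patch(10, 400, background = 200),
                 "clip")
  expect_true(all(patch >= 0 & patch <= 255))
})

test_that("an empty scene is a uniform background with an empty manifest", {
  cfg <- scene_config(image_height = 64, image_width = 64, noise_sd = 0,
                      debris_rate = 0, clump_rate = 0, seed = 1)
  sc <- generate_scene(cfg, n_live = 0, n_dead = 0)
  expect_true(all(sc$image == 200L))
  expect_equal(nrow(sc$manifest$objects), 0L)
})

test_that("scenes are byte-identical across runs with the same seed", {
  cfg <- test_scene_config(seed = 61)
  a <- generate_scene(cfg, n_live = 12, n_dead = 8)
  b <- generate_scene(cfg, n_live = 12, n_dead = 8)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$manifest$objects, b$manifest$objects)
  cfg2 <- test_scene_config(seed = 62)
  c <- generate_scene(cfg2, n_live = 12, n_dead = 8)
  expect_false(identical(unclass(a$image), unclass(c$image)))
})

test_that("manifest class counts equal the requested composition", {
  cfg <- test_scene_config(seed = 63, n_debris = 7, n_clumps = 3)
  sc <- generate_scene(cfg, n_live = 11, n_dead = 6)
  tab <- table(sc$manifest$objects$class)
  expect_equal(unname(tab[c("LIVE", "DEAD", "DEBRIS", "CLUMP")]),
               c(11L, 6L, 7L, 3L), ignore_attr = TRUE)
})

test_that("placement respects the minimum separation and scene capacity errors", {
  cfg <- test_scene_config(seed = 64)
  sc <- generate_scene(cfg, n_live = 30, n_dead = 0)
  o <- sc$manifest$objects
  cells <- o[o$class == "LIVE", ]
  d2 <- as.matrix(stats::dist(cells[, c("row", "col")]))^2
  diag(d2) <- Inf
  mind <- outer(cells$diameter_px, cells$diameter_px, "+") / 2 + 3
  expect_true(all(d2 >= mind^2 - 1e-9))

  tiny <- scene_config(image_height = 128, image_width = 128,
                       cell_diameter_um_range = c(60, 80),
                       debris_rate = 0, clump_rate = 0, seed = 65)
  expect_error(generate_scene(tiny, n_live = 60, n_dead = 0), "capacity")
})

test_that("dilution series counts track the expected occupancy and stay monotone", {
  cfg <- test_scene_config(seed = 66, n_debris = 0, n_clumps = 0)
  conc <- c(2e5, 6e5, 1.6e6)
  series <- generate_dilution_series(cfg, conc, replicates = 3)
  expect_length(series, 9L)
  fov <- attr(series, "fov_area_mm2")
  expect_equal(fov, 512 * 512 * (2.2 / 1000)^2)
  lambda <- conc * fov * 0.1 / 1000
  means <- vapply(seq_along(conc), function(i) {
    mean(vapply(series[(i - 1) * 3 + 1:3], function(s) s$n_objects,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(abs(means - lambda) <= 1))  # low-variance realization
  # manifest totals equal the realized counts
  for (s in series)
    expect_equal(nrow(s$manifest$objects), s$n_objects)
})

test_that("dilution series requires a seed and flags sub-unity occupancy", {
  cfg <- test_scene_config(seed = NULL)
  expect_error(generate_dilution_series(cfg, 2e5), "seed")
  cfg2 <- test_scene_config(seed = 67)
  expect_warning(generate_dilution_series(cfg2, 1e3, replicates = 1),
                 "below 1")
})

test_that("detection scoring matches known configurations", {
  manifest <- list(objects = data.frame(
    row = c(10, 30, 50), col = c(10, 30, 50),
    diameter_px = 8, amplitude = 55,
    class = c("LIVE", "LIVE", "DEAD"), stringsAsFactors = FALSE))
  det <- data.frame(row = c(11, 29, 90), col = c(10, 31, 90),
                    state = c("LIVE", "DEAD", "LIVE"),
                    stringsAsFactors = FALSE)
  ev <- evaluate_detections(manifest, det)
  expect_equal(ev$true_positives, 2L)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$viability_accuracy, 0.5)  # one of two matches mislabeled
})
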
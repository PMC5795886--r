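plane_from_pixels <- function(H, W, pixels) {
  m <- matrix(255L, H, W)
  for (p in pixels) m[p[1], p[2]] <- 96L
  label_plane(m)
}

test_that("an isolated candidate forms a 1x1 single-member cluster", {
  out <- grow_clusters(plane_from_pixels(9, 9, list(c(5, 5))))
  expect_equal(nrow(out$clusters), 1L)
  expect_equal(out$clusters$bbox_height, 1L)
  expect_equal(out$clusters$bbox_width, 1L)
  expect_equal(out$clusters$member_count, 1L)
  expect_equal(out$plane[5, 5], SENTINELS$cluster)
})

test_that("candidates within one 3x3 window merge into one cluster", {
  out <- grow_clusters(plane_from_pixels(9, 9, list(c(4, 4), c(5, 5))))
  expect_equal(nrow(out$clusters), 1L)
  expect_equal(out$clusters$member_count, 2L)
  # diagonal chain: each step inside the previous 3x3 matrix
  chain <- lapply(1:6, function(i) c(i, i))
  out2 <- grow_clusters(plane_from_pixels(9, 9, chain))
  expect_equal(nrow(out2$clusters), 1L)
  expect_equal(out2$clusters$member_count, 6L)
})

test_that("a 2-pixel gap separates clusters; every candidate is absorbed", {
  out <- grow_clusters(plane_from_pixels(9, 9, list(c(2, 2), c(2, 5))))
  expect_equal(nrow(out$clusters), 2L)
  expect_false(any(out$plane == SENTINELS$candidate))
})

test_that("cluster partition equals 8-connected components on random planes", {
  set.seed(31)
  for (density in c(0.02, 0.10, 0.35)) {
    for (rep in 1:5) {
      plane <- random_candidate_plane(96, 96, density)
      out <- grow_clusters(plane)
      expect_identical(cluster_signatures(out$clusters),
                       oracle_signatures(unclass(plane) == 96L),
                       label = sprintf("density %.2f rep %d", density, rep))
      expect_true(all(out$clusters$member_count >= 1L))
      expect_equal(sum(out$clusters$member_count),
                   sum(unclass(plane) == 96L))
    }
  }
})

test_that("clusters are reported in raster order of their seed pixel", {
  plane <- plane_from_pixels(20, 20,
                             list(c(1, 10), c(3, 2), c(3, 15), c(10, 1)))
  out <- grow_clusters(plane)
  expect_equal(out$clusters$seed_row, c(1L, 3L, 3L, 10L))
  expect_equal(out$clusters$seed_col, c(10L, 2L, 15L, 1L))
})

test_that("size rules: singlet within 20x20, doublet within 20x40 either way, else noise", {
  expect_equal(classify_cluster(18, 15), "SINGLET")
  expect_equal(classify_cluster(18, 36), "DOUBLET")
  expect_equal(classify_cluster(36, 18), "DOUBLET")  # orientation symmetric
  expect_equal(classify_cluster(30, 30), "NOISE")
  expect_equal(classify_cluster(20, 20), "SINGLET")  # boundary: still one cell
  expect_equal(classify_cluster(20, 40), "DOUBLET")  # boundary: still a pair
  expect_equal(classify_cluster(21, 21), "NOISE")
  expect_equal(classify_cluster(20, 41), "NOISE")
})

test_that("singlet centers sit at the floor midpoint of the bounding box", {
  cl <- data.frame(seed_row = 10L, seed_col = 20L, bbox_top = 10L,
                   bbox_left = 20L, bbox_height = 9L, bbox_width = 9L,
                   member_count = 40L)
  out <- mark_centers(label_plane(matrix(255L, 40, 40)), cl)
  expect_equal(out$detections$row, 14L)
  expect_equal(out$detections$col, 24L)
  expect_equal(out$plane[14, 24], SENTINELS$center)
  expect_equal(sum(out$plane == SENTINELS$center), 1L)
})

test_that("doublet centers sit at the quarter points of the long axis", {
  # 18x36 box: two overlapping 20-wide sub-boxes, centers at offsets
  # floor(36/4) and floor(3*36/4) from the left edge
  cl <- data.frame(seed_row = 1L, seed_col = 1L, bbox_top = 1L,
                   bbox_left = 1L, bbox_height = 18L, bbox_width = 36L,
                   member_count = 300L)
  out <- mark_centers(label_plane(matrix(255L, 40, 40)), cl)
  d <- out$detections
  expect_equal(nrow(d), 2L)
  expect_equal(d$col, c(1L + 9L, 1L + 27L))
  expect_equal(d$row, c(9L, 9L))
  # each center lies inside its assigned half-box
  expect_true(all(d$col >= d$bbox_left & d$col <= d$bbox_left + d$bbox_w - 1L))
  # vertical doublet mirrors the construction
  clv <- transform(cl, bbox_height = 36L, bbox_width = 18L)
  dv <- mark_centers(label_plane(matrix(255L, 40, 40)), clv)$detections
  expect_equal(dv$row, c(1L + 9L, 1L + 27L))
  expect_equal(dv$col, c(9L, 9L))
})

test_that("noise clusters leave an all-background plane and no detections", {
  cl <- data.frame(seed_row = 1L, seed_col = 1L, bbox_top = 1L,
                   bbox_left = 1L, bbox_height = 30L, bbox_width = 30L,
                   member_count = 700L)
  out <- mark_centers(label_plane(matrix(255L, 40, 40)), cl)
  expect_equal(nrow(out$detections), 0L)
  expect_true(all(out$plane == SENTINELS$background))
})

test_that("cell count equals yields (1/2/0) and the center-pixel census", {
  expect_equal(count_cells(data.frame()), 0L)
  set.seed(32)
  for (rep in 1:10) {
    plane <- random_candidate_plane(128, 128, 0.05)
    grown <- grow_clusters(plane)
    cls <- classify_cluster(grown$clusters$bbox_height,
                            grown$clusters$bbox_width)
    grown$clusters$class <- cls
    marked <- mark_centers(grown$plane, grown$clusters)
    yield <- sum((cls == "SINGLET") + 2L * (cls == "DOUBLET"))
    expect_equal(count_cells(marked$detections), yield)
    expect_equal(sum(marked$plane == SENTINELS$center), yield)
    expect_true(all(marked$plane %in% c(SENTINELS$center,
                                        SENTINELS$background)))
  }
})

test_that("detections are deterministic for identical planes", {
  set.seed(33)
  plane <- random_candidate_plane(100, 100, 0.08)
  run <- function() {
    g <- grow_clusters(plane)
    mark_centers(g$plane, g$clusters)$detections
  }
  expect_identical(run(), run())
})

test_that("adding a well-separated singlet increases the count by exactly one", {
  set.seed(34)
  for (rep in 1:5) {
    plane <- random_candidate_plane(80, 80, 0.03)
    count0 <- {
      g <- grow_clusters(plane)
      g$clusters$class <- classify_cluster(g$clusters$bbox_height,
                                           g$clusters$bbox_width)
      count_cells(mark_centers(g$plane, g$clusters)$detections)
    }
    # find a 9x9 all-background window, plant a 3x3 singlet in its middle
    m <- unclass(plane)
    planted <- FALSE
    for (t in 1:500) {
      r <- sample(4:76, 1); c <- sample(4:76, 1)
      if (all(m[(r - 4):(r + 4), (c - 4):(c + 4)] == 255L)) {
        m[(r - 1):(r + 1), (c - 1):(c + 1)] <- 96L
        planted <- TRUE
        break
      }
    }
    expect_true(planted)
    g <- grow_clusters(label_plane(m))
    g$clusters$class <- classify_cluster(g$clusters$bbox_height,
                                         g$clusters$bbox_width)
    count1 <- count_cells(mark_centers(g$plane, g$clusters)$detections)
    expect_equal(count1, count0 + 1L)
  }
})
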
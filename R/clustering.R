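#' Grow candidate pixels into cluster matrices by 3x3 expansion
#'
#' Scans the binarized plane sequentially from the top-left pixel. Each
#' CANDIDATE (96) pixel seeds a 3x3 matrix; every candidate found inside the
#' matrix is absorbed (relabeled CLUSTER, 175) and itself seeds a further
#' 3x3 matrix, until no matrix can be expanded. Chaining 3x3 windows this
#' way is exactly the transitive closure of 8-connectivity, so each cluster
#' is one 8-connected component of the candidate mask; the property tests
#' enforce that equivalence against an independent component-labeling
#' oracle.
#'
#' @param plane a [label_plane()] with states in `{96, 255}`.
#' @return A list with `clusters`, a data frame (one row per cluster, in
#'   raster order of the seed pixel) with columns `seed_row, seed_col,
#'   bbox_top, bbox_left, bbox_height, bbox_width, member_count`, and
#'   `plane`, the expanded [label_plane()] in which absorbed pixels carry
#'   the CLUSTER (175) state.
#' @export
grow_clusters <- function(plane) {
  M <- unclass(plane)
  H <- nrow(M); W <- ncol(M)
  cand <- which(M == SENTINELS$candidate)
  empty <- data.frame(seed_row = integer(), seed_col = integer(),
                      bbox_top = integer(), bbox_left = integer(),
                      bbox_height = integer(), bbox_width = integer(),
                      member_count = integer())
  if (length(cand) == 0L)
    return(list(clusters = empty, plane = label_plane(M)))
  cr <- (cand - 1L) %% H + 1L
  cc <- (cand - 1L) %/% H + 1L
  seeds <- cand[order(cr, cc)]  # raster order: top row first, left to right

  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  CAND <- SENTINELS$candidate; CLUS <- SENTINELS$cluster

  res <- vector("list", length(seeds))
  n_clusters <- 0L
  stack <- integer(1024L)
  for (s in seeds) {
    if (M[s] != CAND) next
    n_clusters <- n_clusters + 1L
    M[s] <- CLUS
    top <- 1L; stack[1L] <- s
    rmin <- rmax <- (s - 1L) %% H + 1L
    cmin <- cmax <- (s - 1L) %/% H + 1L
    members <- 0L
    while (top > 0L) {
      i <- stack[top]; top <- top - 1L
      members <- members + 1L
      r <- (i - 1L) %% H + 1L
      c <- (i - 1L) %/% H + 1L
      if (r < rmin) rmin <- r else if (r > rmax) rmax <- r
      if (c < cmin) cmin <- c else if (c > cmax) cmax <- c
      nr <- r + dr; nc <- c + dc
      ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
      ni <- (nc[ok] - 1L) * H + nr[ok]
      ni <- ni[M[ni] == CAND]
      if (length(ni)) {
        M[ni] <- CLUS
        if (top + length(ni) > length(stack))
          stack <- c(stack, integer(length(stack)))
        stack[(top + 1L):(top + length(ni))] <- ni
        top <- top + length(ni)
      }
    }
    res[[n_clusters]] <- c((s - 1L) %% H + 1L, (s - 1L) %/% H + 1L,
                           rmin, cmin, rmax - rmin + 1L, cmax - cmin + 1L,
                           members)
  }
  tab <- do.call(rbind, res[seq_len(n_clusters)])
  clusters <- data.frame(seed_row = tab[, 1L], seed_col = tab[, 2L],
                         bbox_top = tab[, 3L], bbox_left = tab[, 4L],
                         bbox_height = tab[, 5L], bbox_width = tab[, 6L],
                         member_count = tab[, 7L])
  list(clusters = clusters, plane = label_plane(M))
}

#' Classify a cluster matrix as singlet, doublet or noise
#'
#' A cluster fitting within 20x20 pixels is one cell (SINGLET). A larger
#' cluster is noise, except when its bounding box still fits within 20x40
#' pixels (either orientation -- attached cell pairs have no preferred
#' axis), in which case it is two attached cells (DOUBLET). Anything larger
#' -- clumps and islands included -- is NOISE and yields no cells.
#'
#' @param bbox_height,bbox_width cluster bounding-box dimensions in pixels
#'   (vectorized).
#' @param max_single side of the singlet box, default 20.
#' @param max_double long side of the doublet box, default 40.
#' @return Character vector over `{"SINGLET", "DOUBLET", "NOISE"}`.
#' @export
classify_cluster <- function(bbox_height, bbox_width,
                             max_single = 20L, max_double = 40L) {
  singlet <- bbox_height <= max_single & bbox_width <= max_single
  doublet <- !singlet &
    ((bbox_height <= max_single & bbox_width <= max_double) |
     (bbox_height <= max_double & bbox_width <= max_single))
  ifelse(singlet, "SINGLET", ifelse(doublet, "DOUBLET", "NOISE"))
}

# floor midpoint of a 1-based span of length n starting at `start`
floor_center <- function(start, n) start + (n - 1L) %/% 2L

#' Mark cell centers and build the detection table
#'
#' Produces the final label plane, in which every counted cell is a single
#' CENTER (60) pixel on a BACKGROUND (255) field. A SINGLET contributes one
#' center at the geometric center of its bounding box (ties broken toward
#' the top-left). A DOUBLET contributes two centers at the quarter points
#' of its long axis -- the centers of the two overlapping 20x20 matrices
#' laid over the pair -- each reported with its half of the bounding box.
#' NOISE clusters contribute nothing.
#'
#' @param plane a [label_plane()] (used for its dimensions; the final plane
#'   is rebuilt from scratch).
#' @param clusters cluster data frame from [grow_clusters()], with a
#'   `class` column from [classify_cluster()] (added automatically when
#'   absent).
#' @return A list with `plane` (final [label_plane()], states in
#'   `{60, 255}`) and `detections`, a data frame with columns `id, row,
#'   col, bbox_top, bbox_left, bbox_h, bbox_w, ppd, state`.
#' @export
mark_centers <- function(plane, clusters) {
  if (is.null(clusters$class))
    clusters$class <- classify_cluster(clusters$bbox_height,
                                       clusters$bbox_width)
  H <- nrow(plane); W <- ncol(plane)
  rows <- integer(0); cols <- integer(0)
  bt <- integer(0); bl <- integer(0); bh <- integer(0); bw <- integer(0)
  for (k in seq_len(nrow(clusters))) {
    cl <- clusters[k, ]
    if (cl$class == "SINGLET") {
      rows <- c(rows, floor_center(cl$bbox_top, cl$bbox_height))
      cols <- c(cols, floor_center(cl$bbox_left, cl$bbox_width))
      bt <- c(bt, cl$bbox_top); bl <- c(bl, cl$bbox_left)
      bh <- c(bh, cl$bbox_height); bw <- c(bw, cl$bbox_width)
    } else if (cl$class == "DOUBLET") {
      if (cl$bbox_width >= cl$bbox_height) {  # long axis along columns
        w <- cl$bbox_width
        half1 <- w %/% 2L
        rows <- c(rows, rep(floor_center(cl$bbox_top, cl$bbox_height), 2L))
        cols <- c(cols, cl$bbox_left + w %/% 4L,
                  cl$bbox_left + (3L * w) %/% 4L)
        bt <- c(bt, rep(cl$bbox_top, 2L))
        bl <- c(bl, cl$bbox_left, cl$bbox_left + half1)
        bh <- c(bh, rep(cl$bbox_height, 2L))
        bw <- c(bw, half1, w - half1)
      } else {                                # long axis along rows
        h <- cl$bbox_height
        half1 <- h %/% 2L
        rows <- c(rows, cl$bbox_top + h %/% 4L,
                  cl$bbox_top + (3L * h) %/% 4L)
        cols <- c(cols, rep(floor_center(cl$bbox_left, cl$bbox_width), 2L))
        bt <- c(bt, cl$bbox_top, cl$bbox_top + half1)
        bl <- c(bl, rep(cl$bbox_left, 2L))
        bh <- c(bh, half1, h - half1)
        bw <- c(bw, rep(cl$bbox_width, 2L))
      }
    }
  }
  final <- matrix(SENTINELS$background, H, W)
  if (length(rows)) final[cbind(rows, cols)] <- SENTINELS$center
  detections <- data.frame(
    id = seq_along(rows), row = rows, col = cols,
    bbox_top = bt, bbox_left = bl, bbox_h = bh, bbox_w = bw,
    ppd = rep(NA_real_, length(rows)),
    state = rep("UNCLASSIFIED", length(rows)),
    stringsAsFactors = FALSE)
  list(plane = label_plane(final), detections = detections)
}

#' Count detected cells
#'
#' The number of CENTER points in the final plane reflects the number of
#' cells in the sample; this is simply the length of the detection table.
#'
#' @param detections detection data frame from [mark_centers()].
#' @return Integer count.
#' @export
count_cells <- function(detections) nrow(detections)
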
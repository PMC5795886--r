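# Independent reference computations for property tests. These must never
# call into the code paths they check.

# 8-connected component labeling of a logical mask via graph components
oracle_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  node <- match(seq_len(H * W), idx)  # pixel -> node id (NA if background)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  edges <- NULL
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nr <- r + d[1L]; nc <- c + d[2L]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    ni <- (nc[ok] - 1L) * H + nr[ok]
    hit <- !is.na(node[ni])
    edges <- rbind(edges, cbind(node[idx[ok]][hit], node[ni][hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lapply(split(idx, memb), sort)
}

# bbox/size signature of a pixel-index component, for partition comparison
component_signature <- function(pixels, H) {
  r <- (pixels - 1L) %% H + 1L
  c <- (pixels - 1L) %/% H + 1L
  c(bbox_top = min(r), bbox_left = min(c),
    bbox_height = diff(range(r)) + 1L, bbox_width = diff(range(c)) + 1L,
    member_count = length(pixels))
}

# sorted matrix of component signatures from the oracle
oracle_signatures <- function(mask) {
  comps <- oracle_components(mask)
  if (length(comps) == 0L)
    return(matrix(numeric(), 0L, 5L))
  sig <- t(vapply(comps, component_signature, numeric(5), H = nrow(mask)))
  sig <- unname(sig)
  colnames(sig) <- NULL
  sig[order(sig[, 1L], sig[, 2L], sig[, 5L]), , drop = FALSE]
}

cluster_signatures <- function(clusters) {
  sig <- as.matrix(clusters[, c("bbox_top", "bbox_left", "bbox_height",
                                "bbox_width", "member_count")])
  sig <- unname(sig)
  storage.mode(sig) <- "double"
  sig[order(sig[, 1L], sig[, 2L], sig[, 5L]), , drop = FALSE]
}

# per-tile means with explicit loops (remainder absorbed by last tile)
oracle_tile_means <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  hs <- H %/% rows; ws <- W %/% cols
  out <- matrix(NA_real_, rows, cols)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    r0 <- (i - 1L) * hs + 1L
    r1 <- if (i == rows) H else i * hs
    c0 <- (j - 1L) * ws + 1L
    c1 <- if (j == cols) W else j * ws
    s <- 0; n <- 0L
    for (r in r0:r1) for (cc in c0:c1) { s <- s + m[r, cc]; n <- n + 1L }
    out[i, j] <- s / n
  }
  out
}

# exhaustive per-pixel max-min window scan
oracle_ppd <- function(m, row, col, side) {
  h <- (side - 1L) %/% 2L
  lo <- 255; hi <- 0
  for (r in max(1L, row - h):min(nrow(m), row + h))
    for (cc in max(1L, col - h):min(ncol(m), col + h)) {
      v <- m[r, cc]
      if (v < lo) lo <- v
      if (v > hi) hi <- v
    }
  hi - lo
}

random_candidate_plane <- function(H, W, density) {
  mask <- matrix(stats::runif(H * W) < density, H, W)
  plane <- matrix(255L, H, W)
  plane[mask] <- 96L
  label_plane(plane)
}
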
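# Independent oracles used across the suite. Each deliberately takes a
# different route than the package implementation.

# Reference sRGB -> Lab: matrix derived from the sRGB primary chromaticities
# and the D65 white (0.3127, 0.3290), rather than the published matrix.
ref_rgb_to_lab <- function(rgb255) {
  xy2XYZ <- function(xy) c(xy[1] / xy[2], 1, (1 - xy[1] - xy[2]) / xy[2])
  prim <- list(r = c(0.64, 0.33), g = c(0.30, 0.60), b = c(0.15, 0.06))
  C <- sapply(prim, xy2XYZ)
  wh <- xy2XYZ(c(0.3127, 0.3290))
  M <- C %*% diag(solve(C, wh))
  s <- rgb255 / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(M)
  fr <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                           t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- fr(xyz[, 1] / wh[1]); fy <- fr(xyz[, 2] / wh[2]); fz <- fr(xyz[, 3] / wh[3])
  cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

# Naive Otsu: O(levels x pixels) scan recomputing class statistics from the
# raw quantized values at every candidate cut.
naive_otsu <- function(x, levels = 256L) {
  q <- as.integer(round(as.numeric(x) * (levels - 1L)))
  best_k <- NA_integer_; best_v <- -Inf
  for (k in 0:(levels - 2L)) {
    lo <- q[q <= k]; hi <- q[q > k]
    if (length(lo) == 0 || length(hi) == 0) v <- 0
    else {
      w0 <- length(lo) / length(q); w1 <- 1 - w0
      v <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  (best_k + 0.5) / (levels - 1L)
}

# Naive DBSCAN via all-pairs distances. Returns core-pixel cluster partition
# (list of sorted linear-index vectors), the noise set, and border pixels
# with the set of clusters each is reachable from.
naive_dbscan <- function(mask, R, MinPxs) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) return(list(core_clusters = list(), noise = integer(0),
                          border = list()))
  h <- nrow(mask)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  d2 <- outer(r, r, "-")^2 + outer(c, c, "-")^2
  nb <- d2 <= R^2
  core <- rowSums(nb) >= MinPxs
  # density-connect core pixels (BFS over the core-core neighbor graph)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in which(core)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nbrs <- which(nb[v, ] & core & is.na(comp))
      comp[nbrs] <- cid
      queue <- c(queue, nbrs)
    }
  }
  border <- list()
  noise <- integer(0)
  for (i in which(!core)) {
    reach <- unique(comp[nb[i, ] & core])
    if (length(reach) == 0) noise <- c(noise, idx[i])
    else border[[as.character(idx[i])]] <- sort(reach)
  }
  core_clusters <- lapply(seq_len(cid), function(k) sort(idx[which(comp == k)]))
  list(core_clusters = core_clusters, noise = sort(noise), border = border)
}

# Canonical form of a partition: set of sorted member vectors, sorted by
# first element, so partitions compare independently of cluster ids.
canonical_partition <- function(clusters) {
  cl <- lapply(unname(clusters), function(x) as.integer(sort(x)))
  cl[order(vapply(cl, function(x) if (length(x)) x[1] else NA_integer_,
                  numeric(1)))]
}

# Neighbor counts within radius R, for identifying core pixels in tests.
shift_count <- function(m, R) {
  vesselquant:::shift_sum(m, vesselquant:::disk_offsets(R))
}

# Small synthetic annulus mask for wall-cleanup tests.
annulus_mask <- function(h = 80, w = 80, r_in = 14, r_out = 30) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- sqrt((rows - (h + 1) / 2)^2 + (cols - (w + 1) / 2)^2)
  rr > r_in & rr <= r_out
}

# Lab image of constant color blocks, for clustering fixtures.
lab_from_matrix <- function(L, a = NULL, b = NULL) {
  if (is.null(a)) a <- matrix(0, nrow(L), ncol(L))
  if (is.null(b)) b <- matrix(0, nrow(L), ncol(L))
  vesselquant:::new_lab_image(L, a, b)
}
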
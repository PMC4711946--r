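#' Density-based clustering of foreground pixels (DBSCAN)
#'
#' Groups foreground pixels of a binary image into density-connected clusters
#' and labels isolated pixels as noise. A pixel is a *core* pixel when the
#' circle of radius `R` around it (Euclidean distance between pixel centers,
#' the pixel itself included) contains at least `MinPxs` foreground pixels.
#' Clusters are the density-connected components of core pixels together with
#' the border pixels reachable from them; foreground pixels reachable from no
#' core pixel are noise.
#'
#' Pixels are visited in a fixed column-major scan order, so the labeling is
#' fully deterministic: scan order only affects cluster numbering and which
#' cluster claims a border pixel reachable from several, never the core
#' structure.
#'
#' @param mask Logical matrix; `TRUE` = foreground.
#' @param cfg List with `R` (neighborhood radius in pixels, > 0) and `MinPxs`
#'   (minimum foreground count per neighborhood, >= 1). See
#'   [dbscan_config()].
#' @return Integer matrix of the same shape: `0` for background pixels, `-1`
#'   for noise, and `1, 2, ...` cluster ids, with attribute `n_clusters`.
#' @export
dbscan_mask <- function(mask, cfg = dbscan_config()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  stopifnot(cfg$R > 0, cfg$MinPxs >= 1)
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  labels[mask] <- -1L
  if (!any(mask)) {
    attr(labels, "n_clusters") <- 0L
    return(labels)
  }

  off <- disk_offsets(cfg$R)
  counts <- shift_sum(mask, off)
  core <- mask & counts >= cfg$MinPxs

  cl <- 0L
  core_idx <- which(core)
  for (seed in core_idx) {
    if (labels[seed] != -1L) next
    cl <- cl + 1L
    labels[seed] <- cl
    frontier <- seed
    while (length(frontier) > 0L) {
      nb <- neighbor_indices(frontier, off, h, w)
      nb <- nb[mask[nb] & labels[nb] == -1L]
      if (length(nb) == 0L) break
      labels[nb] <- cl
      frontier <- nb[core[nb]]
    }
  }
  attr(labels, "n_clusters") <- cl
  labels
}

#' DBSCAN parameters
#'
#' Defaults `R = 3`, `MinPxs = 9` are sized for dust and dirt specks of a few
#' pixels at 4x magnification: a speck of fewer than `MinPxs` pixels can
#' contain no core pixel and is labeled noise.
#'
#' @param R Neighborhood radius in pixels (> 0).
#' @param MinPxs Minimum foreground-pixel count per neighborhood (>= 1).
#' @return A list of class `dbscan_config`.
#' @export
dbscan_config <- function(R = 3, MinPxs = 9) {
  stopifnot(R > 0, MinPxs >= 1)
  structure(list(R = R, MinPxs = MinPxs), class = "dbscan_config")
}

# Integer (dr, dc) offsets whose Euclidean length is <= R, as a 2-column matrix.
disk_offsets <- function(R) {
  r <- floor(R)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= R^2, , drop = FALSE])
}

# Foreground count within the offset neighborhood of every pixel.
shift_sum <- function(mask, off) {
  h <- nrow(mask); w <- ncol(mask)
  counts <- matrix(0L, h, w)
  m <- mask * 1L
  for (i in seq_len(nrow(off))) {
    dr <- off[i, 1]; dc <- off[i, 2]
    r1 <- max(1L, 1L + dr); r2 <- min(h, h + dr)
    c1 <- max(1L, 1L + dc); c2 <- min(w, w + dc)
    if (r1 > r2 || c1 > c2) next
    counts[r1:r2, c1:c2] <- counts[r1:r2, c1:c2] +
      m[(r1 - dr):(r2 - dr), (c1 - dc):(c2 - dc)]
  }
  counts
}

# In-bounds linear indices of all offset neighbors of the given linear indices.
neighbor_indices <- function(idx, off, h, w) {
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  nr <- rep(r, times = nrow(off)) + rep(off[, 1], each = length(idx))
  nc <- rep(c, times = nrow(off)) + rep(off[, 2], each = length(idx))
  ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
  unique((nc[ok] - 1L) * h + nr[ok])
}
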
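#' Mask a Lab image to the vessel wall, white background
#'
#' Removes everything outside the wall region from the color image by
#' painting it white (L* = 100, a* = 0, b* = 0), the input expected by the
#' color clustering: wall pixels keep their stain colors and all remaining
#' pixels collapse into a single near-white background group. Defect pixels
#' flagged invalid during pre-processing are painted white as well, so folds
#' and blood never contribute to a tissue component.
#'
#' @param lab A `lab_image` (typically the contrast-enhanced image).
#' @param wall A [wall_region()].
#' @return A `lab_image` with non-wall and invalid pixels set to white.
#' @export
mask_to_white <- function(lab, wall) {
  stopifnot(inherits(lab, "lab_image"), inherits(wall, "wall_region"))
  if (!all(dim(wall$mask) == dim(lab$L))) stop("wall mask dimensions do not match image")
  out <- !wall$mask | !lab$valid
  L <- lab$L; a <- lab$a; b <- lab$b
  L[out] <- 100; a[out] <- 0; b[out] <- 0
  new_lab_image(L, a, b, lab$valid)
}

#' k-means color clustering in CIELab
#'
#' Partitions pixels into `k` color groups by restarted Lloyd iteration with
#' the Euclidean CIELab color distance. The clustering cost is
#' \deqn{J = \sum_{j=1}^{k} \sum_{i=1}^{n_j} \mathrm{distance}(px_{ij}, centroid_j),}
#' the total color distance of pixels to their group centroid. Each restart
#' draws `k` distinct pixels as initial centroids, alternates
#' nearest-centroid assignment with mean-color centroid updates, and stops
#' when the relative change in `J` falls below `tol` (or when an update would
#' increase `J`, in which case the update is discarded — with mean updates
#' and an unsquared cost, monotonicity is enforced rather than automatic).
#' The restart with the lowest final cost wins; with a fixed seed the whole
#' model is reproducible.
#'
#' A cluster emptied during assignment is rescued by re-seeding its centroid
#' at the pixel currently farthest from its own centroid.
#'
#' @param pixels `n x 3` numeric matrix of (L*, a*, b*) rows.
#' @param cfg A [kmeans_config()].
#' @return A `cluster_model`: list with `k`, `centroids` (`k x 3`),
#'   `assignment` (integer vector in `1..k`), `J`, `n_j`, `J_trace` (per
#'   iteration of the winning restart) and `restart_J`.
#' @export
kmeans_lab <- function(pixels, cfg = kmeans_config()) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 3)
  n <- nrow(pixels)
  k <- cfg$k
  if (n < k) stop("fewer pixels than clusters")
  distinct <- !duplicated(pixels)
  if (sum(distinct) < k) stop(sprintf("fewer than k = %d distinct colors", k))
  distinct_idx <- which(distinct)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  best <- NULL
  restart_J <- numeric(cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    centroids <- pixels[sample(distinct_idx, k), , drop = FALSE]
    fit <- lloyd_run(pixels, centroids, cfg$max_iter, cfg$tol)
    restart_J[r] <- fit$J
    if (is.null(best) || fit$J < best$J) best <- fit
  }
  structure(list(k = k, centroids = best$centroids,
                 assignment = best$assignment, J = best$J, n_j = best$n_j,
                 J_trace = best$J_trace, restart_J = restart_J),
            class = "cluster_model")
}

lloyd_run <- function(px, centroids, max_iter, tol) {
  k <- nrow(centroids)
  J_trace <- numeric(0)
  J_prev <- Inf
  for (it in seq_len(max_iter)) {
    asg <- nearest_centroid(px, centroids)
    # rescue emptied clusters at the most poorly represented pixel
    d <- assigned_distances(px, centroids, asg)
    for (j in which(tabulate(asg, nbins = k) == 0L)) {
      far <- which.max(d)
      centroids[j, ] <- px[far, ]
      asg[far] <- j
      d[far] <- 0
    }
    J_assign <- sum(assigned_distances(px, centroids, asg))
    upd <- centroids
    for (j in seq_len(k)) {
      upd[j, ] <- colMeans(px[asg == j, , drop = FALSE])
    }
    J_upd <- sum(assigned_distances(px, upd, asg))
    if (J_upd <= J_assign) {
      centroids <- upd
      J_new <- J_upd
    } else {
      J_new <- J_assign   # mean update would raise the unsquared cost; stop
    }
    J_trace <- c(J_trace, J_new)
    if (is.finite(J_prev) &&
        (J_prev - J_new) <= tol * max(J_prev, .Machine$double.eps)) break
    J_prev <- J_new
  }
  asg <- nearest_centroid(px, centroids)
  J <- sum(assigned_distances(px, centroids, asg))
  J_trace <- c(J_trace, J)
  list(centroids = centroids, assignment = asg, J = J,
       n_j = tabulate(asg, nbins = k), J_trace = J_trace)
}

nearest_centroid <- function(px, centroids) {
  d2 <- vapply(seq_len(nrow(centroids)), function(j) {
    rowSums((px - matrix(centroids[j, ], nrow(px), 3, byrow = TRUE))^2)
  }, numeric(nrow(px)))
  max.col(-d2, ties.method = "first")
}

assigned_distances <- function(px, centroids, asg) {
  sqrt(rowSums((px - centroids[asg, , drop = FALSE])^2))
}

#' k-means parameters
#'
#' `k = 3` groups pixels into smooth muscle, extracellular matrix and the
#' white background. Multiple random restarts guard against the non-convex
#' cost's local minima.
#'
#' @param k Number of groups (>= 2; default 3).
#' @param n_restarts Random restarts (>= 1).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Relative decrease in the cost J below which a run is converged.
#' @param seed Optional RNG seed for bit-reproducible clustering.
#' @return A list of class `kmeans_config`.
#' @export
kmeans_config <- function(k = 3L, n_restarts = 10L, max_iter = 300L,
                          tol = 1e-4, seed = NULL) {
  stopifnot(k >= 2, n_restarts >= 1, max_iter >= 1, tol > 0)
  structure(list(k = as.integer(k), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol, seed = seed),
            class = "kmeans_config")
}

#' Recompute the clustering cost J from a model
#'
#' @param model A `cluster_model`.
#' @param pixels The `n x 3` pixel matrix the model was fitted on.
#' @return The total within-cluster color distance.
#' @export
cluster_cost <- function(model, pixels) {
  sum(assigned_distances(pixels, model$centroids, model$assignment))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model k=%d, J=%.2f, n_j=(%s)>\n",
              x$k, x$J, paste(x$n_j, collapse = ", ")))
  invisible(x)
}

#' Map color clusters to tissue roles
#'
#' With `k = 3`, the cluster whose centroid lies nearest to white
#' (100, 0, 0) in CIELab is the background; of the remaining two, the
#' centroid with the larger a* (redder, as Masson's trichrome stains muscle
#' red) is the smooth-muscle-fiber group and the other (bluish/greenish
#' collagen stain) is the extracellular matrix. Exact ties are broken toward
#' the lower cluster index with a warning.
#'
#' @param model A `cluster_model` with `k = 3`.
#' @return Named integer vector with elements `background`, `SMF`, `ECM`
#'   giving the cluster index of each role (a bijection onto `1:3`).
#' @export
assign_roles <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3L) stop("role assignment requires k = 3")
  d_white <- lab_distance(model$centroids, c(100, 0, 0))
  if (anyDuplicated(d_white)) warning("tied distance to white; breaking tie by cluster index")
  bg <- which.min(d_white)
  rest <- setdiff(1:3, bg)
  a_vals <- model$centroids[rest, 2]
  if (a_vals[1] == a_vals[2]) warning("tied a* centroids; breaking tie by cluster index")
  smf <- rest[which.max(a_vals)]
  ecm <- setdiff(rest, smf)
  c(background = bg, SMF = smf, ECM = ecm)
}

#' Quantify component areas within the vessel wall
#'
#' Counts the pixels of the muscle and matrix clusters restricted to the
#' wall mask and normalizes by the wall area, giving measures comparable
#' across samples of different size:
#' \deqn{\bar A_{SMF} = A_{SMF} / A_{TOT}, \quad \bar A_{ECM} = A_{ECM} / A_{TOT}.}
#'
#' @param model A `cluster_model` fitted on the full masked image (pixels in
#'   column-major order of the image raster).
#' @param roles Role mapping from [assign_roles()].
#' @param wall A [wall_region()] with `A_TOT > 0`.
#' @return A `quantification`: list with `A_SMF`, `A_ECM`, `A_TOT`,
#'   `ratio_SMF`, `ratio_ECM`.
#' @export
quantify <- function(model, roles, wall) {
  stopifnot(inherits(wall, "wall_region"))
  if (wall$A_TOT <= 0) stop("empty wall region: A_TOT = 0")
  if (length(model$assignment) != length(wall$mask)) {
    stop("assignment length does not match wall raster")
  }
  in_wall <- as.logical(wall$mask)
  a_smf <- sum(model$assignment[in_wall] == roles[["SMF"]])
  a_ecm <- sum(model$assignment[in_wall] == roles[["ECM"]])
  structure(list(A_SMF = a_smf, A_ECM = a_ecm, A_TOT = wall$A_TOT,
                 ratio_SMF = a_smf / wall$A_TOT,
                 ratio_ECM = a_ecm / wall$A_TOT),
            class = "quantification")
}

#' @export
print.quantification <- function(x, ...) {
  cat(sprintf(
    "<quantification A_SMF=%d A_ECM=%d A_TOT=%d ratio_SMF=%.3f ratio_ECM=%.3f>\n",
    x$A_SMF, x$A_ECM, x$A_TOT, x$ratio_SMF, x$ratio_ECM))
  invisible(x)
}

#' Run the feature-extraction stage
#'
#' Masks the contrast-enhanced image to the wall with a white background,
#' clusters all pixels into k = 3 color groups, maps clusters to tissue
#' roles and quantifies normalized component areas.
#'
#' @param enhanced Contrast-enhanced `lab_image` from [preprocess_image()].
#' @param wall A [wall_region()].
#' @param config Pipeline configuration, see [default_config()].
#' @param seed Optional seed for the clustering restarts.
#' @return List with `model`, `roles`, `quant`, and `component_masks`
#'   (logical matrices for SMF and ECM restricted to the wall).
#' @export
segment_image <- function(enhanced, wall, config = default_config(), seed = NULL) {
  masked <- mask_to_white(enhanced, wall)
  px <- cbind(as.numeric(masked$L), as.numeric(masked$a), as.numeric(masked$b))
  km <- config$kmeans
  if (!is.null(seed)) km$seed <- seed
  model <- kmeans_lab(px, do.call(kmeans_config, km))
  roles <- assign_roles(model)
  quant <- quantify(model, roles, wall)
  h <- nrow(enhanced$L); w <- ncol(enhanced$L)
  comp <- lapply(c(SMF = "SMF", ECM = "ECM"), function(r) {
    matrix(model$assignment == roles[[r]], h, w) & wall$mask
  })
  list(model = model, roles = roles, quant = quant, component_masks = comp)
}
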
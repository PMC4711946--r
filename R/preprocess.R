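#' Fold-detection threshold from the lightness histogram
#'
#' Tissue folds appear as dark regions whose color no longer distinguishes
#' muscle from matrix, so they are detected by binarizing the lightness
#' channel at a low threshold. The threshold is the halfway point between 0
#' and the location of the first predominant peak of the lightness histogram:
#' in a typical section the first (darkest) peak is the vessel wall itself,
#' followed by peaks for the region outside the wall and the lumen.
#'
#' "First predominant peak" is made operational as the first local maximum of
#' the smoothed histogram, scanning from L* = 0 upward, whose height is at
#' least `prominence_fraction` of the global maximum. Plateaus (runs of equal
#' smoothed counts) count as a single peak located at their center.
#'
#' @param L Numeric matrix of L* values in \[0, 100\].
#' @param cfg List with `n_bins` (>= 2), `smoothing_window` (odd, >= 1) and
#'   `prominence_fraction` (in (0, 1)); see [fold_threshold_config()].
#' @return Threshold t = peak_location / 2, in \[0, 50\].
#' @export
fold_threshold <- function(L, cfg = fold_threshold_config()) {
  stopifnot(length(L) > 0)
  v <- as.numeric(L)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("unusable image: no finite lightness values")
  nb <- cfg$n_bins
  centers <- seq(0, 100, length.out = nb)
  idx <- pmin(nb - 1L, pmax(0L, as.integer(round(v / 100 * (nb - 1L))))) + 1L
  counts <- tabulate(idx, nbins = nb)

  wdw <- cfg$smoothing_window
  if (wdw > 1L) {
    padded <- c(rep(0, wdw %/% 2), counts, rep(0, wdw %/% 2))
    sm <- as.numeric(stats::filter(padded, rep(1 / wdw, wdw), sides = 2))
    sm <- sm[(wdw %/% 2 + 1):(wdw %/% 2 + nb)]
  } else {
    sm <- as.numeric(counts)
  }

  cutoff <- cfg$prominence_fraction * max(sm)
  runs <- rle(sm)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in seq_along(runs$values)) {
    left <- if (j == 1L) -Inf else runs$values[j - 1L]
    right <- if (j == length(runs$values)) -Inf else runs$values[j + 1L]
    if (runs$values[j] > left && runs$values[j] > right &&
        runs$values[j] >= cutoff && runs$values[j] > 0) {
      peak <- mean(centers[starts[j]:ends[j]])
      return(peak / 2)
    }
  }
  stop("unusable image: no predominant peak in the lightness histogram")
}

#' Fold-threshold parameters
#'
#' @param n_bins Histogram bin count over \[0, 100\] (default 101: unit-width
#'   bins centered on integer L* values).
#' @param smoothing_window Odd moving-average window in bins.
#' @param prominence_fraction Minimum peak height as a fraction of the global
#'   histogram maximum, in (0, 1).
#' @return A list of class `fold_threshold_config`.
#' @export
fold_threshold_config <- function(n_bins = 101L, smoothing_window = 5L,
                                  prominence_fraction = 0.25) {
  stopifnot(n_bins >= 2, smoothing_window >= 1, smoothing_window %% 2 == 1,
            prominence_fraction > 0, prominence_fraction < 1)
  structure(list(n_bins = as.integer(n_bins),
                 smoothing_window = as.integer(smoothing_window),
                 prominence_fraction = prominence_fraction),
            class = "fold_threshold_config")
}

#' Detect tissue folds by low-lightness thresholding
#'
#' @param lab A `lab_image`.
#' @param t Threshold in \[0, 100\], typically from [fold_threshold()].
#' @return A `binary_mask` (role `"defect"`), `TRUE` where L* < t.
#' @export
detect_folds <- function(lab, t) {
  stopifnot(inherits(lab, "lab_image"), t >= 0, t <= 100)
  binary_mask(lab$L < t, role = "defect")
}

#' Detect blood residues by color mask
#'
#' Blood traces bias the muscle-area measurement because their red hue is
#' close to the muscle stain. They are segmented by a color mask: an
#' inclusion ball in CIELab, centered on a reference blood color with a
#' radius wide enough to absorb sample-to-sample variation.
#'
#' @param lab A `lab_image`.
#' @param cm List with `center` (length-3 L*a*b* vector) and `radius`
#'   (>= 0); see [color_mask()].
#' @return A `binary_mask` (role `"defect"`), `TRUE` within the color ball.
#' @export
detect_blood <- function(lab, cm = color_mask()) {
  stopifnot(inherits(lab, "lab_image"), cm$radius >= 0)
  px <- cbind(as.numeric(lab$L), as.numeric(lab$a), as.numeric(lab$b))
  d <- lab_distance(px, cm$center)
  binary_mask(matrix(d <= cm$radius, nrow(lab$L), ncol(lab$L)),
              role = "defect")
}

#' Color mask (inclusion ball in CIELab)
#'
#' The default center/radius target the dark saturated red of residual blood
#' and were tuned on the synthetic generator's blood color; with real stains
#' they should be re-tuned on a subset of samples.
#'
#' @param center Length-3 numeric `(L, a, b)`.
#' @param radius Nonnegative Euclidean radius in CIELab units.
#' @return A list of class `color_mask`.
#' @export
color_mask <- function(center = c(35, 45, 25), radius = 18) {
  stopifnot(length(center) == 3, radius >= 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "color_mask")
}

#' Remove defect pixels from a Lab image
#'
#' Multiplies the lightness channel pixel-wise by the complement of each
#' defect mask, zeroing folds and blood residues, and clears the validity
#' flag on those pixels so that downstream statistics (contrast-stretch
#' range, Otsu histogram) are computed over surviving pixels only — the
#' injected zeros would otherwise drag the lightness minimum to 0.
#'
#' @param lab A `lab_image`.
#' @param masks List of defect `binary_mask`s (possibly empty).
#' @return A `lab_image` with zeroed L* and updated `valid` flags.
#' @export
remove_defects <- function(lab, masks) {
  stopifnot(inherits(lab, "lab_image"))
  L <- lab$L; valid <- lab$valid
  for (m in masks) {
    if (!all(dim(m) == dim(L))) stop("defect mask dimensions do not match image")
    L[m] <- 0
    valid[m] <- FALSE
  }
  new_lab_image(L, lab$a, lab$b, valid)
}

#' Contrast stretching of the lightness channel
#'
#' Remaps each valid lightness value L in \[Lmin, Lmax\] to the full
#' \[0, 100\] range via `round(100 * (L - Lmin) / (Lmax - Lmin))`, where Lmin
#' and Lmax are taken over valid pixels. Lightness-only stretching enhances
#' contrast while preserving hue. Invalid (defect) pixels stay 0.
#'
#' @param L Numeric matrix of L* values.
#' @param valid Logical matrix of the same shape; `NULL` means all valid.
#' @return Numeric matrix with valid pixels in \{0, ..., 100\}.
#' @export
contrast_stretch <- function(L, valid = NULL) {
  stopifnot(is.matrix(L))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(L), ncol(L))
  stopifnot(all(dim(valid) == dim(L)))
  vals <- L[valid]
  if (length(vals) < 2) stop("need at least 2 valid pixels")
  lmin <- min(vals); lmax <- max(vals)
  if (lmax == lmin) stop("constant image: contrast stretch undefined")
  out <- matrix(0, nrow(L), ncol(L))
  out[valid] <- round(100 * (L[valid] - lmin) / (lmax - lmin))
  out
}

#' Otsu's threshold by exhaustive between-class-variance search
#'
#' Chooses the global binarization threshold that maximizes the between-class
#' variance of the two resulting pixel classes, searching exhaustively over a
#' quantized level set. Values are quantized to `levels` levels on \[0, 1\];
#' candidate cuts fall between adjacent levels and the returned threshold is
#' the cut midpoint `(k + 0.5) / (levels - 1)`, so the two quantized classes
#' are separated strictly. Ties are broken toward the lowest threshold.
#'
#' @param x Numeric matrix with values in \[0, 1\] (lightness / 100).
#' @param valid Logical matrix; only valid pixels enter the histogram.
#' @param levels Quantization levels (default 256).
#' @return Threshold T in (0, 1).
#' @export
otsu_threshold <- function(x, valid = NULL, levels = 256L) {
  stopifnot(is.matrix(x), levels >= 2)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(x), ncol(x))
  v <- x[valid]
  if (length(v) < 2 || min(v) < 0 || max(v) > 1) {
    stop("need >= 2 valid values in [0, 1]")
  }
  q <- as.integer(round(v * (levels - 1L)))
  if (length(unique(q)) < 2) stop("constant image: no threshold separates it")
  counts <- tabulate(q + 1L, nbins = levels)
  n <- length(v)
  lev <- 0:(levels - 1L)
  w0 <- cumsum(counts) / n              # class {q <= k}, k = 0..levels-1
  s0 <- cumsum(counts * lev)
  mu <- s0[levels] / n
  mu0 <- ifelse(w0 > 0, s0 / (n * w0), 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (s0[levels] - s0) / (n * w1), 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2    # between-class variance at cut k
  k <- which.max(sigma_b[1:(levels - 1L)]) - 1L   # ties -> lowest k
  (k + 0.5) / (levels - 1L)
}

#' Clean the binarized wall mask with DBSCAN
#'
#' Removes the small dust and dirt objects outside the vessel wall and inside
#' the lumen that survive Otsu binarization, and fills pinholes in the wall.
#' Two clustering passes are run: (a) foreground (wall-candidate) pixels are
#' clustered and only the largest cluster is kept as the wall — all other
#' clusters and noise are dust/dirt; (b) the remaining non-wall pixels are
#' clustered and the two largest clusters (the region exterior to the wall
#' and the lumen) are kept as background, while every smaller non-wall
#' cluster or noise pixel is merged into the wall, closing pinholes.
#'
#' @param binary A `binary_mask` from Otsu binarization (foreground = wall
#'   candidate).
#' @param cfg A [dbscan_config()].
#' @return A [wall_region()] with the cleaned mask and its area `A_TOT`.
#' @export
clean_wall_mask <- function(binary, cfg = dbscan_config()) {
  stopifnot(is.matrix(binary), is.logical(binary))
  lab1 <- dbscan_mask(binary, cfg)
  ncl <- attr(lab1, "n_clusters")
  if (ncl == 0L) stop("segmentation failure: no wall cluster found")
  sizes <- tabulate(lab1[lab1 > 0L], nbins = ncl)
  wall <- lab1 == which.max(sizes)

  bg <- !wall
  lab2 <- dbscan_mask(bg, cfg)
  ncl2 <- attr(lab2, "n_clusters")
  if (ncl2 > 0L) {
    sizes2 <- tabulate(lab2[lab2 > 0L], nbins = ncl2)
    keep <- order(sizes2, decreasing = TRUE)[seq_len(min(2L, ncl2))]
    fill <- bg & !(lab2 %in% c(0L, keep))
    wall <- wall | fill
  }
  wall_region(binary_mask(wall, role = "wall"))
}

#' Run the full pre-processing stage
#'
#' Composes the cleaning pipeline: CIELab conversion, fold and blood defect
#' detection, pixel-wise defect removal, lightness contrast stretching, Otsu
#' binarization (the stained wall is darker than background and lumen, so
#' foreground = below threshold) and DBSCAN mask cleanup. Produces the two
#' outputs consumed by feature extraction: the contrast-enhanced color image
#' and the vessel-wall region.
#'
#' @param img An `H x W x 3` RGB array in \[0, 255\].
#' @param config Pipeline configuration, see [default_config()].
#' @return List with `enhanced` (`lab_image`, stretched L*), `wall`
#'   (`wall_region`), `fold_t`, `otsu_t` (the derived thresholds), and the
#'   intermediate `fold_mask` / `blood_mask`.
#' @export
preprocess_image <- function(img, config = default_config()) {
  lab <- rgb_to_lab(img)
  ft_cfg <- do.call(fold_threshold_config, config$fold_threshold)
  t_fold <- fold_threshold(lab$L, ft_cfg)
  folds <- detect_folds(lab, t_fold)
  blood <- detect_blood(lab, do.call(color_mask, config$blood_mask))
  cleaned <- remove_defects(lab, list(folds, blood))
  Ls <- contrast_stretch(cleaned$L, cleaned$valid)
  enhanced <- new_lab_image(Ls, cleaned$a, cleaned$b, cleaned$valid)
  t_otsu <- otsu_threshold(Ls / 100, cleaned$valid, config$otsu_levels)
  vq_log("fold threshold t = %.2f, Otsu T = %.4f", t_fold, t_otsu)
  candidate <- (Ls / 100 < t_otsu) & cleaned$valid
  wall <- clean_wall_mask(binary_mask(candidate, role = "wall"),
                          do.call(dbscan_config, config$dbscan))
  list(enhanced = enhanced, wall = wall, fold_t = t_fold, otsu_t = t_otsu,
       fold_mask = folds, blood_mask = blood)
}
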
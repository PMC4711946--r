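#' Convert an RGB raster image to CIELab
#'
#' Converts an 8-bit RGB image to the L*a*b* color space used throughout the
#' pipeline. The perceptual uniformity of CIELab makes Euclidean distance a
#' meaningful color-similarity measure for the stain-based clustering, and its
#' lightness channel L* (in \[0, 100\]) serves as the grayscale representation
#' for fold detection, contrast stretching and thresholding.
#'
#' The conversion assumes the sRGB encoding with a D65 white point, the
#' standard interpretation of 8-bit microscope camera output.
#'
#' @param img An `H x W x 3` numeric array with channel values in \[0, 255\]
#'   (integers or doubles), as returned by [read_rgb_image()].
#' @return A `lab_image`: a list with `H x W` matrices `L` (in \[0, 100\]),
#'   `a`, `b`, and a logical matrix `valid` (all `TRUE` initially) marking
#'   pixels that still carry usable tissue information.
#' @seealso [lab_to_rgb()] for the inverse, [lab_distance()] for Eq.-style
#'   color distances.
#' @export
rgb_to_lab <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("`img` must be an H x W x 3 array")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < 1L || w < 1L) stop("degenerate input: empty image")
  v <- as.numeric(img)
  if (anyNA(v) || min(v) < 0 || max(v) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  m <- matrix(v, ncol = 3L) / 255
  lab <- srgb_to_lab(m)
  new_lab_image(
    L = matrix(lab[, 1], h, w),
    a = matrix(lab[, 2], h, w),
    b = matrix(lab[, 3], h, w)
  )
}

# sRGB (IEC 61966-2-1) <-> CIELab, D65 white point. Published constants are
# used directly; the generic grDevices converter parameterizes D65 by a
# slightly different chromaticity, which shifts colors by ~0.3 Lab units.
.srgb_M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                    0.2126729, 0.7151522, 0.0721750,
                    0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
.d65 <- c(0.95047, 1, 1.08883)

srgb_to_lab <- function(m) {
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_M)
  fr <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                           t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- fr(xyz[, 1] / .d65[1])
  fy <- fr(xyz[, 2] / .d65[2])
  fz <- fr(xyz[, 3] / .d65[3])
  cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

lab_to_srgb <- function(lab) {
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  fi <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- cbind(fi(fx) * .d65[1], fi(fy) * .d65[2], fi(fz) * .d65[3])
  lin <- xyz %*% t(solve(.srgb_M))
  lin <- pmin(pmax(lin, 0), 1)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

#' Convert a CIELab image back to an 8-bit RGB array
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped to \[0, 255\].
#' Used by the synthetic generator, which paints tissue in L*a*b* coordinates.
#'
#' @param lab A `lab_image`.
#' @return An `H x W x 3` integer array in \[0, 255\].
#' @export
lab_to_rgb <- function(lab) {
  stopifnot(inherits(lab, "lab_image"))
  h <- nrow(lab$L); w <- ncol(lab$L)
  m <- cbind(as.numeric(lab$L), as.numeric(lab$a), as.numeric(lab$b))
  rgb <- lab_to_srgb(m)
  arr <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(as.integer(round(255 * rgb[, ch])), h, w)
  arr[arr < 0L] <- 0L
  arr[arr > 255L] <- 255L
  arr
}

new_lab_image <- function(L, a, b, valid = NULL) {
  stopifnot(is.matrix(L), all(dim(a) == dim(L)), all(dim(b) == dim(L)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(L), ncol(L))
  structure(list(L = L, a = a, b = b, valid = valid), class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf(
    "<lab_image %d x %d, L* in [%.1f, %.1f], %d invalid pixel(s)>\n",
    nrow(x$L), ncol(x$L), min(x$L), max(x$L), sum(!x$valid)
  ))
  invisible(x)
}

#' Euclidean distance between colors in CIELab
#'
#' The color-similarity measure of the pipeline: the Euclidean norm of the
#' (L*, a*, b*) channel differences. Smaller distances mean more similar
#' colors. Vectorized over rows when matrices are supplied.
#'
#' @param p1,p2 Numeric length-3 vectors `(L, a, b)`, or `n x 3` matrices.
#' @return Nonnegative distance(s); zero iff the colors are equal.
#' @export
lab_distance <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, nrow = 1)
  if (is.null(dim(p2))) p2 <- matrix(p2, nrow = 1)
  d <- p1 - matrix(p2, nrow = nrow(p1), ncol = 3, byrow = nrow(p2) == 1)
  sqrt(rowSums(d * d))
}
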
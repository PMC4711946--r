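#' Construct a binary mask
#'
#' A binary mask is a logical `H x W` matrix with a declared role:
#' `"defect"` masks flag pixels to remove (folds, blood), a `"wall"` mask
#' delimits the vessel-wall study region, `"background"` marks everything
#' else. Internally foreground is always `TRUE`/1; renderers may invert for
#' display.
#'
#' @param values Logical matrix.
#' @param role One of `"defect"`, `"wall"`, `"background"`.
#' @return A `binary_mask` (logical matrix with a `role` attribute).
#' @export
binary_mask <- function(values, role = c("defect", "wall", "background")) {
  role <- match.arg(role)
  stopifnot(is.matrix(values), is.logical(values))
  structure(values, role = role, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask role=%s, %d x %d, area %d px>\n",
              attr(x, "role"), nrow(x), ncol(x), pixel_area(x)))
  invisible(x)
}

#' Area of a mask in pixels
#'
#' The area of any binary image is the number of foreground (TRUE) pixels,
#' i.e. the double sum of pixel values over rows and columns. All areas in
#' this package are reported in pixels; no physical calibration is applied.
#'
#' @param mask Logical matrix (a `binary_mask` or plain logical matrix).
#' @return Integer pixel count.
#' @export
pixel_area <- function(mask) {
  stopifnot(is.logical(mask))
  sum(mask)
}

#' Delimited vessel-wall region
#'
#' Couples the cleaned wall mask with its pixel area `A_TOT`, the
#' normalization denominator for the component area ratios.
#'
#' @param mask A `binary_mask` with role `"wall"`.
#' @return A `wall_region` list with elements `mask` and `A_TOT`.
#' @export
wall_region <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"), attr(mask, "role") == "wall")
  structure(list(mask = mask, A_TOT = pixel_area(mask)), class = "wall_region")
}

#' @export
print.wall_region <- function(x, ...) {
  cat(sprintf("<wall_region %d x %d, A_TOT = %d px>\n",
              nrow(x$mask), ncol(x$mask), x$A_TOT))
  invisible(x)
}
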
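#' Elliptical structuring element
#'
#' Builds the boolean mask of the axis-aligned ellipse inscribed in a
#' `width` x `height` rectangle, anchored at the centre cell.  A cell at
#' offset (r, c) from the anchor belongs to the mask iff
#' `(c/a)^2 + (r/b)^2 <= 1` with `a = (width-1)/2`, `b = (height-1)/2`
#' (degenerate axes fall back to the anchor row/column), which reproduces
#' the common library elliptical elements and guarantees a true anchor.
#'
#' @param width,height element size in pixels (>= 1).
#' @return an object of class `structuring_element`: a list with `mask`
#'   (logical matrix), `width`, `height` and `anchor` (row, col, 1-based).
#' @examples
#' make_elliptical_se(3, 3)$mask  # plus-shaped, corners excluded
#' @export
make_elliptical_se <- function(width, height) {
  if (length(width) != 1L || length(height) != 1L ||
      !is.finite(width) || !is.finite(height) || width < 1 || height < 1)
    stop("structuring element dimensions must be >= 1", call. = FALSE)
  width <- as.integer(width)
  height <- as.integer(height)
  a <- (width - 1) / 2
  b <- (height - 1) / 2
  anchor <- c(row = (height + 1L) %/% 2L, col = (width + 1L) %/% 2L)
  cc <- matrix(rep(seq_len(width) - anchor["col"], each = height), nrow = height)
  rr <- matrix(rep(seq_len(height) - anchor["row"], times = width), nrow = height)
  xs <- if (a > 0) cc / a else ifelse(cc == 0, 0, Inf)
  ys <- if (b > 0) rr / b else ifelse(rr == 0, 0, Inf)
  mask <- xs^2 + ys^2 <= 1
  structure(list(mask = mask, width = width, height = height, anchor = anchor),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring element %dx%d (%d active cells)\n",
              x$width, x$height, sum(x$mask)))
  invisible(x)
}

as_se <- function(se) {
  if (inherits(se, "structuring_element")) return(se)
  stop("expected a structuring_element (see make_elliptical_se)", call. = FALSE)
}

#' Grayscale erosion and dilation
#'
#' Sliding minimum (erosion) or maximum (dilation) over the structuring
#' element's neighbourhood.  Borders are handled by edge replication, so
#' constant images are fixed points and borders are not darkened or
#' brightened.  Output dimensions equal input dimensions.
#'
#' @param image numeric matrix (see [assert_gray_image()]).
#' @param se a `structuring_element`.
#' @return numeric matrix of the same size.
#' @export
gray_erode <- function(image, se) {
  assert_gray_image(image)
  se <- as_se(se)
  cpp_minmax_filter(image, se$mask, se$anchor["row"] - 1L, se$anchor["col"] - 1L, FALSE)
}

#' @rdname gray_erode
#' @export
gray_dilate <- function(image, se) {
  assert_gray_image(image)
  se <- as_se(se)
  cpp_minmax_filter(image, se$mask, se$anchor["row"] - 1L, se$anchor["col"] - 1L, TRUE)
}

#' Morphological mass highlighting
#'
#' Erosion with a small elliptical element removes speckle-scale bright
#' structure, then dilation with a large elliptical element inflates the
#' surviving bright regions into near-circular plateaus of roughly the
#' dilating element's footprint — the shape the circular mass template is
#' designed to match.  Note this is deliberately *not* a morphological
#' opening: the two elements differ (defaults 7x7 and 50x50).
#'
#' @param image numeric matrix.
#' @param erode_se,dilate_se structuring elements; defaults are elliptical
#'   7x7 and 50x50.
#' @return preprocessed image, same size as the input.
#' @export
preprocess_morphology <- function(image,
                                  erode_se = make_elliptical_se(7, 7),
                                  dilate_se = make_elliptical_se(50, 50)) {
  gray_dilate(gray_erode(image, erode_se), dilate_se)
}
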
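#' Bounding boxes and candidates
#'
#' A bounding box is the numeric vector `c(x, y, w, h)`: 0-based top-left
#' corner, half-open extents `[x, x+w) x [y, y+h)`, `w > 0`, `h > 0`.
#' Candidate sets are data frames with columns `x`, `y`, `w`, `h`,
#' `degree` (matching degree) and optionally `probability` (CNN mass
#' probability).  `bbox()` validates and normalizes a box; `box_center()`
#' and `center_to_corner()` convert losslessly between the corner form and
#' the centre form `(cx, cy, w, h)` used by the particle encoding.
#'
#' @param x,y top-left corner (pixels, 0-based).
#' @param w,h box width and height (pixels, > 0).
#' @return `bbox()`: named numeric vector `c(x, y, w, h)`.
#' @export
bbox <- function(x, y, w, h) {
  if (!all(is.finite(c(x, y, w, h)))) stop("box must be finite", call. = FALSE)
  if (w <= 0 || h <= 0) stop("box width and height must be positive", call. = FALSE)
  c(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w), h = as.numeric(h))
}

as_box <- function(b) {
  if (is.data.frame(b)) b <- unlist(b[1, c("x", "y", "w", "h")])
  bbox(b[["x"]], b[["y"]], b[["w"]], b[["h"]])
}

#' @rdname bbox
#' @param box a bounding box.
#' @export
box_center <- function(box) {
  box <- as_box(box)
  c(cx = box[["x"]] + box[["w"]] / 2, cy = box[["y"]] + box[["h"]] / 2,
    w = box[["w"]], h = box[["h"]])
}

#' @rdname bbox
#' @param center named vector `c(cx, cy, w, h)`.
#' @export
center_to_corner <- function(center) {
  bbox(center[["cx"]] - center[["w"]] / 2, center[["cy"]] - center[["h"]] / 2,
       center[["w"]], center[["h"]])
}

#' Intersection over union of two boxes
#'
#' @param a,b bounding boxes (`c(x, y, w, h)`).
#' @return IoU in \[0,1\]; symmetric; 1 iff the boxes are identical.
#' @examples
#' box_iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- as_box(a)
  b <- as_box(b)
  ix <- min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]]) - max(a[["x"]], b[["x"]])
  iy <- min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]]) - max(a[["y"]], b[["y"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter)
}

# Pairwise IoU between the rows of two candidate data frames (vectorized).
iou_matrix <- function(boxes1, boxes2) {
  ix <- outer(boxes1$x + boxes1$w, boxes2$x + boxes2$w, pmin) -
    outer(boxes1$x, boxes2$x, pmax)
  iy <- outer(boxes1$y + boxes1$h, boxes2$y + boxes2$h, pmin) -
    outer(boxes1$y, boxes2$y, pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  union <- outer(boxes1$w * boxes1$h, boxes2$w * boxes2$h, "+") - inter
  inter / union
}

#' Merge overlapping candidates
#'
#' Iteratively merges the candidate pair with the highest IoU exceeding
#' `iou_threshold` until no pair exceeds it (fixpoint).  The merged box is
#' the smallest box containing both; the merged degree (and probability,
#' when present) is the maximum of the pair's.  Ties on IoU are broken
#' deterministically by (degree desc, x, y) of the pair's first member.
#' The result is idempotent and its pairwise IoUs are all `<=`
#' `iou_threshold`.
#'
#' @param candidates candidate data frame (columns `x`, `y`, `w`, `h`,
#'   `degree`, optional `probability`).
#' @param iou_threshold merge threshold in \[0,1\]; default 0.3.
#' @return merged candidate data frame, sorted by descending degree.
#' @export
merge_candidates <- function(candidates, iou_threshold = 0.3) {
  if (iou_threshold < 0 || iou_threshold > 1)
    stop("iou_threshold must be in [0, 1]", call. = FALSE)
  cand <- as.data.frame(candidates)
  if (nrow(cand) <= 1L) return(cand)
  has_prob <- "probability" %in% names(cand)
  repeat {
    n <- nrow(cand)
    iom <- iou_matrix(cand, cand)
    diag(iom) <- 0
    best <- -1
    bi <- bj <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        v <- iom[i, j]
        if (v <= iou_threshold) next
        better <- v > best
        if (!better && v == best) {
          # deterministic tie-break: higher degree, then smaller x, then y
          key_new <- c(-max(cand$degree[c(i, j)]), min(cand$x[c(i, j)]),
                       min(cand$y[c(i, j)]))
          key_old <- c(-max(cand$degree[c(bi, bj)]), min(cand$x[c(bi, bj)]),
                       min(cand$y[c(bi, bj)]))
          cmp <- key_new - key_old
          nz <- which(cmp != 0)
          better <- length(nz) > 0 && cmp[nz[1]] < 0
        }
        if (better) {
          best <- v
          bi <- i
          bj <- j
        }
      }
    }
    if (best <= iou_threshold) break
    a <- cand[bi, ]
    b <- cand[bj, ]
    x0 <- min(a$x, b$x)
    y0 <- min(a$y, b$y)
    merged <- data.frame(x = x0, y = y0,
                         w = max(a$x + a$w, b$x + b$w) - x0,
                         h = max(a$y + a$h, b$y + b$h) - y0,
                         degree = max(a$degree, b$degree))
    if (has_prob) merged$probability <- max(a$probability, b$probability)
    cand <- rbind(cand[-c(bi, bj), , drop = FALSE], merged)
  }
  cand <- cand[order(-cand$degree, cand$x, cand$y), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Crop a candidate patch and resize it for classification
#'
#' Crops `box` from the image (clipped to the image bounds) and resizes
#' the crop to `out_size` by bilinear interpolation.  A crop that already
#' has the target size is returned as an exact pixel copy.
#'
#' @param image numeric matrix.
#' @param box bounding box `c(x, y, w, h)` (0-based, half-open); must
#'   intersect the image.
#' @param out_size `c(width, height)` of the returned patch; default
#'   `c(200, 200)`.
#' @return numeric matrix `out_size[2]` x `out_size[1]`.
#' @export
crop_patch <- function(image, box, out_size = c(200, 200)) {
  assert_gray_image(image)
  box <- as_box(box)
  x0 <- max(0, floor(box[["x"]]))
  y0 <- max(0, floor(box[["y"]]))
  x1 <- min(ncol(image), ceiling(box[["x"]] + box[["w"]]))
  y1 <- min(nrow(image), ceiling(box[["y"]] + box[["h"]]))
  if (x1 <= x0 || y1 <= y0)
    stop("box lies fully outside the image", call. = FALSE)
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  resize_image(crop, out_size[1], out_size[2])
}

#' Read and write candidate boxes as CSV or JSON
#'
#' The on-disk schema is `image_id, x, y, w, h, degree, probability`
#' (missing scores become `NA`).  `format = "center"` reads/writes the
#' `x`/`y` columns as box centres instead of top-left corners; the stored
#' convention must be stated explicitly via this flag.
#'
#' @param boxes candidate data frame; an `image_id` column is added if
#'   absent.
#' @param path file path (`.csv` or `.json`).
#' @param format `"corner"` (default) or `"center"`.
#' @return the data frame (read) or `path` invisibly (write).
#' @export
write_boxes <- function(boxes, path, format = c("corner", "center")) {
  format <- match.arg(format)
  df <- as.data.frame(boxes)
  if (!"image_id" %in% names(df)) df$image_id <- NA_character_
  if (!"degree" %in% names(df)) df$degree <- NA_real_
  if (!"probability" %in% names(df)) df$probability <- NA_real_
  if (format == "center") {
    df$x <- df$x + df$w / 2
    df$y <- df$y + df$h / 2
  }
  df <- df[, c("image_id", "x", "y", "w", "h", "degree", "probability")]
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_boxes
#' @export
read_boxes <- function(path, format = c("corner", "center")) {
  format <- match.arg(format)
  df <- if (tolower(tools::file_ext(path)) == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  if (format == "center") {
    df$x <- df$x - df$w / 2
    df$y <- df$y - df$h / 2
  }
  df
}
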
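#' Grayscale image representation
#'
#' Throughout the package a grayscale image is a plain numeric matrix with
#' rows as image rows (y) and columns as image columns (x).  Intensities
#' are non-negative finite reals at native bit depth: 8-bit images use
#' 0..255, 16-bit 0..65535.  Pixel coordinates in bounding boxes are
#' 0-based with half-open extents `[x, x+w) x [y, y+h)`.
#'
#' @param pixels numeric matrix of intensities.
#' @return the validated matrix (invisibly unchanged).
#' @keywords internal
assert_gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("image intensities must be finite and non-negative", call. = FALSE)
  invisible(pixels)
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (plain `P2` or binary `P5`) images as a numeric
#' matrix at native bit depth (PNG/TIFF decoders return \[0,1\]; values are
#' rescaled to 0..255 or 0..65535 according to `bit_depth`).  Multi-channel
#' input is collapsed to grayscale by the unweighted channel average, with
#' a warning.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`,
#'   `.pgm`).
#' @param bit_depth intensity scale used to rescale decoded PNG/TIFF data;
#'   8 (default) or 16.  PGM files carry their own maxval.
#' @return numeric matrix (rows = image rows).
#' @export
read_gray_image <- function(path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  scale <- if (bit_depth == 16) 65535 else 255
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    warning("multi-channel image collapsed to grayscale by channel average")
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  }
  img <- arr * scale
  assert_gray_image(img)
  img
}

#' Write a grayscale image
#'
#' @param image numeric matrix.
#' @param path output path (`.png` or `.pgm`).
#' @param bit_depth 8 or 16; intensities are clipped to the valid range.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bit_depth = 8) {
  assert_gray_image(image)
  scale <- if (bit_depth == 16) 65535 else 255
  ext <- tolower(tools::file_ext(path))
  clipped <- pmin(pmax(image, 0), scale)
  if (ext == "png") {
    png::writePNG(clipped / scale, path)
  } else if (ext == "pgm") {
    write_pgm(clipped, path, maxval = scale)
  } else {
    stop("unsupported output format: ", ext, call. = FALSE)
  }
  invisible(path)
}

# PGM has no reader among the installed imaging packages, so the two
# netpbm variants used here (P2 ASCII, P5 binary, maxval <= 65535) are
# parsed directly.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PGM header", call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("^[ \t\r\n]$", ch)) {
        tok <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || grepl("^[ \t\r\n]$", ch)) break
          tok <- paste0(tok, ch)
        }
        return(tok)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", magic, call. = FALSE)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      raw2 <- readBin(con, "raw", 2L * n)
      hi <- as.integer(raw2[seq(1L, 2L * n, 2L)])
      lo <- as.integer(raw2[seq(2L, 2L * n, 2L)])
      vals <- hi * 256L + lo
    }
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path, maxval = 255) {
  vals <- as.integer(round(t(image)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), as.integer(maxval)),
            con, eos = NULL)
  if (maxval < 256) {
    writeBin(as.raw(vals), con)
  } else {
    inter <- integer(2L * length(vals))
    inter[seq(1L, length(inter), 2L)] <- vals %/% 256L
    inter[seq(2L, length(inter), 2L)] <- vals %% 256L
    writeBin(as.raw(inter), con)
  }
  invisible(path)
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Output pixel centres are mapped to input coordinates
#' (centre-aligned sampling), so resizing to the same size is an exact
#' copy and constant images stay constant.
#'
#' @param image numeric matrix.
#' @param width,height target size in pixels.
#' @return numeric matrix `height` x `width`.
#' @export
resize_image <- function(image, width, height) {
  assert_gray_image(image)
  if (width < 1 || height < 1) stop("target size must be positive", call. = FALSE)
  cpp_bilinear_resize(image, as.integer(height), as.integer(width))
}
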
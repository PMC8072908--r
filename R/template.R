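#' Synthesize the circular breast-mass template
#'
#' Builds the parametric template used for matching: a filled ellipse
#' inscribed in a `width` x `height` raster whose intensity ramps radially
#' from `center_value` at the centre down to `edge_value` on the ellipse
#' boundary; cells outside the ellipse take `edge_value`.  The value at
#' normalized radius `rho` (0 at the centre, 1 on the boundary) is
#' `round(center_value - (center_value - edge_value) * rho)`, clipped to
#' `[edge_value, center_value]`, so the profile is non-increasing along
#' every ray.  Defaults reproduce the 68x60 template with centre 117 and
#' edge 104.
#'
#' @param width,height template size in pixels (>= 3).
#' @param center_value,edge_value intensities at the centre and on the
#'   ellipse boundary; `center_value >= edge_value` required.
#' @return an object of class `mass_template`: list with `pixels`
#'   (height x width matrix), `width`, `height`, `center_value`,
#'   `edge_value`.
#' @examples
#' tpl <- mass_template()
#' range(tpl$pixels)  # 104 .. 117
#' @export
mass_template <- function(width = 68, height = 60, center_value = 117,
                          edge_value = 104) {
  if (width < 3 || height < 3)
    stop("template must be at least 3x3", call. = FALSE)
  if (center_value < edge_value)
    stop("center_value must be >= edge_value", call. = FALSE)
  width <- as.integer(width)
  height <- as.integer(height)
  a <- (width - 1) / 2
  b <- (height - 1) / 2
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  xs <- matrix(rep(seq_len(width) - cx, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - cy, times = width), nrow = height)
  rho <- sqrt((xs / a)^2 + (ys / b)^2)
  vals <- round(center_value - (center_value - edge_value) * rho)
  vals <- pmin(pmax(vals, edge_value), center_value)
  vals[rho > 1] <- edge_value
  structure(list(pixels = vals, width = width, height = height,
                 center_value = center_value, edge_value = edge_value),
            class = "mass_template")
}

#' @export
print.mass_template <- function(x, ...) {
  cat(sprintf("mass template %dx%d, centre %g, edge %g\n",
              x$width, x$height, x$center_value, x$edge_value))
  invisible(x)
}

as_template <- function(template) {
  if (inherits(template, "mass_template")) return(template)
  if (is.matrix(template) && is.numeric(template))
    return(structure(list(pixels = template, width = ncol(template),
                          height = nrow(template),
                          center_value = max(template),
                          edge_value = min(template)),
                     class = "mass_template"))
  stop("expected a mass_template or a numeric matrix", call. = FALSE)
}

#' Save / load a template as PGM plus a JSON parameter sidecar
#'
#' @param template a `mass_template`.
#' @param path output `.pgm` path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path` (save) or a `mass_template` (load).
#' @export
save_template <- function(template, path) {
  template <- as_template(template)
  write_pgm(template$pixels, path, maxval = max(255, ceiling(template$center_value)))
  jsonlite::write_json(template[c("width", "height", "center_value", "edge_value")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_template
#' @export
load_template <- function(path) {
  pixels <- read_pgm(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(pixels = pixels, width = meta$width, height = meta$height,
                 center_value = meta$center_value, edge_value = meta$edge_value),
            class = "mass_template")
}

new_score_map <- function(values, kind) {
  structure(list(values = values, kind = kind), class = "score_map")
}

#' Export a score map as a 32-bit TIFF (for inspection)
#'
#' Degree maps are written as-is (values already in \[0,1\]); distance
#' maps are scaled by their maximum so the relative structure survives.
#'
#' @param map a `score_map` (or plain numeric matrix with values that can
#'   be scaled into \[0,1\]).
#' @param path output `.tif` path.
#' @export
write_score_map <- function(map, path) {
  vals <- if (inherits(map, "score_map")) map$values else map
  mx <- max(vals)
  if (mx > 1) vals <- vals / mx
  tiff::writeTIFF(vals, path, bits.per.sample = 32L)
  invisible(path)
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("score map (%s), %d x %d offsets, range [%g, %g]\n", x$kind,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Squared-difference template matching
#'
#' `ssd_distance_map()` computes the raw matching distance
#' `D(i,j) = sum_{m,n} (P(m,n) - T(m,n))^2` for every template placement
#' fully inside the image (the sum of squared differences between the
#' template `T` and the patch `P` with top-left offset `(i,j)`; no square
#' root is taken).  `matching_degree_map()` converts it to a similarity in
#' \[0,1\]:
#' `degree = 1 - D / sqrt(sum(P^2) * sum(T^2))`, clipped to \[0,1\], which
#' is 1 exactly when the patch equals the template (both nonzero).  When
#' patch and template are both all-zero the degree is defined as 1; when
#' only one of them is all-zero it is 0.
#'
#' @param image numeric matrix, at least as large as the template.  In the
#'   full pipeline this is the morphologically preprocessed image.
#' @param template a `mass_template` (or plain numeric matrix).
#' @return a `score_map`: list with `values` (matrix of size
#'   `(nrow(image)-height+1) x (ncol(image)-width+1)`, where cell `[i, j]`
#'   (1-based) scores the patch with 0-based top-left offset
#'   `(i-1, j-1)`) and `kind` (`"distance"` or `"degree"`).
#' @export
ssd_distance_map <- function(image, template) {
  assert_gray_image(image)
  template <- as_template(template)
  if (nrow(image) < template$height || ncol(image) < template$width)
    stop("template larger than image", call. = FALSE)
  new_score_map(cpp_ssd_map(image, template$pixels), "distance")
}

#' @rdname ssd_distance_map
#' @export
matching_degree_map <- function(image, template) {
  assert_gray_image(image)
  template <- as_template(template)
  if (nrow(image) < template$height || ncol(image) < template$width)
    stop("template larger than image", call. = FALSE)
  d <- cpp_ssd_map(image, template$pixels)
  psq <- cpp_patch_sumsq_map(image, template$height, template$width)
  tsq <- sum(template$pixels^2)
  denom <- sqrt(psq * tsq)
  degree <- matrix(0, nrow(d), ncol(d))
  pos <- denom > 0
  degree[pos] <- 1 - d[pos] / denom[pos]
  # both patch and template all-zero: identical, degree 1
  degree[!pos & d == 0] <- 1
  degree <- pmin(pmax(degree, 0), 1)
  new_score_map(degree, "degree")
}

#' Extract candidate boxes from a matching-degree map
#'
#' Finds local maxima of the degree map (a cell is a peak if its value is
#' >= all of its 8-neighbours; plateaus of equal-valued connected peak
#' cells contribute their centroid cell) with degree >= `threshold`, and
#' returns one candidate per peak with the template's footprint anchored
#' at the matching offset, sorted by descending degree.
#'
#' @param degree_map a `score_map` of kind `"degree"` (or a plain matrix).
#' @param threshold matching-degree threshold in \[0,1\]; default 0.7.
#' @param template_size `c(width, height)` of the box to anchor at each
#'   peak.
#' @return candidate data frame with columns `x`, `y` (0-based top-left),
#'   `w`, `h`, `degree` (possibly zero rows).
#' @export
extract_candidates <- function(degree_map, threshold = 0.7,
                               template_size = c(68, 60)) {
  if (inherits(degree_map, "score_map")) degree_map <- degree_map$values
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  peaks <- find_peaks(degree_map, threshold)
  w <- as.integer(template_size[1])
  h <- as.integer(template_size[2])
  if (nrow(peaks) == 0L)
    return(data.frame(x = integer(), y = integer(), w = integer(),
                      h = integer(), degree = numeric()))
  out <- data.frame(x = peaks$col, y = peaks$row, w = w, h = h,
                    degree = peaks$value)
  out <- out[order(-out$degree, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Local maxima with plateau handling: candidate cells satisfy
# value >= 3x3-neighbourhood max and value >= threshold; 8-connected
# equal-valued groups of candidate cells are reduced to their (rounded)
# centroid.  Returns 0-based row/col offsets.
find_peaks <- function(values, threshold) {
  nr <- nrow(values)
  nc <- ncol(values)
  box3 <- structure(list(mask = matrix(TRUE, 3, 3), width = 3L, height = 3L,
                         anchor = c(row = 2L, col = 2L)),
                    class = "structuring_element")
  neigh_max <- cpp_minmax_filter(values, box3$mask, 1L, 1L, TRUE)
  cand <- which(values >= neigh_max & values >= threshold)
  if (length(cand) == 0L)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  in_cand <- logical(nr * nc)
  in_cand[cand] <- TRUE
  visited <- logical(nr * nc)
  rows <- integer(0)
  cols <- integer(0)
  vals <- numeric(0)
  for (start in cand) {
    if (visited[start]) next
    comp <- integer(0)
    queue <- start
    visited[start] <- TRUE
    v0 <- values[start]
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      comp <- c(comp, cur)
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (dc in -1:1) for (dr in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr
        cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (!visited[idx] && in_cand[idx] && values[idx] == v0) {
          visited[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
    }
    r <- ((comp - 1L) %% nr) + 1L
    c <- ((comp - 1L) %/% nr) + 1L
    rows <- c(rows, as.integer(round(mean(r))) - 1L)
    cols <- c(cols, as.integer(round(mean(c))) - 1L)
    vals <- c(vals, v0)
  }
  data.frame(row = rows, col = cols, value = vals)
}
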
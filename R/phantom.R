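#' Specification of a synthetic mammogram-like phantom
#'
#' A phantom emulates the gross appearance of a mammographic field that
#' the detection pipeline relies on: a dark background, smooth
#' low-frequency tissue texture, additive Gaussian noise, and bright,
#' approximately elliptical masses with blurred edges at known locations.
#' Masses are planted as filled ellipses of peak intensity
#' `background_level + mass_intensity`, softened by a Gaussian blur of
#' `edge_blur_sigma`; their ground-truth boxes are the tight axis-aligned
#' boxes of the *unblurred* ellipses.  Planted boxes are mutually disjoint
#' (IoU 0) and lie fully inside the image.
#'
#' @param width,height image size in pixels.
#' @param n_masses number of planted masses.
#' @param mass_axes range `c(min, max)` of ellipse semi-axes in pixels.
#' @param mass_intensity range of peak intensity above the background.
#' @param background_level base intensity (8-bit scale).
#' @param texture_amplitude standard deviation of the low-frequency
#'   background texture (0 disables it).
#' @param texture_scale correlation length of the texture in pixels
#'   (Gaussian smoothing sigma applied to white noise).
#' @param edge_blur_sigma mass edge softening in pixels.
#' @param noise_sigma additive Gaussian pixel noise.
#' @param seed integer seed; the phantom is fully determined by it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 400, height = 400, n_masses = 2,
                         mass_axes = c(24, 34), mass_intensity = c(45, 75),
                         background_level = 60, texture_amplitude = 8,
                         texture_scale = 40, edge_blur_sigma = 3,
                         noise_sigma = 3, seed = 1) {
  if (n_masses > 0 && max(mass_axes) * 2 >= min(width, height))
    stop("masses must fit inside the image", call. = FALSE)
  if (min(mass_intensity) <= 0)
    stop("mass peak intensity must exceed the background", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_masses = as.integer(n_masses), mass_axes = mass_axes,
                 mass_intensity = mass_intensity,
                 background_level = background_level,
                 texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale,
                 edge_blur_sigma = edge_blur_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom with known ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric matrix, clipped to 0..255) and
#'   `truth` (data frame of ground-truth boxes: `x`, `y`, `w`, `h` plus
#'   ellipse parameters `cx`, `cy`, `a`, `b`, `peak`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  w <- spec$width
  h <- spec$height
  img <- matrix(spec$background_level, h, w)

  if (spec$texture_amplitude > 0 && spec$texture_scale > 0) {
    # blur on a padded canvas so border replication cannot inflate the
    # local variance, then crop back and normalize to the target sd
    pad <- ceiling(3 * spec$texture_scale)
    tex <- cpp_gaussian_blur(matrix(rnorm((h + 2 * pad) * (w + 2 * pad)),
                                    h + 2 * pad, w + 2 * pad),
                             spec$texture_scale)
    tex <- tex[(pad + 1):(pad + h), (pad + 1):(pad + w)]
    tex <- tex - mean(tex)
    s <- stats::sd(tex)
    if (s > 0) tex <- tex * (spec$texture_amplitude / s)
    img <- img + tex
  }

  truth <- data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), cx = numeric(), cy = numeric(),
                      a = numeric(), b = numeric(), peak = numeric())
  if (spec$n_masses > 0) {
    layer <- matrix(0, h, w)
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), times = w), h, w)
    for (i in seq_len(spec$n_masses)) {
      placed <- FALSE
      for (try in 1:200) {
        a <- runif(1, spec$mass_axes[1], spec$mass_axes[2])
        b <- runif(1, spec$mass_axes[1], spec$mass_axes[2])
        cx <- runif(1, a + 2, w - a - 3)
        cy <- runif(1, b + 2, h - b - 3)
        box <- bbox(cx - a, cy - b, 2 * a, 2 * b)
        ok <- TRUE
        for (j in seq_len(nrow(truth)))
          if (box_iou(box, unlist(truth[j, c("x", "y", "w", "h")])) > 0) ok <- FALSE
        if (ok) {
          peak <- runif(1, spec$mass_intensity[1], spec$mass_intensity[2])
          inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
          layer[inside] <- pmax(layer[inside], peak)
          truth <- rbind(truth, data.frame(x = box[["x"]], y = box[["y"]],
                                           w = box[["w"]], h = box[["h"]],
                                           cx = cx, cy = cy, a = a, b = b,
                                           peak = peak))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place non-overlapping masses; reduce n_masses or axes",
             call. = FALSE)
    }
    if (spec$edge_blur_sigma > 0)
      layer <- cpp_gaussian_blur(layer, spec$edge_blur_sigma)
    img <- img + layer
  }

  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, truth = truth)
}

#' Generate a labelled mass/background patch dataset
#'
#' Mass patches are cropped around planted masses with random top-left
#' jitter of up to `jitter` of the box size; background patches are
#' sampled at mass-sized boxes whose IoU with every ground-truth box is
#' exactly 0.  All patches are resized to `out_size` and labelled.  As
#' many phantoms as needed are generated from seeds derived from
#' `spec$seed`, so the dataset is fully reproducible.
#'
#' @param spec a [phantom_spec()]; its `n_masses` must be >= 1.
#' @param n_mass,n_background patch counts per class (>= 1).
#' @param out_size patch size `c(width, height)`; default `c(200, 200)`.
#' @param jitter fractional crop jitter for mass patches; default 0.1.
#' @return a [patch_dataset()] with provenance (phantom seed and source
#'   box) per patch.
#' @export
generate_patch_dataset <- function(spec, n_mass, n_background,
                                   out_size = c(200, 200), jitter = 0.1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_mass < 1 || n_background < 1)
    stop("patch counts must be >= 1", call. = FALSE)
  if (spec$n_masses < 1)
    stop("spec must plant at least one mass", call. = FALSE)
  # each planted mass yields up to two jittered crops; backgrounds are
  # plentiful per phantom
  n_phantoms <- max(1, ceiling(max(n_mass / (2 * spec$n_masses),
                                   n_background / 8)))
  phantoms <- vector("list", n_phantoms)
  seeds <- (as.numeric(spec$seed) * 7919 + seq_len(n_phantoms)) %% 2147483647
  for (i in seq_len(n_phantoms)) {
    sp <- spec
    sp$seed <- as.integer(seeds[i])
    phantoms[[i]] <- generate_phantom(sp)
  }

  set.seed(spec$seed)
  patches <- list()
  labels <- character()
  prov <- data.frame(phantom_seed = integer(), x = numeric(), y = numeric(),
                     w = numeric(), h = numeric())
  add <- function(ph_i, box, label) {
    ph <- phantoms[[ph_i]]
    patches[[length(patches) + 1L]] <<- crop_patch(ph$image, box, out_size)
    labels[length(labels) + 1L] <<- label
    prov <<- rbind(prov, data.frame(phantom_seed = seeds[ph_i],
                                    x = box[["x"]], y = box[["y"]],
                                    w = box[["w"]], h = box[["h"]]))
  }

  # mass patches: cycle through planted masses with jittered crops
  k <- 0L
  while (k < n_mass) {
    ph_i <- (k %% n_phantoms) + 1L
    tr <- phantoms[[ph_i]]$truth
    row <- tr[(k %/% n_phantoms) %% nrow(tr) + 1L, ]
    dx <- runif(1, -jitter, jitter) * row$w
    dy <- runif(1, -jitter, jitter) * row$h
    box <- bbox(max(0, row$x + dx), max(0, row$y + dy), row$w, row$h)
    add(ph_i, box, "mass")
    k <- k + 1L
  }

  # background patches: mass-sized boxes disjoint from every truth box
  k <- 0L
  guard <- 0L
  while (k < n_background) {
    ph_i <- (k %% n_phantoms) + 1L
    ph <- phantoms[[ph_i]]
    side_w <- runif(1, 2 * spec$mass_axes[1], 2 * spec$mass_axes[2])
    side_h <- runif(1, 2 * spec$mass_axes[1], 2 * spec$mass_axes[2])
    x <- runif(1, 0, spec$width - side_w - 1)
    y <- runif(1, 0, spec$height - side_h - 1)
    box <- bbox(x, y, side_w, side_h)
    clash <- FALSE
    for (j in seq_len(nrow(ph$truth)))
      if (box_iou(box, unlist(ph$truth[j, c("x", "y", "w", "h")])) > 0) clash <- TRUE
    if (!clash) {
      add(ph_i, box, "background")
      k <- k + 1L
      guard <- 0L
    } else {
      guard <- guard + 1L
      if (guard > 1000L)
        stop("image too crowded to sample background patches", call. = FALSE)
    }
  }
  patch_dataset(patches, labels, provenance = prov)
}

#' Write a phantom to disk (PNG image plus ground-truth boxes)
#'
#' @param phantom result of [generate_phantom()].
#' @param image_path output PNG path.
#' @param truth_path output CSV (or JSON) path for the ground-truth boxes.
#' @export
write_phantom <- function(phantom, image_path, truth_path) {
  write_gray_image(phantom$image, image_path)
  tr <- phantom$truth
  tr$image_id <- basename(image_path)
  write_boxes(tr, truth_path)
  invisible(image_path)
}
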
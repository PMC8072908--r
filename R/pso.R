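#' Swarm configuration for bounding-box refinement
#'
#' @param n_particles swarm size; default 20.
#' @param max_iterations velocity/position update sweeps; default 20.
#' @param cp,cg cognitive (personal-best) and social (global-best)
#'   acceleration weights; default 0.5 each.
#' @param expansion search-region expansion as a fraction of the rough
#'   box's width/height on each side; default 0.30.
#' @param min_size minimum decoded box side in pixels.
#' @param vel_clamp velocity bound per coordinate, as a fraction of the
#'   search-region size (the update rule has no inertia damping, so
#'   velocities are clamped to keep the swarm from diverging).
#' @param init_vel initial random velocity scale for the randomly placed
#'   particles, as a fraction of the search-region size.
#' @param init_at_rough if `TRUE`, every particle starts at the rough box
#'   with zero velocity (the degenerate all-at-rough initialization; with
#'   it the swarm provably never moves).  Default `FALSE`: particle 1
#'   keeps the rough box, the rest are placed uniformly at random in the
#'   search region.
#' @param seed integer seed.
#' @return list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 20, max_iterations = 20, cp = 0.5,
                         cg = 0.5, expansion = 0.30, min_size = 8,
                         vel_clamp = 0.5, init_vel = 0.1,
                         init_at_rough = FALSE, seed = 1) {
  if (n_particles < 1) stop("need at least one particle", call. = FALSE)
  if (cp < 0 || cg < 0) stop("cp and cg must be >= 0", call. = FALSE)
  if (expansion < 0) stop("expansion must be >= 0", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles),
                 max_iterations = as.integer(max_iterations), cp = cp, cg = cg,
                 expansion = expansion, min_size = min_size,
                 vel_clamp = vel_clamp, init_vel = init_vel,
                 init_at_rough = isTRUE(init_at_rough), seed = as.integer(seed)),
            class = "swarm_config")
}

#' Search region around a rough box
#'
#' Expands the rough box by `expansion` of its width to the left and
#' right and `expansion` of its height up and down (default 30%:
#' `x' = x - 0.3w`, `y' = y - 0.3h`, `w' = 1.6w`, `h' = 1.6h`), clipped to
#' the image bounds when `image_size` is given.
#'
#' @param rough bounding box `c(x, y, w, h)`.
#' @param expansion per-side expansion fraction; default 0.30.
#' @param image_size optional `c(width, height)` to clip against.
#' @return bounding box of the search region.
#' @export
search_region <- function(rough, expansion = 0.30, image_size = NULL) {
  rough <- as_box(rough)
  x <- rough[["x"]] - expansion * rough[["w"]]
  y <- rough[["y"]] - expansion * rough[["h"]]
  w <- (1 + 2 * expansion) * rough[["w"]]
  h <- (1 + 2 * expansion) * rough[["h"]]
  if (!is.null(image_size)) {
    x1 <- min(x + w, image_size[1])
    y1 <- min(y + h, image_size[2])
    x <- max(x, 0)
    y <- max(y, 0)
    w <- x1 - x
    h <- y1 - y
  }
  bbox(x, y, w, h)
}

#' Particle encoding of a bounding box
#'
#' A particle position is the centre form `(cx, cy, w, h)`.
#' `encode_box()`/`decode_position()` round-trip losslessly for boxes
#' inside the search region; decoding clamps the width/height to
#' `[min_size, region size]` and shifts the centre so the decoded box lies
#' inside the region.
#'
#' @param box bounding box `c(x, y, w, h)`.
#' @return `encode_box()`: numeric `c(cx, cy, w, h)`.
#' @export
encode_box <- function(box) {
  unname(box_center(box))
}

#' @rdname encode_box
#' @param position numeric `c(cx, cy, w, h)`.
#' @param region search-region box to clamp into (optional).
#' @param min_size minimum box side in pixels.
#' @export
decode_position <- function(position, region = NULL, min_size = 8) {
  w <- position[3]
  h <- position[4]
  cx <- position[1]
  cy <- position[2]
  if (!is.null(region)) {
    region <- as_box(region)
    w <- min(max(w, min_size), region[["w"]])
    h <- min(max(h, min_size), region[["h"]])
    cx <- min(max(cx, region[["x"]] + w / 2), region[["x"]] + region[["w"]] - w / 2)
    cy <- min(max(cy, region[["y"]] + h / 2), region[["y"]] + region[["h"]] - h / 2)
  } else {
    w <- max(w, min_size)
    h <- max(h, min_size)
  }
  bbox(cx - w / 2, cy - h / 2, w, h)
}

#' Refine a bounding box by particle swarm optimization
#'
#' Searches the expanded region around `rough` for the box maximizing
#' `fitness` (in the full pipeline: the classifier's mass probability of
#' the cropped, resized patch).  Each sweep updates every particle's
#' velocity towards its personal best and the global best position with
#' independent uniform random weights per coordinate
#' (`V <- V + cp*U1*(pbest - X) + cg*U2*(gbest - X)`, then `X <- X + V`),
#' evaluates the decoded boxes, and updates the bests on strict
#' improvement — so the global best never decreases, and the rough box
#' (particle 1's start) is a guaranteed lower bound on the returned
#' fitness.
#'
#' @param image numeric matrix the boxes refer to.
#' @param rough rough bounding box `c(x, y, w, h)`; must intersect the
#'   image.
#' @param fitness function mapping a *list* of patches (cropped and
#'   resized to `patch_size`) to a numeric vector of scores in \[0,1\];
#'   see [bdcnn_fitness()].  A function of two arguments additionally
#'   receives the list of decoded boxes, for geometric objectives.
#' @param config a [swarm_config()].
#' @param patch_size patch size handed to [crop_patch()] before scoring.
#' @return list with `box` (refined bounding box), `fitness` (its score)
#'   and `trace` (data frame: `iteration`, `gbest_fitness`, `x`, `y`,
#'   `w`, `h`; iteration 0 is the initial swarm).
#' @export
pso_refine <- function(image, rough, fitness, config = swarm_config(),
                       patch_size = c(200, 200)) {
  assert_gray_image(image)
  rough <- as_box(rough)
  region <- search_region(rough, config$expansion,
                          image_size = c(ncol(image), nrow(image)))
  n <- config$n_particles
  rsize <- c(region[["w"]], region[["h"]], region[["w"]], region[["h"]])

  # a fitness taking two arguments is handed the decoded boxes as well,
  # for purely geometric objectives
  pass_boxes <- length(formals(fitness)) >= 2L
  evaluate <- function(positions) {
    boxes <- lapply(seq_len(nrow(positions)), function(i)
      decode_position(positions[i, ], region, config$min_size))
    patches <- lapply(boxes, function(b) crop_patch(image, b, patch_size))
    f <- if (pass_boxes) fitness(patches, boxes) else fitness(patches)
    if (length(f) != length(patches) || any(!is.finite(f)) ||
        any(f < 0) || any(f > 1))
      stop("fitness must return one value in [0, 1] per patch", call. = FALSE)
    list(fit = as.numeric(f), boxes = boxes)
  }

  set.seed(config$seed)
  positions <- matrix(0, n, 4)
  velocities <- matrix(0, n, 4)
  positions[1, ] <- encode_box(rough)
  if (n > 1L) {
    for (i in 2:n) {
      if (config$init_at_rough) {
        positions[i, ] <- encode_box(rough)
      } else {
        # local initialization: the swarm refines the rough box, so the
        # initial particles jitter around it (centre within +/-30% of the
        # box size, scale within roughly [0.7, 1.4]x) rather than spreading
        # uniformly over the search region, which would start the search
        # from arbitrarily tiny or huge boxes
        rc <- encode_box(rough)
        positions[i, ] <- c(rc[1] + runif(1, -0.3, 0.3) * rough[["w"]],
                            rc[2] + runif(1, -0.3, 0.3) * rough[["h"]],
                            rough[["w"]] * runif(1, 0.7, 1.4),
                            rough[["h"]] * runif(1, 0.7, 1.4))
        velocities[i, ] <- runif(4, -1, 1) * config$init_vel * rsize
      }
    }
  }

  ev <- evaluate(positions)
  pbest_pos <- positions
  pbest_fit <- ev$fit
  gbest_idx <- which.max(pbest_fit)
  gbest_pos <- positions[gbest_idx, ]
  gbest_fit <- pbest_fit[gbest_idx]
  gbest_box <- ev$boxes[[gbest_idx]]

  trace <- data.frame(iteration = 0L, gbest_fitness = gbest_fit,
                      x = gbest_box[["x"]], y = gbest_box[["y"]],
                      w = gbest_box[["w"]], h = gbest_box[["h"]])
  vmax <- config$vel_clamp * rsize

  for (it in seq_len(config$max_iterations)) {
    for (i in seq_len(n)) {
      v <- velocities[i, ] +
        config$cp * runif(4) * (pbest_pos[i, ] - positions[i, ]) +
        config$cg * runif(4) * (gbest_pos - positions[i, ])
      velocities[i, ] <- pmin(pmax(v, -vmax), vmax)
      positions[i, ] <- positions[i, ] + velocities[i, ]
    }
    ev <- evaluate(positions)
    improved <- ev$fit > pbest_fit
    pbest_fit[improved] <- ev$fit[improved]
    pbest_pos[improved, ] <- positions[improved, , drop = FALSE]
    for (i in seq_len(n)) {
      if (pbest_fit[i] > gbest_fit) {
        gbest_fit <- pbest_fit[i]
        gbest_pos <- pbest_pos[i, ]
        gbest_box <- decode_position(gbest_pos, region, config$min_size)
      }
    }
    trace <- rbind(trace, data.frame(iteration = it, gbest_fitness = gbest_fit,
                                     x = gbest_box[["x"]], y = gbest_box[["y"]],
                                     w = gbest_box[["w"]], h = gbest_box[["h"]]))
  }
  list(box = gbest_box, fitness = gbest_fit, trace = trace)
}
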
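# Independent brute-force oracles used to validate the fast implementations.

# Sliding min/max with edge replication, straight from the definition.
brute_minmax_filter <- function(img, se, take_max) {
  H <- nrow(img)
  W <- ncol(img)
  offs <- which(se$mask, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - se$anchor["row"]
  offs[, 2] <- offs[, 2] - se$anchor["col"]
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rr <- pmin(pmax(r + offs[, 1], 1), H)
      cc <- pmin(pmax(c + offs[, 2], 1), W)
      v <- img[cbind(rr, cc)]
      out[r, c] <- if (take_max) max(v) else min(v)
    }
  }
  out
}

# The squared-difference template score as a literal double loop over
# every offset.
brute_ssd_map <- function(img, tmpl) {
  th <- nrow(tmpl)
  tw <- ncol(tmpl)
  oh <- nrow(img) - th + 1
  ow <- ncol(img) - tw + 1
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      patch <- img[i:(i + th - 1), j:(j + tw - 1)]
      out[i, j] <- sum((patch - tmpl)^2)
    }
  }
  out
}

# IoU by counting cells on a fine raster (boxes with integer coordinates).
raster_iou <- function(a, b) {
  x0 <- min(a["x"], b["x"])
  y0 <- min(a["y"], b["y"])
  x1 <- max(a["x"] + a["w"], b["x"] + b["w"])
  y1 <- max(a["y"] + a["h"], b["y"] + b["h"])
  xs <- seq(x0 + 0.5, x1 - 0.5, by = 1)
  ys <- seq(y0 + 0.5, y1 - 0.5, by = 1)
  in_box <- function(box, px, py)
    px >= box["x"] & px < box["x"] + box["w"] &
    py >= box["y"] & py < box["y"] + box["h"]
  grid <- expand.grid(px = xs, py = ys)
  ia <- in_box(a, grid$px, grid$py)
  ib <- in_box(b, grid$px, grid$py)
  if (sum(ia | ib) == 0) return(0)
  sum(ia & ib) / sum(ia | ib)
}

# Separable planted-box fitness on (cx, cy, w, h) and its exact optimum
# over the integer search grid, maximized coordinate by coordinate.
planted_box_fitness <- function(target_center, scale) {
  function(patches, boxes) {
    sapply(boxes, function(b) {
      p <- encode_box(b)
      max(0, 1 - sum(abs(p - target_center)) / scale)
    })
  }
}

grid_fitness_optimum <- function(target_center, scale, region, min_size = 8) {
  region <- c(x = region[["x"]], y = region[["y"]],
              w = region[["w"]], h = region[["h"]])
  best_err <- function(target, lo, hi) {
    grid <- seq(ceiling(lo), floor(hi), by = 1)
    min(abs(grid - target))
  }
  # decoded boxes satisfy: w,h in [min_size, region size], centre inside
  err <- best_err(target_center[3], min_size, region["w"]) +
    best_err(target_center[4], min_size, region["h"]) +
    best_err(target_center[1], region["x"] + min_size / 2,
             region["x"] + region["w"] - min_size / 2) +
    best_err(target_center[2], region["y"] + min_size / 2,
             region["y"] + region["h"] - min_size / 2)
  max(0, 1 - err / scale)
}

# Exhaustive optimal one-to-one assignment of detections to truths,
# maximizing the number of IoU >= thr matches (instances of <= 4 boxes).
brute_best_matching <- function(det_boxes, truth_boxes, thr) {
  nd <- length(det_boxes)
  nt <- length(truth_boxes)
  if (nd == 0 || nt == 0) return(0L)
  best <- 0L
  assign_next <- function(d, used, count) {
    if (d > nd) {
      best <<- max(best, count)
      return()
    }
    assign_next(d + 1L, used, count)  # leave detection d unmatched
    for (t in seq_len(nt)) {
      if (used[t]) next
      if (box_iou(det_boxes[[d]], truth_boxes[[t]]) >= thr) {
        used[t] <- TRUE
        assign_next(d + 1L, used, count + 1L)
        used[t] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, nt), 0L)
  best
}

random_candidates <- function(n, field = 100, wmax = 40) {
  data.frame(x = runif(n, 0, field), y = runif(n, 0, field),
             w = runif(n, 5, wmax), h = runif(n, 5, wmax),
             degree = runif(n))
}
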
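#' Full-pipeline configuration
#'
#' Bundles every stage's tunables with the published defaults: resize to
#' 1500x2000, elliptical 7x7 erosion / 50x50 dilation, 68x60 template
#' (centre 117, edge 104), matching threshold 0.7, merge IoU 0.3,
#' classifier decision threshold 0.5, a +/-30% PSO search region, and an
#' IoU >= 0.5 true-positive criterion for evaluation.
#'
#' @param resize_to `c(width, height)` applied to the input image before
#'   detection, or `NULL` to detect at native size (ground-truth boxes
#'   must be on the same scale as the detected image).
#' @param erode_size,dilate_size elliptical structuring-element sizes
#'   `c(width, height)`.
#' @param template a [mass_template()].
#' @param matching_threshold matching-degree threshold for candidates.
#' @param degree_smooth_sigma Gaussian smoothing (pixels) applied to the
#'   matching-degree map before peak extraction.  The dilated mass
#'   plateau carries noise-scale ripple that otherwise splinters into
#'   several off-centre peaks per mass; smoothing at roughly the noise
#'   correlation scale consolidates each plateau into one centred peak.
#'   0 disables smoothing.
#' @param merge_iou IoU above which candidate boxes merge.
#' @param decision_threshold mass-probability cutoff for keeping a
#'   candidate.
#' @param tp_iou_threshold IoU at or above which a detection counts as a
#'   true positive in [evaluate_detections()].
#' @param swarm a [swarm_config()] for box refinement.
#' @param refine run PSO refinement on kept detections.
#' @param final_nms after refinement, suppress duplicate detections of the
#'   same region: among accepted detections whose final boxes overlap
#'   above `merge_iou`, only the one with the highest probability is
#'   emitted.  Refinement draws the duplicated candidates of one mass
#'   onto the same region, so without this step each extra candidate
#'   would surface as a false positive.
#' @param patch_size classifier patch size `c(width, height)`.
#' @param seed base seed for the per-candidate refinement swarms.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(resize_to = c(1500, 2000),
                            erode_size = c(7, 7), dilate_size = c(50, 50),
                            template = mass_template(),
                            matching_threshold = 0.7, degree_smooth_sigma = 8,
                            merge_iou = 0.3,
                            decision_threshold = 0.5, tp_iou_threshold = 0.5,
                            swarm = swarm_config(), refine = TRUE,
                            final_nms = TRUE, patch_size = c(200, 200),
                            seed = 1) {
  for (v in c(matching_threshold, merge_iou, decision_threshold, tp_iou_threshold))
    if (v < 0 || v > 1) stop("thresholds must be in [0, 1]", call. = FALSE)
  structure(list(resize_to = resize_to, erode_size = as.integer(erode_size),
                 dilate_size = as.integer(dilate_size), template = template,
                 matching_threshold = matching_threshold,
                 degree_smooth_sigma = degree_smooth_sigma,
                 merge_iou = merge_iou,
                 decision_threshold = decision_threshold,
                 tp_iou_threshold = tp_iou_threshold, swarm = swarm,
                 refine = isTRUE(refine), final_nms = isTRUE(final_nms),
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

empty_detections <- function() {
  data.frame(image_id = character(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric(), degree = numeric(),
             probability = numeric(), classified = logical(),
             kept = logical(),
             refined_x = numeric(), refined_y = numeric(),
             refined_w = numeric(), refined_h = numeric(),
             refined_probability = numeric())
}

#' Detect breast masses in a grayscale image
#'
#' Runs the full chain: optional resize, morphological highlighting,
#' template matching on the preprocessed image, candidate extraction and
#' IoU merging, patch cropping *from the original (resized) image*,
#' classification, and PSO refinement of every candidate whose mass
#' probability reaches the decision threshold.
#'
#' All scored candidates are returned (so that classification-level
#' metrics and probability/IoU diagnostics can be computed); rows with
#' `kept = TRUE` are the emitted detections, carrying refined boxes when
#' refinement ran.
#'
#' @param image numeric matrix.
#' @param model a trained [bdcnn_build()] model.
#' @param config a [pipeline_config()].
#' @param image_id identifier recorded on each detection row.
#' @return detection data frame (see [empty_detections()] for columns);
#'   box coordinates are on the scale of the (possibly resized) image.
#' @export
detect_masses <- function(image, model, config = pipeline_config(),
                          image_id = "image") {
  assert_gray_image(image)
  stopifnot(inherits(model, "bdcnn"))
  if (!is.null(config$resize_to))
    image <- resize_image(image, config$resize_to[1], config$resize_to[2])

  pre <- preprocess_morphology(
    image,
    erode_se = make_elliptical_se(config$erode_size[1], config$erode_size[2]),
    dilate_se = make_elliptical_se(config$dilate_size[1], config$dilate_size[2]))
  degree <- matching_degree_map(pre, config$template)$values
  if (config$degree_smooth_sigma > 0)
    degree <- cpp_gaussian_blur(degree, config$degree_smooth_sigma)
  cand <- extract_candidates(degree, config$matching_threshold,
                             c(config$template$width, config$template$height))
  cand <- merge_candidates(cand, config$merge_iou)
  if (nrow(cand) == 0L) return(empty_detections())

  patches <- lapply(seq_len(nrow(cand)), function(i)
    crop_patch(image, unlist(cand[i, c("x", "y", "w", "h")]), config$patch_size))
  prob <- predict_mass_probability(model, patches)

  det <- data.frame(image_id = image_id, x = cand$x, y = cand$y, w = cand$w,
                    h = cand$h, degree = cand$degree, probability = prob,
                    classified = prob >= config$decision_threshold,
                    kept = prob >= config$decision_threshold,
                    refined_x = NA_real_, refined_y = NA_real_,
                    refined_w = NA_real_, refined_h = NA_real_,
                    refined_probability = NA_real_)
  if (config$refine && any(det$kept)) {
    fit <- bdcnn_fitness(model)
    for (i in which(det$kept)) {
      sw <- config$swarm
      sw$seed <- as.integer((as.numeric(config$seed) * 131 + i) %% 2147483647)
      ref <- pso_refine(image, unlist(det[i, c("x", "y", "w", "h")]), fit,
                        config = sw, patch_size = config$patch_size)
      det$refined_x[i] <- ref$box[["x"]]
      det$refined_y[i] <- ref$box[["y"]]
      det$refined_w[i] <- ref$box[["w"]]
      det$refined_h[i] <- ref$box[["h"]]
      det$refined_probability[i] <- ref$fitness
    }
  }
  if (config$final_nms && sum(det$kept) > 1L) {
    idx <- which(det$kept)
    score <- ifelse(is.na(det$refined_probability[idx]),
                    det$probability[idx], det$refined_probability[idx])
    idx <- idx[order(-score, det$x[idx], det$y[idx])]
    accepted <- integer(0)
    for (i in idx) {
      bi <- final_box(det[i, ])
      dup <- FALSE
      for (j in accepted)
        if (box_iou(bi, final_box(det[j, ])) > config$merge_iou) dup <- TRUE
      if (dup) det$kept[i] <- FALSE else accepted <- c(accepted, i)
    }
  }
  det
}

final_box <- function(det_row) {
  rx <- det_row$refined_x
  if (!is.null(rx) && length(rx) == 1L && !is.na(rx))
    return(bbox(det_row$refined_x, det_row$refined_y,
                det_row$refined_w, det_row$refined_h))
  bbox(det_row$x, det_row$y, det_row$w, det_row$h)
}

#' Evaluate detections against ground truth
#'
#' Detection-level metrics use greedy one-to-one matching: emitted
#' detections (`kept = TRUE`; refined boxes when present) are visited in
#' order of descending probability and claim the unclaimed ground-truth
#' box of highest IoU, counting as true positives iff that IoU is at
#' least `tp_iou_threshold`.  TPR is matched truths over all truths; FPI
#' is unmatched detections per image; `mean_iou` averages the IoU of the
#' matched pairs.
#'
#' Classification-level accuracy/precision/recall/F1 are computed over
#' *all* scored candidates (kept or not): a candidate's reference label
#' is whether its rough box overlaps any ground-truth box at
#' `tp_iou_threshold`, its decision is its `kept` flag.
#'
#' @param detections detection rows from [detect_masses()] (any number of
#'   images, distinguished by `image_id`).
#' @param truths ground-truth data frame with `image_id`, `x`, `y`, `w`,
#'   `h` (one row per mass).
#' @param tp_iou_threshold IoU deciding a hit; default 0.5.
#' @param n_images number of evaluated images; defaults to the distinct
#'   `image_id`s in `truths`.
#' @return list of class `mass_metrics`: `TPR`, `FPI`, `accuracy`,
#'   `precision`, `recall`, `F1`, `mean_iou`, `counts`, and a `per_image`
#'   breakdown.
#' @export
evaluate_detections <- function(detections, truths, tp_iou_threshold = 0.5,
                                n_images = NULL) {
  detections <- as.data.frame(detections)
  truths <- as.data.frame(truths)
  if (!"image_id" %in% names(truths))
    stop("truths must carry an image_id column", call. = FALSE)
  if (nrow(detections) > 0 &&
      !all(detections$image_id %in% truths$image_id))
    stop("detections reference image ids absent from the ground truth",
         call. = FALSE)
  ids <- unique(truths$image_id)
  if (is.null(n_images)) n_images <- length(ids)
  if (!"kept" %in% names(detections) && nrow(detections) > 0)
    detections$kept <- TRUE

  tp <- 0L
  fp <- 0L
  total_truths <- nrow(truths)
  ious <- numeric(0)
  per_image <- data.frame(image_id = character(), truths = integer(),
                          detections = integer(), tp = integer(),
                          fp = integer())
  for (id in ids) {
    tr <- truths[truths$image_id == id, , drop = FALSE]
    de <- detections[detections$image_id == id & detections$kept, , drop = FALSE]
    claimed <- rep(FALSE, nrow(tr))
    itp <- 0L
    if (nrow(de) > 0) {
      de <- de[order(-de$probability), , drop = FALSE]
      for (i in seq_len(nrow(de))) {
        b <- final_box(de[i, ])
        best_iou <- -1
        best_j <- 0L
        for (j in seq_len(nrow(tr))) {
          if (claimed[j]) next
          v <- box_iou(b, unlist(tr[j, c("x", "y", "w", "h")]))
          if (v > best_iou) {
            best_iou <- v
            best_j <- j
          }
        }
        if (best_j > 0L && best_iou >= tp_iou_threshold) {
          claimed[best_j] <- TRUE
          itp <- itp + 1L
          ious <- c(ious, best_iou)
        }
      }
    }
    ifp <- nrow(de) - itp
    tp <- tp + itp
    fp <- fp + ifp
    per_image <- rbind(per_image,
                       data.frame(image_id = id, truths = nrow(tr),
                                  detections = nrow(de), tp = itp, fp = ifp))
  }

  # classification level, over every scored candidate; the decision is the
  # classifier's (pre-suppression) call when available
  if (!"classified" %in% names(detections) && nrow(detections) > 0)
    detections$classified <- detections$kept
  cls <- data.frame(pred = logical(), truth = logical())
  if (nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      tr <- truths[truths$image_id == detections$image_id[i], , drop = FALSE]
      rough <- bbox(detections$x[i], detections$y[i], detections$w[i],
                    detections$h[i])
      max_iou <- 0
      for (j in seq_len(nrow(tr)))
        max_iou <- max(max_iou, box_iou(rough, unlist(tr[j, c("x", "y", "w", "h")])))
      cls <- rbind(cls, data.frame(pred = detections$classified[i],
                                   truth = max_iou >= tp_iou_threshold))
    }
  }
  ctp <- sum(cls$pred & cls$truth)
  cfp <- sum(cls$pred & !cls$truth)
  cfn <- sum(!cls$pred & cls$truth)
  ctn <- sum(!cls$pred & !cls$truth)
  precision <- if (ctp + cfp > 0) ctp / (ctp + cfp) else NA_real_
  recall <- if (ctp + cfn > 0) ctp / (ctp + cfn) else 0
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  accuracy <- if (nrow(cls) > 0) (ctp + ctn) / nrow(cls) else NA_real_

  structure(list(
    TPR = if (total_truths > 0) tp / total_truths else NA_real_,
    FPI = if (n_images > 0) fp / n_images else NA_real_,
    accuracy = accuracy, precision = precision, recall = recall, F1 = f1,
    mean_iou = if (length(ious) > 0) mean(ious) else NA_real_,
    counts = c(tp = tp, fp = fp, truths = total_truths, images = n_images),
    per_image = per_image), class = "mass_metrics")
}

#' @export
print.mass_metrics <- function(x, ...) {
  cat(sprintf(
    "TPR %.3f | FPI %.3f | acc %.3f | prec %.3f | recall %.3f | F1 %.3f | mean IoU %.3f\n",
    x$TPR, x$FPI, x$accuracy, x$precision, x$recall, x$F1, x$mean_iou))
  invisible(x)
}
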
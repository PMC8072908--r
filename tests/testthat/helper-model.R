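# Heavyweight shared fixtures: the classifier trained on the synthetic
# patch dataset and the end-to-end detection results.  Built once per test
# session and reused across tests.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Desk-scale training recipe: the published architecture with a learning
# rate, batch size and batch-norm momentum suited to a few hundred
# patches (the published 1e-4/200-epoch recipe targets a much larger
# clinical corpus).
sanity_train_config <- function() {
  bdcnn_config(learning_rate = 3e-3, max_epochs = 50, batch_size = 16,
               bn_momentum = 0.3, seed = 0)
}

sanity_train_data <- function() {
  memo("train_data", function() {
    generate_patch_dataset(phantom_spec(seed = 0), 200, 200)
  })
}

sanity_heldout_data <- function() {
  memo("heldout_data", function() {
    generate_patch_dataset(phantom_spec(seed = 1000), 50, 50)
  })
}

sanity_model <- function() {
  memo("model", function() {
    bdcnn_train(bdcnn_build(sanity_train_config()), sanity_train_data())
  })
}

e2e_pipeline_config <- function() {
  pipeline_config(
    resize_to = NULL,  # phantoms are detected at native size
    swarm = swarm_config(n_particles = 8, max_iterations = 6, seed = 1),
    seed = 1)
}

# Full pipeline over 20 phantoms (2 masses each); returns every scored
# candidate with per-candidate best-truth IoUs for the rough and refined
# boxes, plus the ground-truth table.
e2e_results <- function() {
  memo("e2e", function() {
    model <- sanity_model()
    cfg <- e2e_pipeline_config()
    dets <- list()
    truths <- list()
    for (seed in 101:120) {
      id <- sprintf("phantom%03d", seed)
      ph <- generate_phantom(phantom_spec(seed = seed))
      d <- detect_masses(ph$image, model, cfg, image_id = id)
      tr <- ph$truth[, c("x", "y", "w", "h")]
      tr$image_id <- id
      if (nrow(d) > 0) {
        d$rough_iou <- NA_real_
        d$refined_iou <- NA_real_
        for (i in seq_len(nrow(d))) {
          ious_r <- ious_f <- numeric(nrow(tr))
          for (j in seq_len(nrow(tr))) {
            tb <- bbox(tr$x[j], tr$y[j], tr$w[j], tr$h[j])
            ious_r[j] <- box_iou(bbox(d$x[i], d$y[i], d$w[i], d$h[i]), tb)
            ious_f[j] <- if (is.na(d$refined_x[i])) ious_r[j] else
              box_iou(bbox(d$refined_x[i], d$refined_y[i],
                           d$refined_w[i], d$refined_h[i]), tb)
          }
          d$rough_iou[i] <- max(ious_r)
          d$refined_iou[i] <- max(ious_f)
        }
      }
      dets[[id]] <- d
      truths[[id]] <- tr
    }
    list(detections = do.call(rbind, dets), truths = do.call(rbind, truths))
  })
}
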
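test_that("IoU matches hand counts and the raster oracle", {
  a <- bbox(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bbox(20, 20, 5, 5)), 0)
  expect_equal(box_iou(a, bbox(5, 0, 10, 10)), 1 / 3)
  expect_equal(box_iou(bbox(5, 0, 10, 10), a), 1 / 3)  # symmetry

  set.seed(3)
  for (i in 1:25) {
    b1 <- bbox(sample(0:20, 1), sample(0:20, 1), sample(3:15, 1), sample(3:15, 1))
    b2 <- bbox(sample(0:20, 1), sample(0:20, 1), sample(3:15, 1), sample(3:15, 1))
    expect_equal(box_iou(b1, b2), raster_iou(b1, b2), tolerance = 1e-12)
    expect_equal(box_iou(b1, b2), box_iou(b2, b1))
  }
})

test_that("corner/centre conversions round-trip", {
  b <- bbox(10, 20, 30, 40)
  expect_equal(box_center(b), c(cx = 25, cy = 40, w = 30, h = 40))
  expect_equal(center_to_corner(box_center(b)), b)
})

test_that("merging respects the IoU threshold and preserves coverage", {
  two <- data.frame(x = c(0, 50), y = c(0, 50), w = c(10, 10), h = c(10, 10),
                    degree = c(0.9, 0.8))
  expect_equal(merge_candidates(two, 0.3), two[order(-two$degree), ])

  same <- data.frame(x = c(5, 5), y = c(5, 5), w = c(10, 10), h = c(10, 10),
                     degree = c(0.7, 0.9))
  m <- merge_candidates(same, 0.3)
  expect_equal(nrow(m), 1)
  expect_equal(m$degree, 0.9)
  expect_equal(unlist(m[1, c("x", "y", "w", "h")]),
               c(x = 5, y = 5, w = 10, h = 10))

  # chain of five heavily overlapping boxes collapses to the union box
  chain <- data.frame(x = c(0, 4, 8, 12, 16), y = 0, w = 20, h = 20,
                      degree = seq(0.9, 0.5, by = -0.1))
  mc <- merge_candidates(chain, 0.3)
  expect_equal(nrow(mc), 1)
  expect_equal(unlist(mc[1, c("x", "y", "w", "h")]),
               c(x = 0, y = 0, w = 36, h = 20))
  expect_equal(mc$degree, 0.9)
})

test_that("merge reaches a fixpoint, is idempotent, and keeps coverage", {
  set.seed(9)
  for (i in 1:40) {
    cand <- random_candidates(sample(2:8, 1))
    merged <- merge_candidates(cand, 0.3)
    if (nrow(merged) > 1) {
      iom <- mammocad:::iou_matrix(merged, merged)
      diag(iom) <- 0
      expect_true(all(iom <= 0.3))
    }
    expect_equal(merge_candidates(merged, 0.3), merged)
    # coverage: every input box lies inside some output box's union region
    for (j in seq_len(nrow(cand))) {
      contained <- FALSE
      for (k in seq_len(nrow(merged)))
        if (merged$x[k] <= cand$x[j] + 1e-9 && merged$y[k] <= cand$y[j] + 1e-9 &&
            merged$x[k] + merged$w[k] >= cand$x[j] + cand$w[j] - 1e-9 &&
            merged$y[k] + merged$h[k] >= cand$y[j] + cand$h[j] - 1e-9)
          contained <- TRUE
      expect_true(contained)
    }
  }
})

test_that("crop_patch crops, clips and resizes as specified", {
  set.seed(10)
  img <- matrix(runif(300 * 300, 0, 255), 300, 300)

  # box of exactly the output size: exact pixel copy
  got <- crop_patch(img, bbox(40, 60, 200, 200), c(200, 200))
  expect_equal(got, img[61:260, 41:240])

  # whole image resized
  whole <- crop_patch(img, bbox(0, 0, 300, 300), c(200, 200))
  expect_equal(dim(whole), c(200L, 200L))

  # constant region stays constant under interpolation
  img2 <- matrix(37, 150, 150)
  expect_equal(crop_patch(img2, bbox(10, 10, 100, 100), c(200, 200)),
               matrix(37, 200, 200))

  # clipped at the border, still valid
  clipped <- crop_patch(img, bbox(-50, -50, 100, 100), c(64, 64))
  expect_equal(dim(clipped), c(64L, 64L))

  expect_error(crop_patch(img, bbox(400, 400, 10, 10)), "outside")
})

test_that("boxes round-trip through CSV and JSON in both conventions", {
  df <- data.frame(image_id = c("a", "a", "b"), x = c(1, 5.5, 10),
                   y = c(2, 6, 11), w = c(10, 20, 5), h = c(12, 22, 6),
                   degree = c(0.9, 0.8, 0.7), probability = c(0.95, NA, 0.2))
  for (ext in c("csv", "json")) {
    p <- file.path(tempdir(), paste0("boxes.", ext))
    write_boxes(df, p)
    back <- read_boxes(p)
    expect_equal(back$x, df$x)
    expect_equal(back$probability, df$probability)

    write_boxes(df, p, format = "center")
    back2 <- read_boxes(p, format = "center")
    expect_equal(back2$x, df$x)
    expect_equal(back2$y, df$y)
  }
})
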
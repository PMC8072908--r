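test_that("phantom generation is seeded-deterministic with valid ground truth", {
  spec <- phantom_spec(seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)

  other <- generate_phantom(phantom_spec(seed = 6))
  expect_false(identical(a$image, other$image))

  expect_equal(nrow(a$truth), 2)
  # masses fully inside the image and mutually disjoint
  for (i in seq_len(nrow(a$truth))) {
    expect_gte(a$truth$x[i], 0)
    expect_gte(a$truth$y[i], 0)
    expect_lte(a$truth$x[i] + a$truth$w[i], spec$width)
    expect_lte(a$truth$y[i] + a$truth$h[i], spec$height)
  }
  expect_equal(box_iou(unlist(a$truth[1, c("x", "y", "w", "h")]),
                       unlist(a$truth[2, c("x", "y", "w", "h")])), 0)
})

test_that("degenerate phantoms reduce to the constant background", {
  spec <- phantom_spec(n_masses = 0, noise_sigma = 0, texture_amplitude = 0,
                       width = 80, height = 60, seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(ph$image, matrix(60, 60, 80))
})

test_that("the brightest pixel of a noise-free phantom lies in a mass box", {
  spec <- phantom_spec(n_masses = 1, noise_sigma = 0, seed = 9)
  ph <- generate_phantom(spec)
  peak <- which(ph$image == max(ph$image), arr.ind = TRUE)[1, ]
  tr <- ph$truth[1, ]
  expect_gte(peak["col"] - 1, tr$x)
  expect_lte(peak["col"] - 1, tr$x + tr$w)
  expect_gte(peak["row"] - 1, tr$y)
  expect_lte(peak["row"] - 1, tr$y + tr$h)
})

test_that("patch datasets are balanced, leak-free and brighter in masses", {
  spec <- phantom_spec(seed = 0)
  ds <- generate_patch_dataset(spec, 12, 12)
  expect_s3_class(ds, "patch_dataset")
  expect_length(ds$patches, 24)
  expect_equal(sum(ds$labels == 1), 12)
  expect_equal(sum(ds$labels == 0), 12)
  expect_true(all(sapply(ds$patches, function(p) all(dim(p) == c(200, 200)))))

  # background patches have IoU 0 with every ground-truth box by
  # construction; verify through the recorded provenance
  prov <- ds$provenance[ds$labels == 0, ]
  for (i in seq_len(nrow(prov))) {
    sp <- spec
    sp$seed <- as.integer(prov$phantom_seed[i])
    tr <- generate_phantom(sp)$truth
    for (j in seq_len(nrow(tr)))
      expect_equal(box_iou(unlist(prov[i, c("x", "y", "w", "h")]),
                           unlist(tr[j, c("x", "y", "w", "h")])), 0)
  }

  m_mass <- mean(sapply(ds$patches[ds$labels == 1], mean))
  m_bg <- mean(sapply(ds$patches[ds$labels == 0], mean))
  expect_gt(m_mass, m_bg)

  # determinism
  ds2 <- generate_patch_dataset(spec, 12, 12)
  expect_identical(ds$patches, ds2$patches)
  expect_identical(ds$labels, ds2$labels)
})

test_that("morphology plus matching recovers planted masses", {
  # recoverability across seeds: candidates at degree >= 0.5 hit at least
  # 90% of planted masses at IoU >= 0.25
  tpl <- mass_template()
  hits <- 0L
  total <- 0L
  for (seed in 1:10) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    pre <- preprocess_morphology(ph$image)
    cand <- extract_candidates(matching_degree_map(pre, tpl), 0.5,
                               c(tpl$width, tpl$height))
    cand <- merge_candidates(cand, 0.3)
    for (j in seq_len(nrow(ph$truth))) {
      total <- total + 1L
      tr <- unlist(ph$truth[j, c("x", "y", "w", "h")])
      best <- 0
      for (k in seq_len(nrow(cand)))
        best <- max(best, box_iou(unlist(cand[k, c("x", "y", "w", "h")]), tr))
      if (best >= 0.25) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("phantoms round-trip to PNG plus ground-truth CSV", {
  ph <- generate_phantom(phantom_spec(seed = 2, width = 260, height = 220))
  ip <- file.path(tempdir(), "phantom.png")
  tp <- file.path(tempdir(), "phantom.csv")
  write_phantom(ph, ip, tp)
  img <- read_gray_image(ip)
  expect_equal(dim(img), c(220L, 260L))
  expect_equal(img, round(ph$image), tolerance = 0.51)
  tr <- read_boxes(tp)
  expect_equal(nrow(tr), nrow(ph$truth))
  expect_equal(tr$x, ph$truth$x, tolerance = 1e-6)
})
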
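test_that("the default template reproduces the published intensity ramp", {
  tpl <- mass_template()
  expect_equal(dim(tpl$pixels), c(60L, 68L))
  expect_equal(max(tpl$pixels), 117)
  expect_equal(min(tpl$pixels), 104)
  expect_equal(tpl$pixels[30, 34], 117)  # centre region at the peak
})

test_that("template generation follows the radial formula", {
  # zero ramp degenerates to a constant
  flat <- mass_template(11, 11, 100, 100)
  expect_equal(flat$pixels, matrix(100, 11, 11))

  # 11x11: evaluate the formula on every cell independently
  tpl <- mass_template(11, 11, 117, 104)
  a <- b <- 5
  for (r in 1:11) {
    for (c in 1:11) {
      rho <- sqrt(((c - 6) / a)^2 + ((r - 6) / b)^2)
      v <- if (rho > 1) 104 else min(max(round(117 - 13 * rho), 104), 117)
      expect_equal(tpl$pixels[r, c], v)
    }
  }
  expect_equal(tpl$pixels[6, 6], 117)
  expect_equal(tpl$pixels[6, 1], 104)  # on the inscribed ellipse boundary

  expect_error(mass_template(11, 11, 100, 110), "center_value")
  expect_error(mass_template(2, 11), "at least")
})

test_that("template is radially non-increasing along sampled rays", {
  tpl <- mass_template()
  cx <- (tpl$width + 1) / 2
  cy <- (tpl$height + 1) / 2
  for (ang in seq(0, 2 * pi, length.out = 90)) {
    rr <- seq(0, max(tpl$width, tpl$height) / 2, by = 0.5)
    cols <- pmin(pmax(round(cx + rr * cos(ang)), 1), tpl$width)
    rows <- pmin(pmax(round(cy + rr * sin(ang)), 1), tpl$height)
    vals <- tpl$pixels[cbind(rows, cols)]
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("ssd distance matches direct evaluation and the brute-force oracle", {
  tpl <- mass_template()
  m <- ssd_distance_map(tpl$pixels, tpl)
  expect_equal(dim(m$values), c(1L, 1L))
  expect_equal(m$values[1, 1], 0)

  m1 <- ssd_distance_map(tpl$pixels + 1, tpl)
  expect_equal(m1$values[1, 1], 68 * 60)

  set.seed(5)
  small <- structure(list(pixels = matrix(sample(0:255, 25, TRUE), 5, 5),
                          width = 5L, height = 5L, center_value = 255,
                          edge_value = 0), class = "mass_template")
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  got <- ssd_distance_map(img, small)
  expect_equal(dim(got$values), c(16L, 16L))
  expect_identical(got$values, brute_ssd_map(img, small$pixels))

  expect_error(ssd_distance_map(matrix(0, 10, 10), tpl), "larger")
})

test_that("matching degree is a normalized similarity in [0, 1]", {
  tpl <- mass_template()
  expect_equal(matching_degree_map(tpl$pixels, tpl)$values[1, 1], 1)
  # scalar-multiple patch: 1 - k*S / sqrt(k^2*S*S) has closed form 0.5 at k=2
  expect_equal(matching_degree_map(2 * tpl$pixels, tpl)$values[1, 1], 0.5)

  set.seed(6)
  img <- matrix(runif(80 * 80, 0, 255), 80, 80)
  dm <- matching_degree_map(img, tpl)$values
  expect_true(all(dm >= 0 & dm <= 1))

  # all-zero conventions
  z5 <- structure(list(pixels = matrix(0, 5, 5), width = 5L, height = 5L,
                       center_value = 0, edge_value = 0),
                  class = "mass_template")
  expect_equal(matching_degree_map(matrix(0, 5, 5), z5)$values[1, 1], 1)
  expect_equal(matching_degree_map(matrix(10, 5, 5), z5)$values[1, 1], 0)
})

test_that("embedding the template makes its location the degree argmax", {
  tpl <- mass_template(21, 17, 117, 104)
  img <- matrix(104, 80, 90)
  img[31:47, 41:61] <- tpl$pixels  # top-left offset (40, 30) 0-based
  dm <- matching_degree_map(img, tpl)$values
  peak <- which(dm == max(dm), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(31, 41))
  expect_equal(max(dm), 1)
})

test_that("candidate extraction thresholds local maxima and sorts by degree", {
  flat <- matrix(0.2, 30, 30)
  expect_equal(nrow(extract_candidates(flat, 0.7, c(68, 60))), 0)

  m <- matrix(0, 40, 50)
  m[11, 21] <- 0.9
  got <- extract_candidates(m, 0.7, c(68, 60))
  expect_equal(nrow(got), 1)
  expect_equal(got$x, 20)  # 0-based offsets
  expect_equal(got$y, 10)
  expect_equal(got$w, 68)
  expect_equal(got$h, 60)
  expect_equal(got$degree, 0.9)

  m3 <- matrix(0, 40, 40)
  m3[5, 5] <- 0.95
  m3[20, 20] <- 0.75
  m3[35, 35] <- 0.65
  got3 <- extract_candidates(m3, 0.7, c(10, 10))
  expect_equal(got3$degree, c(0.95, 0.75))

  # plateau contributes a single centroid candidate
  mp <- matrix(0, 30, 30)
  mp[10:14, 10:14] <- 0.8
  gp <- extract_candidates(mp, 0.7, c(10, 10))
  expect_equal(nrow(gp), 1)
  expect_equal(gp$x, 11)
  expect_equal(gp$y, 11)

  # candidate count is non-increasing in the threshold
  set.seed(8)
  rnd <- matrix(runif(900), 30, 30)
  counts <- sapply(c(0.2, 0.5, 0.7, 0.9),
                   function(t) nrow(extract_candidates(rnd, t, c(5, 5))))
  expect_true(all(diff(counts) <= 0))
})

test_that("templates round-trip through PGM plus JSON sidecar", {
  tpl <- mass_template()
  path <- file.path(tempdir(), "tpl.pgm")
  save_template(tpl, path)
  back <- load_template(path)
  expect_equal(back$pixels, tpl$pixels)
  expect_equal(back$width, tpl$width)
  expect_equal(back$center_value, tpl$center_value)
})
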
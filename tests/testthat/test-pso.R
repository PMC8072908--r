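test_that("search region expands by the configured fraction and clips", {
  expect_equal(search_region(bbox(100, 100, 100, 100), 0.3),
               bbox(70, 70, 160, 160))
  b <- bbox(10, 20, 30, 40)
  expect_equal(search_region(b, 0), b)
  corner <- search_region(bbox(0, 0, 100, 100), 0.3, image_size = c(200, 200))
  expect_equal(corner, bbox(0, 0, 130, 130))
})

test_that("encode/decode round-trips and clamps degenerate positions", {
  expect_equal(encode_box(bbox(10, 20, 30, 40)), c(25, 40, 30, 40))

  set.seed(21)
  region <- bbox(0, 0, 500, 500)
  for (i in 1:100) {
    b <- bbox(runif(1, 10, 300), runif(1, 10, 300), runif(1, 9, 100),
              runif(1, 9, 100))
    expect_equal(decode_position(encode_box(b), region, 8), b)
  }

  # negative width decodes at the minimum box size
  d <- decode_position(c(100, 100, -5, 50), region, 8)
  expect_equal(d[["w"]], 8)
  # decoded boxes stay inside the region
  d2 <- decode_position(c(1000, -50, 80, 80), region, 8)
  expect_gte(d2[["x"]], 0)
  expect_lte(d2[["x"]] + d2[["w"]], 500)
  expect_gte(d2[["y"]], 0)
})

test_that("degenerate swarms do not move and constant fitness is preserved", {
  img <- matrix(50, 300, 300)
  rough <- bbox(100, 100, 80, 80)

  # all particles at the rough box, zero velocity, constant fitness:
  # the swarm provably never moves
  const_fit <- function(patches) rep(0.4, length(patches))
  cfg <- swarm_config(n_particles = 5, max_iterations = 5, init_at_rough = TRUE,
                      seed = 1)
  out <- pso_refine(img, rough, const_fit, cfg, patch_size = c(32, 32))
  expect_equal(out$fitness, 0.4)
  expect_equal(out$box, rough)
  expect_true(all(out$trace$gbest_fitness == 0.4))

  # cp = cg = 0 with zero initial velocities: output is the best initial
  # particle position
  target <- c(150, 140, 60, 70)
  fit <- planted_box_fitness(target, 640)
  cfg0 <- swarm_config(n_particles = 8, max_iterations = 6, cp = 0, cg = 0,
                       init_vel = 0, seed = 3)
  out0 <- pso_refine(img, rough, fit, cfg0, patch_size = c(32, 32))
  # recompute the initial positions under the same seed (particle 1 at the
  # rough box; the rest jittered locally around it)
  region <- search_region(rough, 0.3, c(300, 300))
  set.seed(3)
  init_fits <- numeric(8)
  init_fits[1] <- fit(list(), list(decode_position(encode_box(rough), region, 8)))
  rc <- encode_box(rough)
  for (i in 2:8) {
    pos <- c(rc[1] + runif(1, -0.3, 0.3) * rough[["w"]],
             rc[2] + runif(1, -0.3, 0.3) * rough[["h"]],
             rough[["w"]] * runif(1, 0.7, 1.4),
             rough[["h"]] * runif(1, 0.7, 1.4))
    runif(4)  # the (zero-scaled) initial velocity draws
    init_fits[i] <- fit(list(), list(decode_position(pos, region, 8)))
  }
  expect_equal(out0$fitness, max(init_fits))
})

test_that("refinement is seeded-deterministic with a non-decreasing trace", {
  img <- matrix(50, 300, 300)
  rough <- bbox(90, 110, 90, 70)
  fit <- planted_box_fitness(c(160, 140, 70, 60), 640)
  cfg <- swarm_config(n_particles = 10, max_iterations = 10, seed = 11)
  a <- pso_refine(img, rough, fit, cfg, patch_size = c(32, 32))
  b <- pso_refine(img, rough, fit, cfg, patch_size = c(32, 32))
  expect_identical(a$trace, b$trace)
  expect_identical(a$box, b$box)
  expect_true(all(diff(a$trace$gbest_fitness) >= 0))
  # the rough box is a lower bound on the returned fitness
  expect_gte(a$fitness, fit(list(), list(rough))[1])
})

test_that("fitness outside [0, 1] is rejected as a contract violation", {
  img <- matrix(50, 200, 200)
  bad <- function(patches) rep(1.5, length(patches))
  expect_error(pso_refine(img, bbox(50, 50, 60, 60), bad,
                          swarm_config(n_particles = 3, max_iterations = 1),
                          patch_size = c(16, 16)),
               "fitness")
})
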
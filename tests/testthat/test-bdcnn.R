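# Unit tests run on a scaled-down architecture (small input, few kernels)
# so that the full conv/BN/pool/FC machinery is exercised in seconds; the
# default-size network is covered by the acceptance suite.
tiny_config <- function(max_epochs = 30) {
  bdcnn_config(input_size = c(24, 24), n_kernels = c(8, 8),
               kernel_sizes = c(3, 3), fc_nodes = 16, batch_size = 8,
               learning_rate = 0.01, max_epochs = max_epochs, seed = 7)
}

tiny_patches <- function(n_per_class, seed = 1) {
  set.seed(seed)
  mk <- function(bright) {
    p <- matrix(runif(576, 0, 40), 24, 24)
    if (bright) p[8:16, 8:16] <- p[8:16, 8:16] + 150
    p
  }
  patch_dataset(c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
                  lapply(seq_len(n_per_class), function(i) mk(FALSE))),
                rep(c("mass", "background"), each = n_per_class))
}

test_that("the network outputs valid softmax probabilities deterministically", {
  cfg <- tiny_config()
  m1 <- bdcnn_build(cfg)
  m2 <- bdcnn_build(cfg)
  set.seed(99)
  patch <- matrix(runif(576, 0, 255), 24, 24)
  p1 <- bdcnn_predict(m1, patch)
  p2 <- bdcnn_predict(m2, patch)
  expect_equal(rowSums(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)  # same seed, same input, same output
  expect_identical(predict_mass_probability(m1, patch),
                   predict_mass_probability(m1, patch))
})

test_that("parameter counts match layer-by-layer arithmetic", {
  cfg <- tiny_config()
  m <- bdcnn_build(cfg)
  # conv blocks: Cin*k^2*Cout + Cout biases + 2*Cout batch-norm params
  expected <- (1 * 9 * 8 + 8 + 16) + (8 * 9 * 8 + 8 + 16)
  # after two poolings 24 -> 12 -> 6: flatten 6*6*8
  flat <- 6 * 6 * 8
  expected <- expected + (flat * 16 + 16) + (16 * 2 + 2)
  expect_equal(bdcnn_n_parameters(m), expected)

  # the published geometry: three blocks of 128 kernels (5x5, 3x3, 3x3)
  # on 200x200 input leaves 25x25x128 before the 1024-node FC layer
  dflt <- bdcnn_config()
  expect_equal(mammocad:::bdcnn_flat_dim(dflt), 25 * 25 * 128)
  expected_default <-
    (1 * 25 * 128 + 128 + 256) + (128 * 9 * 128 + 128 + 256) +
    (128 * 9 * 128 + 128 + 256) +
    (25 * 25 * 128 * 1024 + 1024) + (1024 * 2 + 2)
  expect_equal(bdcnn_n_parameters(bdcnn_build(dflt)), expected_default)
})

test_that("training learns a separable task and the stop rule fires", {
  ds <- tiny_patches(30)
  m <- bdcnn_train(bdcnn_build(tiny_config()), ds)
  expect_true(m$trained)
  expect_lt(nrow(m$history), 30)  # stopped before the epoch cap
  expect_equal(tail(m$history$train_accuracy, 1), 1)
  # every epoch logged loss and accuracy
  expect_equal(m$history$epoch, seq_len(nrow(m$history)))

  # held-out separation
  heldout <- tiny_patches(10, seed = 2)
  p <- predict_mass_probability(m, heldout$patches)
  expect_gt(mean(p[heldout$labels == 1]), mean(p[heldout$labels == 0]))
})

test_that("training is reproducible and validates its inputs", {
  ds <- tiny_patches(12)
  m1 <- bdcnn_train(bdcnn_build(tiny_config()), ds)
  m2 <- bdcnn_train(bdcnn_build(tiny_config()), ds)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$fc2$W, m2$weights$fc2$W)

  single <- patch_dataset(ds$patches[ds$labels == 1],
                          rep("mass", sum(ds$labels == 1)))
  expect_error(bdcnn_train(bdcnn_build(tiny_config()), single), "both classes")

  # max_epochs = 0: untouched model, empty history
  m0 <- bdcnn_train(bdcnn_build(tiny_config(max_epochs = 0)), ds)
  expect_false(m0$trained)
  expect_equal(nrow(m0$history), 0)
})

test_that("checkpoints round-trip with config, seed and history", {
  ds <- tiny_patches(8)
  m <- bdcnn_train(bdcnn_build(tiny_config(max_epochs = 2)), ds)
  path <- file.path(tempdir(), "model.rds")
  bdcnn_save(m, path)
  back <- bdcnn_load(path)
  expect_equal(back$config$seed, 7)
  expect_identical(back$history, m$history)
  set.seed(123)
  patch <- matrix(runif(576, 0, 255), 24, 24)
  expect_equal(predict_mass_probability(back, patch),
               predict_mass_probability(m, patch), tolerance = 1e-6)

  hp <- file.path(tempdir(), "history.csv")
  write_history(m, hp)
  expect_equal(nrow(read.csv(hp)), nrow(m$history))
})

test_that("configs are validated", {
  expect_error(bdcnn_config(learning_rate = 0), "learning_rate")
  expect_error(bdcnn_config(n_kernels = c(8, 8), kernel_sizes = c(3, 3, 3)),
               "same length")
  expect_error(bdcnn_config(kernel_sizes = c(4, 3, 3)), "odd")
  expect_error(patch_dataset(list(matrix(0, 2, 2)), c("mass", "mass")),
               "equal length")
  expect_error(patch_dataset(list(matrix(0, 2, 2)), "tumour"), "labels")
})
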
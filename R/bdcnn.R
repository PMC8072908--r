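#' Configuration of the mass/background patch classifier
#'
#' The classifier is a small convolutional network: three blocks of
#' convolution (stride 1, zero "same" padding) -> batch normalization ->
#' ReLU -> 2x2/2 max-pooling, with 128 kernels per block of sizes 5x5,
#' 3x3, 3x3, followed by a 1024-node fully connected layer (ReLU) and a
#' 2-way softmax.  On the default 200x200 single-channel input the three
#' poolings leave 25x25x128 feature maps before flattening.  Training is
#' plain stochastic gradient descent on cross-entropy, stopping at
#' `max_epochs` or when training accuracy reaches
#' `stop_train_accuracy` (1.0 = 100%), whichever comes first.
#'
#' @param input_size patch size `c(width, height)`; default `c(200, 200)`.
#' @param n_kernels kernels per convolutional block.
#' @param kernel_sizes square kernel side per block.
#' @param fc_nodes nodes in the fully connected layer.
#' @param classes number of output classes (2: background, mass).
#' @param learning_rate SGD step size; default 1e-4.
#' @param max_epochs epoch cap; default 200.
#' @param stop_train_accuracy early-stop threshold on full-training-set
#'   accuracy; default 1.0.
#' @param batch_size minibatch size; default 32.
#' @param bn_momentum running-statistics momentum for batch norm.
#' @param intensity_scale patches are divided by this before entering the
#'   network (255 for 8-bit input).
#' @param seed integer seed controlling weight initialization and epoch
#'   shuffling.
#' @return a list of class `bdcnn_config`.
#' @export
bdcnn_config <- function(input_size = c(200, 200), n_kernels = c(128, 128, 128),
                         kernel_sizes = c(5, 3, 3), fc_nodes = 1024, classes = 2,
                         learning_rate = 1e-4, max_epochs = 200,
                         stop_train_accuracy = 1.0, batch_size = 32,
                         bn_momentum = 0.1, intensity_scale = 255, seed = 1) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (length(n_kernels) != length(kernel_sizes))
    stop("n_kernels and kernel_sizes must have the same length", call. = FALSE)
  if (any(kernel_sizes %% 2 == 0))
    stop("kernel sizes must be odd (same padding)", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 n_kernels = as.integer(n_kernels),
                 kernel_sizes = as.integer(kernel_sizes),
                 fc_nodes = as.integer(fc_nodes), classes = as.integer(classes),
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 stop_train_accuracy = stop_train_accuracy,
                 batch_size = as.integer(batch_size), bn_momentum = bn_momentum,
                 intensity_scale = intensity_scale, seed = as.integer(seed)),
            class = "bdcnn_config")
}

# Architecture descriptor passed to the C++ engine.  The fast dimension of
# the flattened patch vector is the matrix row (image height).
bdcnn_arch <- function(config) {
  list(df = config$input_size[2], ds = config$input_size[1],
       channels = config$n_kernels, ksize = config$kernel_sizes,
       fc_nodes = config$fc_nodes, classes = config$classes)
}

bdcnn_flat_dim <- function(config) {
  ds <- config$input_size[1]
  df <- config$input_size[2]
  for (i in seq_along(config$n_kernels)) {
    ds <- ds %/% 2L
    df <- df %/% 2L
  }
  ds * df * config$n_kernels[length(config$n_kernels)]
}

#' Build an initialized classifier
#'
#' Initializes all weights reproducibly from `config$seed`: He-normal for
#' convolutional and first fully connected weights, small normal for the
#' output layer, unit gamma / zero beta for batch norm.
#'
#' @param config a [bdcnn_config()].
#' @return an object of class `bdcnn`: list with `config`, `weights`,
#'   `trained`, `history`.
#' @export
bdcnn_build <- function(config = bdcnn_config()) {
  if (!inherits(config, "bdcnn_config")) stop("need a bdcnn_config", call. = FALSE)
  set.seed(config$seed)
  nb <- length(config$n_kernels)
  conv <- vector("list", nb)
  cin <- 1L
  for (i in seq_len(nb)) {
    k <- config$kernel_sizes[i]
    cout <- config$n_kernels[i]
    fan_in <- cin * k * k
    conv[[i]] <- list(
      W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
      b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
      rmean = numeric(cout), rvar = rep(1, cout))
    cin <- cout
  }
  flat <- bdcnn_flat_dim(config)
  weights <- list(
    conv = conv,
    fc1 = list(W = matrix(rnorm(flat * config$fc_nodes, sd = sqrt(2 / flat)),
                          flat, config$fc_nodes),
               b = numeric(config$fc_nodes)),
    fc2 = list(W = matrix(rnorm(config$fc_nodes * config$classes, sd = 0.01),
                          config$fc_nodes, config$classes),
               b = numeric(config$classes)))
  structure(list(config = config, weights = weights, trained = FALSE,
                 version = 0L, cache = new.env(parent = emptyenv()),
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      train_accuracy = numeric())),
            class = "bdcnn")
}

# The single-precision net used by the C++ engine is expensive to rebuild
# from the R weight list, so it is cached behind an external pointer keyed
# by the model's version stamp (and transparently rebuilt after
# deserialization, when the pointer comes back dead).
bdcnn_handle <- function(model) {
  cache <- model$cache
  if (!is.environment(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$handle) || !identical(cache$version, model$version) ||
      !cpp_cnn_handle_valid(cache$handle)) {
    cache$handle <- cpp_cnn_make_handle(model$weights, bdcnn_arch(model$config))
    cache$version <- model$version
  }
  cache$handle
}

#' @export
print.bdcnn <- function(x, ...) {
  cat(sprintf("bdcnn: %s input, blocks [%s] kernels [%s], fc %d, %s\n",
              paste(x$config$input_size, collapse = "x"),
              paste(x$config$n_kernels, collapse = ", "),
              paste(x$config$kernel_sizes, collapse = ", "),
              x$config$fc_nodes,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

#' Number of learnable parameters
#'
#' Counts convolution weights/biases, batch-norm gamma/beta and fully
#' connected weights/biases (running statistics are not learnable).
#'
#' @param model a `bdcnn`.
#' @return integer count.
#' @export
bdcnn_n_parameters <- function(model) {
  w <- model$weights
  n <- 0
  for (l in w$conv)
    n <- n + length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  n + length(w$fc1$W) + length(w$fc1$b) + length(w$fc2$W) + length(w$fc2$b)
}

#' Labelled patch dataset
#'
#' @param patches list of numeric matrices (or a 3-D array sliced along
#'   the third dimension), one per sample.
#' @param labels vector of `"mass"` / `"background"` (or 1/0).
#' @param provenance optional data frame recording each patch's source.
#' @return list of class `patch_dataset`.
#' @export
patch_dataset <- function(patches, labels, provenance = NULL) {
  if (is.array(patches) && length(dim(patches)) == 3L)
    patches <- lapply(seq_len(dim(patches)[3]), function(i) patches[, , i])
  labels <- normalize_labels(labels)
  if (length(patches) != length(labels))
    stop("patches and labels must have equal length", call. = FALSE)
  structure(list(patches = patches, labels = labels, provenance = provenance),
            class = "patch_dataset")
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("mass", "background")
    if (any(bad)) stop("labels must be 'mass' or 'background'", call. = FALSE)
    return(as.integer(labels == "mass"))
  }
  if (!all(labels %in% c(0, 1)))
    stop("numeric labels must be 0 (background) or 1 (mass)", call. = FALSE)
  as.integer(labels)
}

# Stack patches into the N x (w*h) design matrix expected by the engine.
patch_design_matrix <- function(patches, config) {
  h <- config$input_size[2]
  w <- config$input_size[1]
  X <- matrix(0, length(patches), h * w)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (nrow(p) != h || ncol(p) != w) p <- resize_image(p, w, h)
    X[i, ] <- as.vector(p) / config$intensity_scale
  }
  X
}

#' Train the classifier by SGD
#'
#' Runs minibatch SGD on cross-entropy.  After every epoch the training
#' accuracy is recomputed on the full training set in evaluation mode
#' (batch norm uses running statistics) and training stops as soon as it
#' reaches `stop_train_accuracy` or the epoch cap is hit.  Training is
#' reproducible given the config seed.
#'
#' @param model a `bdcnn` from [bdcnn_build()].
#' @param data a [patch_dataset()] containing both classes.
#' @param quiet suppress per-epoch progress messages.
#' @return the trained model; `model$history` holds one row per epoch
#'   (`epoch`, `loss`, `train_accuracy`).
#' @export
bdcnn_train <- function(model, data, quiet = TRUE) {
  stopifnot(inherits(model, "bdcnn"))
  if (!inherits(data, "patch_dataset")) stop("need a patch_dataset", call. = FALSE)
  y <- data$labels
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  config <- model$config
  arch <- bdcnn_arch(config)
  X <- patch_design_matrix(data$patches, config)
  n <- nrow(X)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_accuracy = numeric())
  set.seed(config$seed)
  handle <- cpp_cnn_make_handle(model$weights, arch)
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    perm <- sample.int(n)
    res <- cpp_cnn_epoch_ptr(handle, X, y, config$learning_rate,
                             config$batch_size, perm, config$bn_momentum)
    probs <- cpp_cnn_predict_ptr(handle, X, config$batch_size)
    acc <- mean((probs[, 2] >= 0.5) == (y == 1L))
    history <- rbind(history, data.frame(epoch = epoch, loss = res$loss,
                                         train_accuracy = acc))
    if (!quiet)
      message(sprintf("epoch %d: loss %.4f, train accuracy %.3f",
                      epoch, res$loss, acc))
    if (acc >= config$stop_train_accuracy) break
  }
  if (epoch > 0L) {
    model$weights <- cpp_cnn_get_weights(handle)
    model$trained <- TRUE
    model$version <- model$version + 1L
  }
  model$history <- history
  model$cache <- new.env(parent = emptyenv())
  model$cache$handle <- handle
  model$cache$version <- model$version
  model
}

#' Classify patches
#'
#' `bdcnn_predict()` returns the full softmax output (columns:
#' background, mass); `predict_mass_probability()` returns just the mass
#' probability.  Patches not matching the configured input size are
#' resized bilinearly first.
#'
#' @param model a built (and normally trained) `bdcnn`.
#' @param patches a single numeric matrix or a list of them.
#' @return `bdcnn_predict()`: numeric matrix `n x classes`, rows summing
#'   to 1; `predict_mass_probability()`: numeric vector in \[0,1\].
#' @export
bdcnn_predict <- function(model, patches) {
  stopifnot(inherits(model, "bdcnn"))
  if (is.null(model$weights)) stop("model has no weights", call. = FALSE)
  if (is.matrix(patches)) patches <- list(patches)
  X <- patch_design_matrix(patches, model$config)
  probs <- cpp_cnn_predict_ptr(bdcnn_handle(model), X, model$config$batch_size)
  colnames(probs) <- c("background", "mass")[seq_len(ncol(probs))]
  probs
}

#' @rdname bdcnn_predict
#' @export
predict_mass_probability <- function(model, patches) {
  bdcnn_predict(model, patches)[, 2]
}

#' Vectorized PSO fitness from a trained classifier
#'
#' @param model a trained `bdcnn`.
#' @return function mapping a list of patches to their mass probabilities,
#'   suitable as the `fitness` argument of [pso_refine()].
#' @export
bdcnn_fitness <- function(model) {
  force(model)
  function(patches) predict_mass_probability(model, patches)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint embeds the full configuration (including the seed) and
#' the training history alongside the weights.
#'
#' @param model a `bdcnn`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
bdcnn_save <- function(model, path) {
  stopifnot(inherits(model, "bdcnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname bdcnn_save
#' @export
bdcnn_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bdcnn"))
  model
}

#' Export a training history as CSV
#'
#' @param model a trained `bdcnn`.
#' @param path output CSV path.
#' @export
write_history <- function(model, path) {
  write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
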
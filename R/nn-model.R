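#' Classifier architecture configuration
#'
#' Two architectures are provided. `"designed_cnn"` is the lightweight
#' network at the heart of the pipeline: exactly three convolutional stages
#' (convolution, batch normalization, ReLU, 2x2 max pooling) followed by
#' two fully connected layers (a hidden dense layer with ReLU and dropout,
#' then the 3-way softmax output) on a 64 x 64 single-channel input.
#' `"residual18"` is the standard 18-layer residual topology (eight
#' two-convolution residual blocks in four channel stages of 64/128/256/512
#' plus stem and final dense layer) adapted to the single-channel 64 x 64
#' input, always randomly initialized with no frozen layers.
#' `"residual_small"` is a reduced-depth residual variant for desk-scale
#' experiments.
#'
#' @param architecture `"designed_cnn"`, `"residual18"` or `"residual_small"`.
#' @param conv_channels integer triple: channels of the three convolutional
#'   stages of the designed network.
#' @param kernel_size convolution kernel side (odd).
#' @param dense_units hidden units of the first fully connected layer.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param use_batch_norm include batch normalization after convolutions.
#' @param n_classes number of output classes.
#' @param input_size input side length in pixels.
#' @return Object of class `model_config`.
#' @export
model_config <- function(architecture = c("designed_cnn", "residual18", "residual_small"),
                         conv_channels = c(16L, 32L, 64L),
                         kernel_size = 3L,
                         dense_units = 128L,
                         dropout_rate = 0.5,
                         use_batch_norm = TRUE,
                         n_classes = 3L,
                         input_size = 64L) {
  architecture <- match.arg(architecture)
  if (length(conv_channels) != 3L || any(conv_channels < 1)) {
    stop("`conv_channels` must be three positive integers", call. = FALSE)
  }
  check_number(dropout_rate, "dropout_rate", min = 0, max = 1 - 1e-9)
  if (input_size %% 8L != 0L) {
    stop("`input_size` must be divisible by 8 (three 2x2 poolings)", call. = FALSE)
  }
  structure(
    list(architecture = architecture,
         conv_channels = as.integer(conv_channels),
         kernel_size = as.integer(kernel_size),
         dense_units = as.integer(dense_units),
         dropout_rate = dropout_rate,
         use_batch_norm = isTRUE(use_batch_norm),
         n_classes = as.integer(n_classes),
         input_size = as.integer(input_size)),
    class = "model_config"
  )
}

build_layers <- function(config) {
  k <- config$kernel_size
  if (config$architecture == "designed_cnn") {
    ch <- config$conv_channels
    layers <- list()
    in_c <- 1L
    for (i in 1:3) {
      layers <- c(layers, list(layer_conv(in_c, ch[i], k)))
      if (config$use_batch_norm) layers <- c(layers, list(layer_bn(ch[i])))
      layers <- c(layers, list(layer_relu(), layer_maxpool()))
      in_c <- ch[i]
    }
    feat <- (config$input_size %/% 8L)^2 * ch[3]
    c(layers, list(layer_flatten(),
                   layer_dense(feat, config$dense_units),
                   layer_relu(),
                   layer_dropout(config$dropout_rate),
                   layer_dense(config$dense_units, config$n_classes)))
  } else if (config$architecture == "residual18") {
    layers <- list(layer_conv(1L, 64L, k), layer_bn(64L), layer_relu(),
                   layer_residual(64L, 64L, 1L, k),
                   layer_residual(64L, 64L, 1L, k),
                   layer_residual(64L, 128L, 2L, k),
                   layer_residual(128L, 128L, 1L, k),
                   layer_residual(128L, 256L, 2L, k),
                   layer_residual(256L, 256L, 1L, k),
                   layer_residual(256L, 512L, 2L, k),
                   layer_residual(512L, 512L, 1L, k),
                   layer_gap(),
                   layer_dense(512L, config$n_classes))
  } else {
    layers <- list(layer_conv(1L, 8L, k), layer_bn(8L), layer_relu(),
                   layer_residual(8L, 8L, 1L, k),
                   layer_residual(8L, 16L, 2L, k),
                   layer_residual(16L, 32L, 2L, k),
                   layer_gap(),
                   layer_dense(32L, config$n_classes))
  }
}

#' Build an (untrained) classifier
#'
#' Parameters are randomly initialized (He-scaled Gaussians) from `seed`;
#' two calls with the same configuration and seed produce identical
#' networks.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initialization.
#' @return Object of class `cvm_model` with `config`, `layers`, `history`.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  layers <- with_seed(seed, build_layers(config))
  structure(list(config = config, layers = layers, seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "cvm_model")
}

#' @export
print.cvm_model <- function(x, ...) {
  cat(sprintf("<cvm_model> %s, %s parameters, %s\n",
              x$config$architecture, format(n_params(x), big.mark = ","),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `cvm_model`.
#' @return Total count of trainable weights (convolution and dense weights
#'   and biases, batch-norm scales and offsets).
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "cvm_model"))
  paths <- collect_param_paths(model$layers)
  sum(vapply(paths, function(p) length(pluck_path(model$layers, p)), numeric(1)))
}

# stack a list of HxW matrices into the internal (H*W*N) x 1 tensor
images_to_tensor <- function(images, input_size) {
  n <- length(images)
  for (im in images) {
    px <- if (inherits(im, "roi_image")) im$pixels else im
    if (!is.matrix(px) || nrow(px) != input_size || ncol(px) != input_size) {
      stopf("every image must be a %d x %d matrix", input_size, input_size)
    }
  }
  px <- vapply(images, function(im) {
    as.vector(if (inherits(im, "roi_image")) im$pixels else im)
  }, numeric(input_size^2))
  sp_attr(matrix(as.vector(px), ncol = 1L), input_size, input_size, n)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Predict stage probabilities for a batch of images
#'
#' @param model a `cvm_model`.
#' @param images list of 64 x 64 matrices or [roi_image()] objects (a single
#'   matrix is accepted).
#' @param batch_size forward-pass batch size.
#' @return List with `probabilities` (n x 3 matrix, rows summing to 1) and
#'   `labels` (character; argmax with ties broken toward the earlier
#'   stage).
#' @export
predict_stages <- function(model, images, batch_size = 64L) {
  stopifnot(inherits(model, "cvm_model"))
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "roi_image")) images <- list(images)
  n <- length(images)
  probs <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, stage_levels()))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- images_to_tensor(images[idx], model$config$input_size)
    logits <- seq_forward(model$layers, x, training = FALSE)$out
    probs[idx, ] <- t(softmax_cols(logits))
  }
  labels <- stage_levels()[apply(probs, 1, which.max)]
  list(probabilities = probs, labels = labels)
}

#' Save / load a trained model
#'
#' The weights, configuration and training history are serialized together
#' into one portable RDS file.
#'
#' @param model a `cvm_model`.
#' @param path file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cvm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cvm_model"))
  m
}
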
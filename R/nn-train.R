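#' Training configuration
#'
#' @param epochs number of passes over the training partition.
#' @param batch_size minibatch size.
#' @param initial_lr initial learning rate of the adaptive-moment
#'   optimizer (the ecosystem default of 1e-3).
#' @param lr_schedule `"decreasing"` (step decay: multiply by
#'   `decay_factor` every `decay_every` epochs) or `"constant"`.
#' @param decay_every,decay_factor step-decay parameters.
#' @param augmentation list with `max_rotation_deg` (default 20),
#'   `shift_frac` (default 0.10) and `zoom_frac` (default 0.10); set all to
#'   0 to disable augmentation.
#' @param seed integer seed driving shuffling, augmentation and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, initial_lr = 1e-3,
                         lr_schedule = c("decreasing", "constant"),
                         decay_every = 50L, decay_factor = 0.5,
                         augmentation = list(max_rotation_deg = 20,
                                             shift_frac = 0.10,
                                             zoom_frac = 0.10),
                         seed = 0L) {
  lr_schedule <- match.arg(lr_schedule)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  check_number(initial_lr, "initial_lr", min = 0)
  aug <- utils::modifyList(
    list(max_rotation_deg = 20, shift_frac = 0.10, zoom_frac = 0.10),
    augmentation %||% list())
  if (any(unlist(aug) < 0)) stop("augmentation magnitudes must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_schedule = lr_schedule,
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, augmentation = aug,
                 seed = as.integer(seed)),
            class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reflect a continuous pixel coordinate into [1, n]
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  x <- (x - 1) %% p
  x <- ifelse(x > (n - 1), p - x, x)
  x + 1
}

#' Apply a rotation / shift / zoom transform to an image
#'
#' Inverse-mapped affine warp with bilinear sampling and reflection at the
#' image borders. A shift of `(dr, dc)` moves image content down by `dr`
#' rows and right by `dc` columns; zoom > 1 magnifies about the center.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param rotation_deg rotation about the image center, degrees.
#' @param shift_rows,shift_cols translation in pixels.
#' @param zoom magnification factor.
#' @return Warped matrix of the same size, clipped to `[0, 1]`.
#' @export
affine_warp <- function(img, rotation_deg = 0, shift_rows = 0, shift_cols = 0,
                        zoom = 1) {
  stopifnot(is.matrix(img), zoom > 0)
  h <- nrow(img); w <- ncol(img)
  if (rotation_deg == 0 && shift_rows == 0 && shift_cols == 0 && zoom == 1) {
    return(img)
  }
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  th <- rotation_deg * pi / 180
  ur <- matrix(rep(seq_len(h) - cr - shift_rows, times = w), h, w)
  uc <- matrix(rep(seq_len(w) - cc - shift_cols, each = h), h, w)
  src_r <- cr + (cos(th) * ur - sin(th) * uc) / zoom
  src_c <- cc + (sin(th) * ur + cos(th) * uc) / zoom
  src_r <- reflect_coord(src_r, h)
  src_c <- reflect_coord(src_c, w)
  r0 <- pmin(floor(src_r), h - 1); r1 <- r0 + 1
  c0 <- pmin(floor(src_c), w - 1); c1 <- c0 + 1
  r0 <- pmax(r0, 1); c0 <- pmax(c0, 1)
  fr <- src_r - r0; fc <- src_c - c0
  i00 <- img[cbind(as.vector(r0), as.vector(c0))]
  i10 <- img[cbind(as.vector(r1), as.vector(c0))]
  i01 <- img[cbind(as.vector(r0), as.vector(c1))]
  i11 <- img[cbind(as.vector(r1), as.vector(c1))]
  out <- (1 - as.vector(fr)) * (1 - as.vector(fc)) * i00 +
    as.vector(fr) * (1 - as.vector(fc)) * i10 +
    (1 - as.vector(fr)) * as.vector(fc) * i01 +
    as.vector(fr) * as.vector(fc) * i11
  out <- matrix(out, h, w)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Randomly augment one training image
#'
#' Draws a rotation uniform in +/- `max_rotation_deg`, row and column
#' shifts uniform in +/- `shift_frac` of the image size, and a zoom factor
#' uniform in `1 +/- zoom_frac`, then applies [affine_warp()]. With all
#' magnitudes zero the image is returned unchanged.
#'
#' @param img numeric matrix.
#' @param config a [train_config()] (its `augmentation` entry is used) or a
#'   plain list with the three magnitude fields.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as during training).
#' @return Augmented matrix of identical size.
#' @export
augment <- function(img, config, seed = NULL) {
  aug <- if (inherits(config, "train_config")) config$augmentation else config
  draw <- function() {
    ang <- if (aug$max_rotation_deg > 0) {
      stats::runif(1, -aug$max_rotation_deg, aug$max_rotation_deg)
    } else 0
    sr <- if (aug$shift_frac > 0) stats::runif(1, -1, 1) * aug$shift_frac * nrow(img) else 0
    sc <- if (aug$shift_frac > 0) stats::runif(1, -1, 1) * aug$shift_frac * ncol(img) else 0
    zm <- if (aug$zoom_frac > 0) stats::runif(1, 1 - aug$zoom_frac, 1 + aug$zoom_frac) else 1
    affine_warp(img, ang, sr, sc, zm)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

labels_to_onehot <- function(labels) {
  f <- as_stage(labels)
  if (anyNA(f)) stop("training labels must all be one of the three stages", call. = FALSE)
  y <- matrix(0, 3, length(f))
  y[cbind(as.integer(f), seq_along(f))] <- 1
  y
}

#' Assemble in-memory training data from a dataset split
#'
#' @param split a [stratified_split()] result whose rows carry either an
#'   `image_id` column indexing into `images`, or a `roi_path`/`path`
#'   column of PNG files.
#' @param images optional list of [roi_image()] (or matrices) referenced by
#'   `image_id`.
#' @return List with `train`, `validation`, `test`, each a list of
#'   `x` (list of matrices) and `y` (stage labels).
#' @export
dataset_from_split <- function(split, images = NULL) {
  stopifnot(inherits(split, "dataset_split"))
  one <- function(d) {
    if (nrow(d) == 0L) return(list(x = list(), y = character(0)))
    x <- if (!is.null(images) && "image_id" %in% names(d)) {
      lapply(d$image_id, function(i) {
        im <- images[[i]]
        if (inherits(im, "roi_image")) im$pixels else im
      })
    } else {
      col <- intersect(c("roi_path", "path"), names(d))[1]
      if (is.na(col)) stop("split rows carry neither image_id nor a path column",
                           call. = FALSE)
      lapply(d[[col]], read_image)
    }
    list(x = x, y = d$stage_label)
  }
  list(train = one(split$train), validation = one(split$validation),
       test = one(split$test))
}

model_eval <- function(layers, images, labels, input_size, batch_size = 64L) {
  n <- length(images)
  loss <- 0; correct <- 0
  y_all <- labels_to_onehot(labels)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- images_to_tensor(images[idx], input_size)
    logits <- seq_forward(layers, x, training = FALSE)$out
    p <- softmax_cols(logits)
    y <- y_all[, idx, drop = FALSE]
    loss <- loss - sum(log(pmax(colSums(p * y), 1e-12)))
    correct <- correct + sum(apply(p, 2, which.max) == apply(y, 2, which.max))
  }
  c(loss = loss / n, accuracy = correct / n)
}

#' Train a classifier on a dataset split
#'
#' Minibatch training with softmax cross-entropy loss and the Adam
#' optimizer; every image presentation is independently augmented per
#' [augment()]. The learning rate follows the configured schedule. After
#' every epoch the model is evaluated on the validation partition and the
#' weights from the best validation-accuracy epoch (earliest on ties) are
#' retained in the returned model. All randomness (shuffling, augmentation,
#' dropout) is driven by `config$seed`.
#'
#' @param model an untrained (or previously trained) `cvm_model`.
#' @param data list with `train` and `validation`, each `list(x = <list of
#'   matrices>, y = <stage labels>)`, e.g. from [dataset_from_split()].
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return The trained `cvm_model`, with `history` (data frame of per-epoch
#'   train/validation loss and accuracy) and `best_epoch` filled in.
#' @export
train_model <- function(model, data, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cvm_model"), inherits(config, "train_config"))
  train <- data$train; val <- data$validation
  if (length(train$x) == 0L || length(val$x) == 0L) {
    stop("train and validation partitions must both be non-empty", call. = FALSE)
  }
  input_size <- model$config$input_size
  layers <- model$layers
  paths <- collect_param_paths(layers)
  opt_m <- lapply(paths, function(p) pluck_path(layers, p) * 0)
  opt_v <- opt_m
  beta1 <- 0.9; beta2 <- 0.999; opt_eps <- 1e-8; t_step <- 0L
  y_train <- labels_to_onehot(train$y)
  n_train <- length(train$x)
  history <- vector("list", config$epochs)
  best <- list(acc = -Inf, epoch = NA_integer_, layers = layers)
  aug_on <- any(unlist(config$augmentation) > 0)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$initial_lr
      if (config$lr_schedule == "decreasing") {
        lr <- lr * config$decay_factor^((epoch - 1L) %/% config$decay_every)
      }
      ord <- sample.int(n_train)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n_train, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_train)]
        imgs <- train$x[idx]
        if (aug_on) imgs <- lapply(imgs, augment, config = config)
        x <- images_to_tensor(imgs, input_size)
        fw <- seq_forward(layers, x, training = TRUE)
        layers <- fw$layers                       # batch-norm running stats
        p <- softmax_cols(fw$out)
        y <- y_train[, idx, drop = FALSE]
        nb <- length(idx)
        ep_loss <- ep_loss - sum(log(pmax(colSums(p * y), 1e-12)))
        ep_correct <- ep_correct + sum(apply(p, 2, which.max) == apply(y, 2, which.max))
        if (!all(is.finite(p))) {
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        }
        dlogits <- (p - y) / nb
        bw <- seq_backward(layers, fw$caches, dlogits)
        if (lr > 0) {
          t_step <- t_step + 1L
          for (j in seq_along(paths)) {
            g <- pluck_path(bw$grads, paths[[j]])
            opt_m[[j]] <- beta1 * opt_m[[j]] + (1 - beta1) * g
            opt_v[[j]] <- beta2 * opt_v[[j]] + (1 - beta2) * g^2
            mhat <- opt_m[[j]] / (1 - beta1^t_step)
            vhat <- opt_v[[j]] / (1 - beta2^t_step)
            w <- pluck_path(layers, paths[[j]]) - lr * mhat / (sqrt(vhat) + opt_eps)
            layers <- assign_path(layers, paths[[j]], w)
          }
        }
      }
      vm <- model_eval(layers, val$x, val$y, input_size)
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        train_loss = ep_loss / n_train, train_accuracy = ep_correct / n_train,
        val_loss = vm[["loss"]], val_accuracy = vm[["accuracy"]])
      if (vm[["accuracy"]] > best$acc) {
        best <- list(acc = vm[["accuracy"]], epoch = epoch, layers = layers)
      }
      if (verbose) {
        message(sprintf(
          "epoch %3d  lr %.2g  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
          epoch, lr, ep_loss / n_train, ep_correct / n_train,
          vm[["loss"]], vm[["accuracy"]]))
      }
    }
  })
  model$layers <- best$layers
  model$final_layers <- layers
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model$best_epoch <- best$epoch
  model
}

#' Class-activation heat map (gradient-weighted)
#'
#' Computes the gradient of the predicted class's logit with respect to the
#' activations of the last convolutional stage (the input of the flatten or
#' global-pooling layer), averages the gradient spatially into per-channel
#' weights, forms the weighted, rectified sum of the activation channels,
#' upsamples it bilinearly to the input size and normalizes the maximum to
#' 1 (an all-zero map stays all zero).
#'
#' @param model a trained `cvm_model`.
#' @param image 64 x 64 matrix or [roi_image()].
#' @return List with `map` (input-sized matrix in `[0, 1]`), `class` (the
#'   predicted stage) and `raw` (the unnormalized low-resolution map).
#' @export
class_activation_map <- function(model, image) {
  stopifnot(inherits(model, "cvm_model"))
  if (inherits(image, "roi_image")) image <- image$pixels
  layers <- model$layers
  j <- which(vapply(layers, function(l) l$type %in% c("flatten", "gap"), logical(1)))
  if (length(j) == 0L) {
    stop("architecture has no convolutional stage to map", call. = FALSE)
  }
  j <- j[1]
  if (!any(vapply(layers[seq_len(j - 1L)],
                  function(l) l$type %in% c("conv", "residual"), logical(1)))) {
    stop("architecture has no convolutional stage to map", call. = FALSE)
  }
  x <- images_to_tensor(list(image), model$config$input_size)
  fw <- seq_forward(layers, x, training = FALSE, keep_activations = TRUE)
  probs <- softmax_cols(fw$out)
  cls <- which.max(probs[, 1])
  donehot <- matrix(0, nrow(fw$out), 1)
  donehot[cls, 1] <- 1
  bw <- seq_backward(layers, fw$caches, donehot, stop_at = j - 1L)
  a <- fw$activations[[j]]                      # input of flatten/gap: P x C
  da <- bw$dx
  alpha <- colMeans(da)
  cam <- as.vector(a %*% alpha)
  cam[cam < 0] <- 0
  d <- sp_dims(a)
  raw <- matrix(cam, d[["H"]], d[["W"]])
  up <- resize_image(raw, model$config$input_size, model$config$input_size)
  up[up < 0] <- 0
  if (max(up) > 0) up <- up / max(up)
  list(map = up, class = stage_levels()[cls], raw = raw)
}
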
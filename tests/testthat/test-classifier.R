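test_that("model configuration is validated", {
  expect_error(model_config("vgg16"))
  expect_error(model_config(dropout_rate = 1), "dropout_rate")
  expect_error(model_config(conv_channels = c(8, 16)), "conv_channels")
  expect_error(model_config(input_size = 60L), "divisible")
})

test_that("designed network has the closed-form parameter count", {
  m <- build_model(model_config("designed_cnn"), seed = 1)
  # independent arithmetic over layer shapes: 3 conv stages (3x3 kernels,
  # channels 1->16->32->64, bias + batch-norm scale/offset), dense 4096->128,
  # dense 128->3
  conv <- (3 * 3 * 1 * 16 + 16) + (3 * 3 * 16 * 32 + 32) + (3 * 3 * 32 * 64 + 64)
  bn <- 2 * (16 + 32 + 64)
  dense <- (8 * 8 * 64) * 128 + 128 + 128 * 3 + 3
  expect_equal(n_params(m), conv + bn + dense)
})

test_that("untrained predictions are valid softmax outputs, deterministically", {
  m <- build_model(model_config("designed_cnn"), seed = 3)
  img <- matrix(runif(64 * 64), 64, 64)
  pr <- predict_stages(m, img)
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-9)
  expect_true(all(pr$probabilities >= 0 & pr$probabilities <= 1))
  m2 <- build_model(model_config("designed_cnn"), seed = 3)
  expect_identical(predict_stages(m2, img)$probabilities, pr$probabilities)
  m3 <- build_model(model_config("designed_cnn"), seed = 4)
  expect_false(identical(predict_stages(m3, img)$probabilities, pr$probabilities))
})

test_that("the 18-layer residual network builds and predicts", {
  m <- build_model(model_config("residual18"), seed = 2)
  expect_gt(n_params(m), 1e7)            # standard-depth residual topology
  pr <- predict_stages(m, matrix(0.5, 64, 64))
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-9)
})

test_that("batched predictions preserve order and duplicates", {
  m <- build_model(model_config("designed_cnn"), seed = 5)
  imgs <- lapply(1:7, function(i) matrix(runif(4096), 64, 64))
  imgs[[7]] <- imgs[[2]]
  pr <- predict_stages(m, imgs, batch_size = 3)
  expect_equal(nrow(pr$probabilities), 7L)
  expect_equal(pr$probabilities[7, ], pr$probabilities[2, ])
  expect_error(predict_stages(m, matrix(0.5, 32, 32)), "64 x 64")
})

test_that("augmentation with zero magnitudes is the identity", {
  img <- matrix(runif(4096), 64, 64)
  cfg <- train_config(augmentation = list(max_rotation_deg = 0, shift_frac = 0,
                                          zoom_frac = 0))
  expect_identical(augment(img, cfg, seed = 1), img)
  expect_identical(affine_warp(img), img)
})

test_that("augmentation draws are reproducible under a fixed seed", {
  img <- matrix(runif(4096), 64, 64)
  cfg <- train_config()
  a <- augment(img, cfg, seed = 10)
  expect_identical(augment(img, cfg, seed = 10), a)
  expect_false(identical(augment(img, cfg, seed = 11), a))
  expect_false(identical(a, img))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), c(64L, 64L))
})

test_that("pure integer shifts move pixels by exact index arithmetic", {
  img <- matrix(0, 64, 64)
  img[20, 30] <- 1
  shifted <- affine_warp(img, rotation_deg = 0, shift_rows = 6, shift_cols = 0)
  expect_equal(shifted[26, 30], 1)
  expect_equal(sum(shifted), 1)
  both <- affine_warp(img, shift_rows = -3, shift_cols = 5)
  expect_equal(both[17, 35], 1)
})

test_that("a zero learning rate leaves the weights unchanged", {
  env <- trained_fixture()
  data <- env$data
  m <- build_model(model_config("designed_cnn"), seed = 9)
  cfg <- train_config(epochs = 1, initial_lr = 0, seed = 1,
                      augmentation = list(max_rotation_deg = 0, shift_frac = 0,
                                          zoom_frac = 0))
  mt <- train_model(m, data, cfg)
  # weights identical; only batch-norm running statistics may advance
  paths <- cvmgrowth:::collect_param_paths(m$layers)
  for (p in paths) {
    expect_identical(cvmgrowth:::pluck_path(mt$final_layers, p),
                     cvmgrowth:::pluck_path(m$layers, p))
  }
})

test_that("training on separable synthetic data reduces the loss and beats chance", {
  env <- trained_fixture()
  h <- env$model$history
  expect_equal(nrow(h), 18L)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
  pr <- predict_stages(env$model, env$data$test$x)
  acc <- mean(pr$labels == env$data$test$y)
  expect_gte(acc, 2 / 3)                      # at least twice the 1/3 chance rate
})

test_that("training is bit-reproducible under identical seeds", {
  env <- trained_fixture()
  small <- list(
    train = list(x = env$data$train$x[c(1:10, 21:30, 41:50)],
                 y = env$data$train$y[c(1:10, 21:30, 41:50)]),
    validation = env$data$validation
  )
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 5)
  m1 <- train_model(build_model(model_config("designed_cnn"), seed = 2), small, cfg)
  m2 <- train_model(build_model(model_config("designed_cnn"), seed = 2), small, cfg)
  expect_identical(m1$history, m2$history)
  img <- env$data$test$x[[1]]
  expect_identical(predict_stages(m1, img)$probabilities,
                   predict_stages(m2, img)$probabilities)
})

test_that("the reduced residual variant trains end to end", {
  env <- trained_fixture()
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 3)
  m <- train_model(build_model(model_config("residual_small"), seed = 3),
                   env$data, cfg)
  expect_equal(nrow(m$history), 2L)
  expect_true(all(is.finite(m$history$train_loss)))
  pr <- predict_stages(m, env$data$test$x[1:3])
  expect_equal(rowSums(pr$probabilities), rep(1, 3), tolerance = 1e-9)
})

test_that("class-activation maps are normalized and finite", {
  env <- trained_fixture()
  cam <- class_activation_map(env$model, env$data$test$x[[1]])
  expect_equal(dim(cam$map), c(64L, 64L))
  expect_true(all(cam$map >= 0 & cam$map <= 1))
  expect_true(cam$class %in% stage_levels())
  zero <- class_activation_map(env$model, matrix(0, 64, 64))
  expect_true(all(is.finite(zero$map)))
})

test_that("activation maps concentrate on the drawn vertebral column", {
  env <- trained_fixture()
  imgs <- build_synthetic_dataset(17, render_params(), seed = 99)$images
  inside <- 0
  for (im in imgs[1:50]) {
    cam <- class_activation_map(env$model, im)
    if (sum(cam$map) == 0) next
    w <- cam$map / sum(cam$map)
    com_r <- sum(rowSums(w) * seq_len(64))
    com_c <- sum(colSums(w) * seq_len(64))
    # column bounding box: vertical span 0.1-0.9 of the image, widest body
    # ~20 px around the centerline
    if (com_r >= 6.4 && com_r <= 57.6 && com_c >= 22 && com_c <= 43) {
      inside <- inside + 1
    }
  }
  expect_gte(inside / 50, 0.8)
})

test_that("architectures without convolutions cannot produce activation maps", {
  m <- build_model(model_config("designed_cnn"), seed = 1)
  m$layers <- m$layers[13:17]                 # strip the convolutional stages
  expect_error(class_activation_map(m, matrix(0.5, 64, 64)),
               "no convolutional stage")
})

test_that("models survive a save/load round trip", {
  env <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(env$model, path)
  m2 <- load_model(path)
  img <- env$data$test$x[[2]]
  expect_identical(predict_stages(m2, img), predict_stages(env$model, img))
  expect_equal(m2$history, env$model$history)
})
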